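# score aggregation, correlation, permutation inference, cross-prediction

make_model <- function(fiber_ids, t_values, valid = rep(TRUE, length(fiber_ids)),
                       n_stims = 10L) {
  structure(list(fiber_ids = as.integer(fiber_ids), t_values = t_values,
                 n_connected = rep(5L, length(fiber_ids)), valid = valid,
                 min_per_group = 2L, n_stims = n_stims, var_equal = TRUE,
                 provenance = "test"),
            class = "fiber_score_model")
}

two_stim_cohort <- function(amplitudes, improvements = c(20, 40)) {
  g <- test_grid()
  sphere_cohort(rbind(c(0, 0, 0), c(10, 10, 10)), c(3, 3), g,
                improvements = improvements, amplitudes = amplitudes)
}

test_that("aggregate scores sum connected valid t-values over amplitude", {
  inc <- incidence_matrix(rbind(c(TRUE, FALSE), c(TRUE, FALSE), c(FALSE, FALSE)),
                          1:3, c("test_s01", "test_s02"))
  model <- make_model(1:3, c(2, -1, 99), n_stims = 2L)
  co <- two_stim_cohort(amplitudes = c(2, 3))
  sc <- aggregate_scores(inc, model, co)
  expect_equal(sc$raw_sum, c(1, 0))     # 2 + (-1); nothing connected to s02
  expect_equal(sc$score, c(0.5, 0))     # divided by amplitude; empty -> 0

  # invalid fibers contribute nothing even with nonzero stored t
  model2 <- make_model(1:3, c(2, -1, 99), valid = c(TRUE, FALSE, TRUE), n_stims = 2L)
  expect_equal(aggregate_scores(inc, model2, co)$raw_sum, c(2, 0))

  # doubling amplitude halves the score exactly
  co2 <- two_stim_cohort(amplitudes = c(4, 6))
  expect_equal(aggregate_scores(inc, model, co2)$score, sc$score / 2)
})

test_that("aggregation is additive in the model and ignores unconnected fibers", {
  inc <- random_incidence(50, 8, seed = 41)
  inc$stim_ids <- sprintf("test_s%02d", 1:8)
  g <- test_grid()
  co <- sphere_cohort(matrix(rnorm(24, sd = 5), 8, 3), rep(3, 8), g,
                      amplitudes = runif(8, 2, 5))
  set.seed(42)
  ta <- rnorm(50); tb <- rnorm(50)
  sa <- aggregate_scores(inc, make_model(1:50, ta, n_stims = 8L), co)
  sb <- aggregate_scores(inc, make_model(1:50, tb, n_stims = 8L), co)
  sab <- aggregate_scores(inc, make_model(1:50, ta + tb, n_stims = 8L), co)
  expect_equal(sab$raw_sum, sa$raw_sum + sb$raw_sum, tolerance = 1e-12)

  # appending fibers connected to nothing changes no score
  inc2 <- incidence_matrix(rbind(as.matrix(inc$entries), matrix(FALSE, 5, 8)),
                           c(1:50, 51:55), inc$stim_ids)
  m2 <- make_model(c(1:50, 51:55), c(ta, rep(9, 5)), n_stims = 8L)
  expect_equal(aggregate_scores(inc2, m2, co)$score, sa$score)
})

test_that("correlation handles the canonical examples and degenerate input", {
  expect_equal(correlate(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1.0)
  expect_equal(correlate(c(1, 2, 3, 4), -c(1, 2, 3, 4)), -1.0)
  expect_equal(correlate(c(1, 2, 3), c(2, 1, 3)), 0.5)   # hand Pearson
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")
  expect_equal(correlate(c(1, 2, 3), c(10, 20, 25), method = "spearman"), 1.0)
})

test_that("Pearson r is invariant to positive affine rescaling of either side", {
  set.seed(51)
  x <- rnorm(15); y <- rnorm(15)
  r <- correlate(x, y)
  expect_equal(correlate(3 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(correlate(x, 0.2 * y - 11), r, tolerance = 1e-12)
})

test_that("permutation p uses the add-one estimator and is seed-deterministic", {
  set.seed(61)
  x <- rnorm(12)
  y <- 2 * x + 1          # perfectly matched: no permutation ties |r| = 1
  res <- permutation_p(x, y, n_perm = 1000, seed = 4)
  expect_equal(res$p_perm, 1 / 1001)
  expect_equal(res$r, 1.0)

  res2 <- permutation_p(x, y, n_perm = 1000, seed = 4)
  expect_identical(res2$p_perm, res$p_perm)
  set.seed(999)  # ambient RNG state must not leak in
  res3 <- permutation_p(x, y, n_perm = 1000, seed = 4)
  expect_identical(res3$p_perm, res$p_perm)
  expect_identical(res$seed, 4L)
  expect_identical(res$n_perm, 1000L)

  y2 <- rnorm(12)
  r_pear <- permutation_p(x, y2, n_perm = 200, seed = 1)
  expect_true(r_pear$p_perm > 0 && r_pear$p_perm <= 1)
  expect_gte(r_pear$p_perm, 1 / 201)
})

test_that("one-sided permutation alternatives bound the two-sided p", {
  set.seed(62)
  x <- rnorm(15)
  y <- x + rnorm(15, sd = 0.8)
  two <- permutation_p(x, y, n_perm = 500, seed = 2)
  gt <- permutation_p(x, y, n_perm = 500, seed = 2, alternative = "greater")
  expect_lte(gt$p_perm, two$p_perm + 1e-12)
})

test_that("cross-prediction is self-consistent and firewalled from test outcomes", {
  exp <- synthetic_experiment(seed = 5, n_planted = 60, n_background = 150,
                              n_stims = 10)
  inc_a <- compute_incidence(exp$tract, exp$cohort_a)
  inc_b <- compute_incidence(exp$tract, exp$cohort_b)
  imp_a <- improvements(exp$cohort_a)

  # test == train reproduces the in-sample r exactly
  model <- fit_fiber_scores(inc_a, imp_a)
  sc <- aggregate_scores(inc_a, model, exp$cohort_a)
  r_in <- correlate(sc, imp_a)
  self <- cross_predict(inc_a, exp$cohort_a, inc_a, exp$cohort_a,
                        n_perm = 200, seed = 1)
  expect_equal(self$r, r_in)

  # mutating test improvements never changes the fitted t-values
  cp1 <- cross_predict(inc_a, exp$cohort_a, inc_b, exp$cohort_b,
                       n_perm = 200, seed = 1)
  mutated <- exp$cohort_b
  for (i in seq_along(mutated$records)) {
    mutated$records[[i]]$improvement_pct <- rnorm(1, 0, 100)
  }
  cp2 <- cross_predict(inc_a, exp$cohort_a, inc_b, mutated,
                       n_perm = 200, seed = 1)
  expect_identical(cp1$model$t_values, cp2$model$t_values)
  expect_identical(score_vector(cp1$scores), score_vector(cp2$scores))

  # fiber-order mismatch is rejected
  inc_sub <- compute_incidence(subset_tractogram(exp$tract, exp$tract$ids[-1]),
                               exp$cohort_b)
  expect_error(cross_predict(inc_a, exp$cohort_a, inc_sub, exp$cohort_b),
               "fiber order")
})

test_that("low/high subgroup contrast matches the hand oracle and errors sanely", {
  # groups {10,20} vs {30,40}: low minus high -> t = -2.8284...
  out <- low_high_comparison(c(1, 2, 60, 70), c(10, 20, 30, 40), cutoff = 50)
  expect_equal(out$t_statistic, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(unname(out$group_sizes), c(2L, 2L))
  ref <- stats::t.test(c(10, 20), c(30, 40), var.equal = TRUE)
  expect_equal(out$p_value, unname(ref$p.value), tolerance = 1e-12)

  expect_error(low_high_comparison(c(1, 2, 3), c(5, 6, 7), cutoff = 0.5),
               "achievable cutoff")
  same <- low_high_comparison(c(1, 1, 9, 9), c(30, 30, 30, 30), cutoff = 5)
  expect_equal(same$t_statistic, 0)
})

test_that("prediction results serialize with their scatter data", {
  set.seed(71)
  x <- rnorm(10); y <- x + rnorm(10)
  res <- permutation_p(x, y, n_perm = 200, seed = 3)
  path <- file.path(withr::local_tempdir(), "pred.json")
  write_prediction_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$r, res$r)
  expect_equal(back$p_perm, res$p_perm)
  expect_equal(back$data$improvement, y)
})
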