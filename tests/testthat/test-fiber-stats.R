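# per-fiber two-sample t-statistics and fiber selection

test_that("pooled t matches the hand-computed two-group example", {
  # improvements {10,20,30,40}; fiber connected to the {30,40} stimulations:
  # means 35 vs 15, pooled var 50 -> t = 20 / sqrt(50 * (1/2 + 1/2)) = 2.8284...
  entries <- matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4)
  inc <- incidence_matrix(entries, 1L, sprintf("s%d", 1:4))
  model <- fit_fiber_scores(inc, c(10, 20, 30, 40), min_per_group = 2)
  expect_true(model$valid[1])
  expect_equal(model$t_values[1], 2 * sqrt(2), tolerance = 1e-12)
})

test_that("vectorized t agrees with stats::t.test per fiber to 1e-10", {
  inc <- random_incidence(300, 16, seed = 21)
  set.seed(22)
  imp <- rnorm(16, mean = 30, sd = 20)
  model <- fit_fiber_scores(inc, imp, min_per_group = 2)
  dense <- incidence_dense(inc) == 1L
  for (f in seq_len(nrow(dense))) {
    n1 <- sum(dense[f, ]); n2 <- 16 - n1
    if (n1 >= 2 && n2 >= 2) {
      ref <- stats::t.test(imp[dense[f, ]], imp[!dense[f, ]], var.equal = TRUE)
      expect_true(model$valid[f])
      expect_lt(abs(model$t_values[f] - unname(ref$statistic)), 1e-10)
    } else {
      expect_false(model$valid[f])
      expect_identical(model$t_values[f], 0)
    }
  }
})

test_that("Welch option agrees with stats::t.test(var.equal = FALSE)", {
  inc <- random_incidence(100, 12, seed = 5)
  set.seed(6)
  imp <- rnorm(12, 30, 15)
  model <- fit_fiber_scores(inc, imp, var_equal = FALSE)
  dense <- incidence_dense(inc) == 1L
  for (f in which(model$valid)) {
    ref <- stats::t.test(imp[dense[f, ]], imp[!dense[f, ]], var.equal = FALSE)
    expect_lt(abs(model$t_values[f] - unname(ref$statistic)), 1e-10)
  }
})

test_that("t-values are antisymmetric in outcome sign and shift/scale free", {
  inc <- random_incidence(150, 14, seed = 9)
  set.seed(10)
  imp <- rnorm(14, 25, 18)
  m0 <- fit_fiber_scores(inc, imp)
  expect_equal(fit_fiber_scores(inc, -imp)$t_values, -m0$t_values,
               tolerance = 1e-12)
  expect_equal(fit_fiber_scores(inc, imp + 1000)$t_values, m0$t_values,
               tolerance = 1e-12)
  expect_equal(fit_fiber_scores(inc, imp * 3.7)$t_values, m0$t_values,
               tolerance = 1e-12)
})

test_that("reordering stimulations with aligned improvements changes nothing", {
  inc <- random_incidence(80, 10, seed = 13)
  set.seed(14)
  imp <- rnorm(10, 30, 20)
  perm <- sample(10)
  inc_perm <- incidence_matrix(as.matrix(inc$entries)[, perm],
                               inc$fiber_ids, inc$stim_ids[perm])
  m1 <- fit_fiber_scores(inc, imp)
  m2 <- fit_fiber_scores(inc_perm, imp[perm])
  expect_equal(m1$t_values, m2$t_values, tolerance = 1e-12)
  expect_identical(m1$valid, m2$valid)
})

test_that("degenerate groups are flagged invalid, not scored", {
  # fiber connected to ALL stimulations: unconnected group empty
  inc <- incidence_matrix(matrix(TRUE, 1, 6), 1L, sprintf("s%d", 1:6))
  m <- fit_fiber_scores(inc, c(10, 20, 30, 40, 50, 60))
  expect_false(m$valid[1])
  expect_identical(m$t_values[1], 0)

  # all-equal improvements: every fiber invalid, with a warning
  inc2 <- random_incidence(20, 8, seed = 2)
  expect_warning(m2 <- fit_fiber_scores(inc2, rep(30, 8)), "all improvements")
  expect_false(any(m2$valid))

  # zero pooled variance with unequal means: invalid with a warning
  entries <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4)
  inc3 <- incidence_matrix(entries, 1L, sprintf("s%d", 1:4))
  expect_warning(m3 <- fit_fiber_scores(inc3, c(10, 10, 40, 40)),
                 "zero pooled variance")
  expect_false(m3$valid[1])
})

test_that("signed counts track t signs and swap under outcome negation", {
  inc <- random_incidence(200, 12, seed = 17)
  set.seed(18)
  imp <- rnorm(12, 30, 20)
  m <- fit_fiber_scores(inc, imp)
  cs <- count_signed(m)
  expect_identical(unname(cs["n_positive"]), sum(m$valid & m$t_values > 0))
  expect_identical(unname(cs["n_negative"]), sum(m$valid & m$t_values < 0))
  cs_neg <- count_signed(fit_fiber_scores(inc, -imp))
  expect_identical(unname(cs_neg["n_positive"]), unname(cs["n_negative"]))
  expect_identical(unname(cs_neg["n_negative"]), unname(cs["n_positive"]))
})

test_that("top_fraction selects by |t| within sign with deterministic ties", {
  m <- structure(list(
    fiber_ids = 1:10,
    t_values = c(5, 4, 4, 3, 2, -6, -1, 0.5, 0.2, 0.1),
    n_connected = rep(5L, 10), valid = rep(TRUE, 10),
    min_per_group = 2L, n_stims = 10L, var_equal = TRUE, provenance = "test"),
    class = "fiber_score_model")
  # 9 positive fibers, fraction 0.2 -> ceiling(1.8) = 2; tie at t=4 broken by id
  expect_identical(top_fraction(m, 0.2, "positive"), c(1L, 2L))
  expect_identical(top_fraction(m, 0.4, "positive"), c(1L, 2L, 3L, 4L))
  expect_identical(top_fraction(m, 1.0, "negative"), c(6L, 7L))
  expect_identical(top_fraction(m, 0.1, "absolute"), 6L)
  m$t_values[m$t_values < 0] <- 1
  expect_warning(out <- top_fraction(m, 0.2, "negative"), "no valid fibers")
  expect_length(out, 0)
})

test_that("fiber-score models round-trip through TSV + JSON bit-identically", {
  inc <- random_incidence(60, 10, seed = 25)
  set.seed(26)
  m <- fit_fiber_scores(inc, rnorm(10, 30, 20))
  path <- file.path(withr::local_tempdir(), "scores.tsv")
  write_fiber_scores(m, path)
  back <- read_fiber_scores(path)
  expect_identical(back$t_values, m$t_values)
  expect_identical(back$valid, m$valid)
  expect_identical(back$fiber_ids, m$fiber_ids)
  expect_identical(back$min_per_group, m$min_per_group)
  expect_identical(back$n_stims, m$n_stims)
})

test_that("null outcomes yield calibrated tail rates on independent fibers", {
  # fibers connected to disjoint random stimulation subsets of one large null
  # cohort; |t| should exceed the two-sided 5% Student critical value at
  # roughly the nominal rate
  set.seed(33)
  n_stims <- 40
  n_fibers <- 600
  entries <- t(vapply(seq_len(n_fibers), function(f) {
    x <- rep(FALSE, n_stims)
    x[sample(n_stims, 20)] <- TRUE
    x
  }, logical(n_stims)))
  inc <- incidence_matrix(entries, seq_len(n_fibers), sprintf("s%d", seq_len(n_stims)))
  imp <- rnorm(n_stims)
  m <- fit_fiber_scores(inc, imp)
  crit <- qt(0.975, df = n_stims - 2)
  rate <- mean(abs(m$t_values[m$valid]) > crit)
  # fibers share the outcome vector so tests are correlated; wide 99% band
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.20)
})
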