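# planted-bundle and cohort generators

test_that("bundle generation is seed-deterministic with smooth fibers", {
  spec <- default_bundle_spec()
  spec$n_fibers <- 20L
  b1 <- make_bundle(spec, seed = 7)
  b2 <- make_bundle(spec, seed = 7)
  expect_identical(b1$streamlines, b2$streamlines)
  b3 <- make_bundle(spec, seed = 8)
  expect_false(identical(b1$streamlines, b3$streamlines))

  # vertex spacing obeys the spec step
  seg_max <- max(vapply(b1$streamlines, function(s) {
    max(sqrt(rowSums((s[-1, ] - s[-nrow(s), ])^2)))
  }, numeric(1)))
  expect_lte(seg_max, spec$step + 1e-9)

  # zero fibers and zero jitter degenerate cleanly
  spec0 <- spec; spec0$n_fibers <- 0L
  expect_equal(n_streamlines(make_bundle(spec0)), 0)
  specc <- spec; specc$radial_sd <- 0; specc$n_fibers <- 5L
  coll <- make_bundle(specc, seed = 1)
  for (i in 2:5) {
    expect_lt(max(abs(coll$streamlines[[i]] - coll$streamlines[[1]])), 1e-9)
  }
})

test_that("background fibers respect the box, length range and seed", {
  box <- rbind(c(-30, -20, -10), c(30, 20, 10))
  tr <- make_background(40, box, length_range = c(25, 50), seed = 4)
  pts <- do.call(rbind, tr$streamlines)
  expect_true(all(pts >= matrix(box[1, ], nrow(pts), 3, byrow = TRUE) - 1e-9))
  expect_true(all(pts <= matrix(box[2, ], nrow(pts), 3, byrow = TRUE) + 1e-9))
  len <- streamline_lengths(tr)
  expect_true(all(len <= 50 + 1e-6))
  expect_true(all(len >= 20))   # reflections can shorten below the draw, not much
  expect_false(identical(
    make_background(40, box, length_range = c(25, 50), seed = 5)$streamlines,
    tr$streamlines))
  expect_identical(
    make_background(40, box, length_range = c(25, 50), seed = 4)$streamlines,
    tr$streamlines)
})

test_that("cohort outcomes follow improvement = beta * overlap + noise exactly", {
  template <- synthetic_grid()
  spec <- default_bundle_spec(); spec$n_fibers <- 50L
  bundle <- make_bundle(spec, seed = 2)
  mid <- colMeans(do.call(rbind, bundle$streamlines))

  # noiseless limit: improvement == beta * overlap
  cs <- cohort_spec(n_stims = 6, center_mean = mid + c(0, 0, 3),
                    effect_beta = 100, noise_sd = 0, seed = 3)
  co <- make_cohort(cs, bundle, template)
  gt <- attr(co, "ground_truth")
  expect_equal(improvements(co), 100 * gt$table$overlap)
  expect_true(any(gt$table$overlap > 0))

  # ground truth reconstructs improvements exactly in the noisy case
  cs2 <- cohort_spec(n_stims = 8, center_mean = mid + c(0, 0, 3),
                     effect_beta = 60, noise_sd = 10, seed = 4)
  co2 <- make_cohort(cs2, bundle, template)
  gt2 <- attr(co2, "ground_truth")
  expect_equal(improvements(co2),
               gt2$effect_beta * gt2$table$overlap + gt2$table$noise)

  # centers far outside the grid region of the bundle: pure noise
  cs3 <- cohort_spec(n_stims = 5, center_mean = c(30, -30, -30),
                     center_sd = 1, effect_beta = 60, noise_sd = 10, seed = 5)
  co3 <- make_cohort(cs3, bundle, template)
  gt3 <- attr(co3, "ground_truth")
  expect_true(all(gt3$table$overlap == 0))
  expect_equal(improvements(co3), gt3$table$noise)
})

test_that("outcome variance decomposes into signal plus noise", {
  # law of total variance under the generative model:
  # Var(improvement) = beta^2 Var(overlap) + noise_sd^2, checked empirically
  # over 50 replicate cohorts around one bundle
  template <- synthetic_grid()
  spec <- default_bundle_spec(); spec$n_fibers <- 60L
  bundle <- make_bundle(spec, seed = 1)
  mid <- colMeans(do.call(rbind, bundle$streamlines))
  imp <- c(); ov <- c()
  for (rep in 1:50) {
    cs <- cohort_spec(n_stims = 20, center_mean = mid + c(0, 0, 3.5),
                      effect_beta = 60, noise_sd = 10, seed = 1000 + rep)
    co <- make_cohort(cs, bundle, template)
    imp <- c(imp, improvements(co))
    ov <- c(ov, attr(co, "ground_truth")$table$overlap)
  }
  predicted <- 60^2 * stats::var(ov) + 10^2
  expect_lt(abs(stats::var(imp) - predicted) / predicted, 0.15)
})

test_that("generated datasets round-trip through the file formats into the pipeline", {
  dir <- withr::local_tempdir()
  exp <- synthetic_experiment(seed = 6, n_planted = 40, n_background = 80,
                              n_stims = 6)
  write_tractogram(exp$tract, file.path(dir, "t.tck"))
  write_cohort(exp$cohort_a, file.path(dir, "a.csv"))
  tract2 <- read_tractogram(file.path(dir, "t.tck"))
  cohort2 <- load_cohort(file.path(dir, "a.csv"), mask_dir = dir)
  expect_identical(tract2$space, exp$tract$space)

  inc1 <- incidence_dense(compute_incidence(exp$tract, exp$cohort_a))
  inc2 <- incidence_dense(compute_incidence(tract2, cohort2))
  expect_identical(inc2, inc1)
  expect_equal(improvements(cohort2), improvements(exp$cohort_a))
})

test_that("the two default cohorts stimulate overlapping but distinct fiber sets", {
  exp <- synthetic_experiment(seed = 2, n_planted = 80, n_background = 200,
                              n_stims = 12)
  inc_a <- compute_incidence(exp$tract, exp$cohort_a)
  inc_b <- compute_incidence(exp$tract, exp$cohort_b)
  set_a <- which(Matrix::rowSums(inc_a$entries) > 0)
  set_b <- which(Matrix::rowSums(inc_b$entries) > 0)
  jaccard <- length(intersect(set_a, set_b)) / length(union(set_a, set_b))
  expect_gt(jaccard, 0)
  expect_lt(jaccard, 1)
})

test_that("the fixture writer emits a complete miniature dataset", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_dataset(dir, seed = 1)
  expect_true(all(file.exists(unlist(paths))))
  tr <- read_tractogram(paths$tractogram)
  expect_equal(n_streamlines(tr), 200)
  co <- load_cohort(paths$cohort, mask_dir = dir)
  expect_equal(length(co), 6)
  gt <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  expect_equal(gt$effect_beta * gt$table$overlap + gt$table$noise,
               improvements(co), tolerance = 1e-8)
})
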