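# Synthetic connectome + cohort generator. Plants a coherent fiber bundle in
# incoherent background and simulates stimulation cohorts whose percent
# improvement is a noisy linear function of each stimulation sphere's overlap
# with the planted bundle:
#     improvement = effect_beta * overlap_fraction + N(0, noise_sd^2)
# This is the generative model the discriminative fiber analysis assumes, so
# every pipeline stage is testable with known ground truth and no download.

#' Specification of a planted bundle
#'
#' @param waypoints matrix (>= 2 x 3) of control coordinates in mm; a smooth
#'   centerline is interpolated through them.
#' @param n_fibers number of fibers, >= 0.
#' @param radial_sd per-fiber Gaussian radial displacement (mm) around the
#'   centerline, varying smoothly along the arc; 0 collapses all fibers onto
#'   the centerline.
#' @param step maximum vertex spacing in mm, > 0.
#' @param label bundle name.
#' @return a `bundle_spec` list.
#' @export
bundle_spec <- function(waypoints, n_fibers = 200L, radial_sd = 2, step = 1,
                        label = "bundle") {
  assert_points_matrix(waypoints, "waypoints")
  if (nrow(waypoints) < 2) stopf("waypoints needs at least 2 control points")
  if (!is_count(n_fibers)) stopf("n_fibers must be a nonnegative integer")
  if (!is.numeric(radial_sd) || radial_sd < 0) stopf("radial_sd must be >= 0")
  if (!is.numeric(step) || step <= 0) stopf("step must be > 0")
  structure(list(waypoints = waypoints, n_fibers = as.integer(n_fibers),
                 radial_sd = radial_sd, step = step, label = label),
            class = "bundle_spec")
}

#' Default bundle geometry
#'
#' A gently curved ~62 mm centerline running along the x axis inside the
#' default [synthetic_grid()], loosely evoking a capsular tract's anterior-
#' posterior course.
#' @return a [bundle_spec()].
#' @export
default_bundle_spec <- function() {
  bundle_spec(rbind(c(-30, 0, 0), c(-10, 3, 4), c(10, 6, 2), c(30, 10, 0)),
              n_fibers = 200L, radial_sd = 2, step = 1, label = "planted")
}

# smooth centerline through waypoints at vertex spacing <= step
bundle_centerline <- function(waypoints, step) {
  d <- sqrt(rowSums((waypoints[-1, , drop = FALSE] -
                       waypoints[-nrow(waypoints), , drop = FALSE])^2))
  u <- c(0, cumsum(d))
  total <- u[length(u)]
  n_out <- max(2L, as.integer(ceiling(total / (step / 2))) + 1L)
  uu <- seq(0, total, length.out = n_out)
  if (nrow(waypoints) == 2) {
    sapply(1:3, function(k) stats::approx(u, waypoints[, k], xout = uu)$y)
  } else {
    sapply(1:3, function(k) stats::spline(u, waypoints[, k], xout = uu,
                                          method = "natural")$y)
  }
}

#' Generate a planted bundle
#'
#' Each fiber is the centerline plus a per-fiber Gaussian radial offset
#' (sd = `radial_sd`) drawn at a few knots along the arc and interpolated
#' smoothly, then resampled to the spec's vertex spacing. Draws come from
#' per-fiber substreams of `seed`, so coordinates are bit-identical for a
#' given seed regardless of draw order.
#'
#' @param spec a [bundle_spec()].
#' @param seed integer seed.
#' @param space space label of the output.
#' @param id_offset IDs are `id_offset + 1:n_fibers`.
#' @return a [tractogram()].
#' @export
make_bundle <- function(spec, seed = 1, space = "synthetic", id_offset = 0L) {
  stopifnot(inherits(spec, "bundle_spec"))
  if (spec$n_fibers == 0) {
    return(tractogram(list(), ids = integer(0), space = space))
  }
  center <- bundle_centerline(spec$waypoints, spec$step)
  n_pts <- nrow(center)
  u <- seq(0, 1, length.out = n_pts)
  knots <- seq(0, 1, length.out = 4)
  streamlines <- lapply(seq_len(spec$n_fibers), function(i) {
    off <- with_seed(substream_seed(seed, i), {
      matrix(stats::rnorm(length(knots) * 3, sd = spec$radial_sd), ncol = 3)
    })
    disp <- sapply(1:3, function(k) {
      stats::spline(knots, off[, k], xout = u, method = "natural")$y
    })
    resample_streamline(center + disp, spec$step)
  })
  tractogram(streamlines, ids = id_offset + seq_len(spec$n_fibers), space = space)
}

#' Generate incoherent background fibers
#'
#' Correlated random walks: each fiber starts at a uniform point in the box
#' with a random direction; at every step the direction is a convex blend of
#' the previous direction (weight `smoothness`) and a fresh uniform random
#' unit vector, renormalized. Walks reflect off the box walls, so all
#' vertices stay inside. Arc length is drawn uniformly from `length_range`.
#' This is the stand-in for the non-predictive bulk of a normative
#' connectome.
#'
#' @param n_fibers number of fibers, >= 0.
#' @param bounding_box 2 x 3 matrix: row 1 lower corner, row 2 upper corner.
#' @param length_range arc length range in mm (lo, hi).
#' @param smoothness momentum in [0, 1); higher = straighter fibers.
#' @param step vertex spacing in mm.
#' @param seed integer seed.
#' @param space,id_offset as in [make_bundle()].
#' @return a [tractogram()].
#' @export
make_background <- function(n_fibers, bounding_box, length_range = c(40, 80),
                            smoothness = 0.85, step = 1, seed = 1,
                            space = "synthetic", id_offset = 0L) {
  if (!is_count(n_fibers)) stopf("n_fibers must be a nonnegative integer")
  stopifnot(is.matrix(bounding_box), all(dim(bounding_box) == c(2, 3)))
  if (any(bounding_box[2, ] <= bounding_box[1, ])) stopf("bounding box is degenerate")
  stopifnot(length(length_range) == 2, length_range[1] > 0,
            length_range[2] >= length_range[1],
            smoothness >= 0, smoothness < 1, step > 0)
  if (n_fibers == 0) return(tractogram(list(), ids = integer(0), space = space))
  lo <- bounding_box[1, ]; hi <- bounding_box[2, ]
  rand_unit <- function() {
    repeat {
      v <- stats::rnorm(3)
      n <- sqrt(sum(v^2))
      if (n > 1e-8) return(v / n)
    }
  }
  streamlines <- lapply(seq_len(n_fibers), function(i) {
    with_seed(substream_seed(seed, 100000 + i), {
      len <- stats::runif(1, length_range[1], length_range[2])
      n_steps <- max(1L, as.integer(round(len / step)))
      pos <- lo + stats::runif(3) * (hi - lo)
      dir <- rand_unit()
      pts <- matrix(0, n_steps + 1L, 3)
      pts[1, ] <- pos
      for (s in seq_len(n_steps)) {
        dir <- smoothness * dir + (1 - smoothness) * rand_unit()
        dir <- dir / sqrt(sum(dir^2))
        nxt <- pos + step * dir
        # reflect at the walls
        for (k in 1:3) {
          if (nxt[k] < lo[k]) { nxt[k] <- 2 * lo[k] - nxt[k]; dir[k] <- -dir[k] }
          if (nxt[k] > hi[k]) { nxt[k] <- 2 * hi[k] - nxt[k]; dir[k] <- -dir[k] }
          nxt[k] <- min(max(nxt[k], lo[k]), hi[k])
        }
        pos <- nxt
        pts[s + 1L, ] <- pos
      }
      pts
    })
  })
  tractogram(streamlines, ids = id_offset + seq_len(n_fibers), space = space)
}

#' Default synthetic voxel grid
#'
#' 81 x 81 x 81 voxels of 1 mm covering world coordinates -40..40 mm on each
#' axis, mimicking a subcortical field of view at typical VTA-model
#' resolution.
#' @return an all-zero [mask_volume()].
#' @export
synthetic_grid <- function() {
  mask_grid(c(81, 81, 81), voxel_size = 1, origin = c(-40, -40, -40))
}

#' Specification of a simulated stimulation cohort
#'
#' @param n_stims number of stimulations (one per simulated patient).
#' @param center_mean,center_sd mean (length 3, mm) and spread (scalar or
#'   length 3, mm) of the Gaussian distribution of stimulation centers.
#' @param radius_map strictly increasing function mapping amplitude to
#'   sphere radius in mm; default `1.5 + 0.6 * amplitude`, landing in the
#'   2.7-4.5 mm range typical of clinical VTA models at 2-5 V.
#' @param amplitude_range uniform amplitude range (lo, hi), lo > 0; in volts.
#' @param effect_beta improvement units per unit overlap fraction.
#' @param noise_sd additive Gaussian outcome noise, improvement units.
#' @param seed integer seed.
#' @param name cohort name.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_stims = 20L, center_mean, center_sd = c(8, 3, 3),
                        radius_map = function(a) 1.5 + 0.6 * a,
                        amplitude_range = c(2, 5), effect_beta = 60,
                        noise_sd = 10, seed = 1, name = "synthetic_cohort") {
  if (!is_count(n_stims) || n_stims < 1) stopf("n_stims must be a positive integer")
  stopifnot(length(center_mean) == 3, all(is.finite(center_mean)))
  center_sd <- rep_len(as.numeric(center_sd), 3)
  stopifnot(all(center_sd >= 0))
  stopifnot(is.function(radius_map))
  stopifnot(length(amplitude_range) == 2, amplitude_range[1] > 0,
            amplitude_range[2] >= amplitude_range[1])
  if (radius_map(amplitude_range[2]) <= radius_map(amplitude_range[1]) &&
      amplitude_range[2] > amplitude_range[1]) {
    stopf("radius_map must be strictly increasing over the amplitude range")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_stims = as.integer(n_stims), center_mean = as.numeric(center_mean),
                 center_sd = center_sd, radius_map = radius_map,
                 amplitude_range = as.numeric(amplitude_range),
                 effect_beta = effect_beta, noise_sd = noise_sd,
                 seed = as.integer(seed), name = name),
            class = "cohort_spec")
}

#' Simulate a stimulation cohort around a planted bundle
#'
#' For each stimulation: a center is drawn from the spec's Gaussian, an
#' amplitude from its uniform range, a sphere of radius `radius_map(amplitude)`
#' is voxelized on the template grid, the overlap fraction `o` = (planted
#' fibers intersecting the sphere) / (planted fiber count) is computed, and
#' the outcome is `improvement = effect_beta * o + N(0, noise_sd^2)`.
#' All draws flow from per-stimulation substreams of `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param bundle the planted-bundle [tractogram()] (ground-truth fibers only).
#' @param template a [mask_volume()] grid template.
#' @return a [cohort_table()] with a `ground_truth` attribute: a list with
#'   the per-stimulation draw table (center, amplitude, radius, overlap,
#'   noise, improvement), `effect_beta`, `noise_sd`, `planted_ids` and
#'   `seed` — sufficient to recompute every improvement exactly.
#' @export
make_cohort <- function(spec, bundle, template) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(bundle, "tractogram"),
            inherits(template, "mask_volume"))
  if (length(bundle$streamlines) == 0) stopf("bundle is empty")
  max_step <- min(voxel_edges(template)) / 2
  res <- lapply(bundle$streamlines, resample_streamline, max_step = max_step)
  npts <- vapply(res, nrow, integer(1))
  pts <- do.call(rbind, res)
  fidx <- rep.int(seq_along(res), npts)

  records <- vector("list", spec$n_stims)
  gt <- data.frame(stim_id = character(spec$n_stims), cx = 0, cy = 0, cz = 0,
                   amplitude = 0, radius = 0, overlap = 0, noise = 0,
                   improvement = 0, stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_stims)) {
    draws <- with_seed(substream_seed(spec$seed, i), {
      list(center = spec$center_mean + stats::rnorm(3) * spec$center_sd,
           amplitude = stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2]),
           noise = stats::rnorm(1, 0, spec$noise_sd))
    })
    radius <- spec$radius_map(draws$amplitude)
    mask <- sphere_mask(draws$center, radius, template)
    hit <- mask_contains(mask, pts)
    o <- length(unique(fidx[hit])) / length(res)
    improvement <- spec$effect_beta * o + draws$noise
    stim_id <- sprintf("%s_s%02d", spec$name, i)
    records[[i]] <- stimulation_record(
      stim_id = stim_id, patient_id = sprintf("%s_p%02d", spec$name, i),
      cohort = spec$name, masks = list(mask), amplitude = draws$amplitude,
      improvement_pct = improvement)
    gt[i, ] <- list(stim_id, draws$center[1], draws$center[2], draws$center[3],
                    draws$amplitude, radius, o, draws$noise, improvement)
  }
  cohort <- cohort_table(records, name = spec$name, space = bundle$space)
  attr(cohort, "ground_truth") <- list(table = gt,
                                       effect_beta = spec$effect_beta,
                                       noise_sd = spec$noise_sd,
                                       planted_ids = bundle$ids,
                                       seed = spec$seed)
  cohort
}

#' The default two-cohort planted-bundle experiment
#'
#' Builds the study conditions used throughout the package's tests: a planted
#' bundle of `n_planted` fibers plus `n_background` incoherent fibers in the
#' default grid, and two cohorts of `n_stims` stimulations whose centers sit
#' on different sides of the bundle — cohort A dorsal (+z offset), cohort B
#' lateral (+y offset) — mimicking two surgical targets stimulating one tract
#' from different approaches. Outcomes follow
#' `improvement = effect_beta * overlap + N(0, noise_sd^2)`.
#'
#' @param seed master seed; bundle, background and the two cohorts use
#'   distinct substreams of it.
#' @param n_planted,n_background fiber counts.
#' @param n_stims stimulations per cohort.
#' @param effect_beta,noise_sd outcome model parameters.
#' @return list with `tract` (planted + background, planted IDs first),
#'   `bundle`, `planted_ids`, `cohort_a`, `cohort_b`, `template`.
#' @export
synthetic_experiment <- function(seed = 1, n_planted = 200L, n_background = 2000L,
                                 n_stims = 20L, effect_beta = 60, noise_sd = 10) {
  template <- synthetic_grid()
  bspec <- default_bundle_spec()
  bspec$n_fibers <- as.integer(n_planted)
  bundle <- make_bundle(bspec, seed = substream_seed(seed, 1))
  background <- make_background(n_background,
                                bounding_box = rbind(c(-40, -40, -40), c(40, 40, 40)),
                                seed = substream_seed(seed, 2),
                                id_offset = n_planted)
  tract <- if (n_background > 0) bind_tractograms(bundle, background) else bundle
  mid <- colMeans(bundle_centerline(bspec$waypoints, bspec$step))
  spec_a <- cohort_spec(n_stims = n_stims, center_mean = mid + c(0, 0, 3.5),
                        effect_beta = effect_beta, noise_sd = noise_sd,
                        seed = substream_seed(seed, 3), name = "cohort_a")
  spec_b <- cohort_spec(n_stims = n_stims, center_mean = mid + c(0, 3.5, 0),
                        effect_beta = effect_beta, noise_sd = noise_sd,
                        seed = substream_seed(seed, 4), name = "cohort_b")
  list(tract = tract, bundle = bundle, planted_ids = bundle$ids,
       cohort_a = make_cohort(spec_a, bundle, template),
       cohort_b = make_cohort(spec_b, bundle, template),
       template = template)
}

#' Write a miniature fixture dataset
#'
#' 200 fibers (150 planted + 50 background) and one cohort of 6 stimulations,
#' written as TCK + NIfTI masks + cohort CSV + a ground-truth JSON sidecar.
#' Everything re-enters the pipeline through [read_tractogram()] and
#' [load_cohort()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, a list of the written paths.
#' @export
write_fixture_dataset <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  template <- synthetic_grid()
  bspec <- default_bundle_spec()
  bspec$n_fibers <- 150L
  bundle <- make_bundle(bspec, seed = substream_seed(seed, 1))
  background <- make_background(50L, rbind(c(-40, -40, -40), c(40, 40, 40)),
                                seed = substream_seed(seed, 2), id_offset = 150L)
  tract <- bind_tractograms(bundle, background)
  mid <- colMeans(bundle_centerline(bspec$waypoints, bspec$step))
  spec <- cohort_spec(n_stims = 6L, center_mean = mid + c(0, 0, 3.5),
                      seed = substream_seed(seed, 3), name = "fixture")
  cohort <- make_cohort(spec, bundle, template)
  gt <- attr(cohort, "ground_truth")

  tract_path <- file.path(dir, "tract.tck")
  write_tractogram(tract, tract_path, dialect = "tck")
  csv_path <- file.path(dir, "cohort.csv")
  write_cohort(cohort, csv_path)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(tractogram = tract_path, cohort = csv_path, ground_truth = gt_path))
}
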