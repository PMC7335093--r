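#' Literature-defined OCD DBS targets
#'
#' The eleven stereotactic targets reported across the OCD-DBS literature,
#' with their published MNI coordinates (x printed as a +/- pair, one per
#' hemisphere) and, where available, the reported mean percent Y-BOCS
#' improvement. Three thalamic rows (MD, VA, iml) stem from one study and
#' share one reported improvement; they are retained as separate points.
#' Targets without a reported improvement (amGPi, NAcc, BNST) carry `NA` and
#' are excluded from correlations.
#'
#' @return data.frame with columns `name`, `mni_x` (unsigned magnitude;
#'   expand with [expand_hemispheres()]), `mni_y`, `mni_z`,
#'   `improvement_pct`, `n_patients`, `target_type`.
#' @export
builtin_targets <- function() {
  data.frame(
    name = c("STN", "amGPi", "VC/VS", "slMFB", "NAcc", "ALIC",
             "MD", "VA", "iml", "ITP", "BNST"),
    mni_x = c(11.30, 15.66, 7.92, 8.35, 6.98, 13.84,
              5.10, 7.52, 6.36, 6.92, 6.33),
    mni_y = c(-9.90, -1.41, 5.51, -13.64, 3.69, 5.17,
              -18.17, -12.68, -13.99, -1.84, 1.39),
    mni_z = c(-7.81, -8.22, -9.01, -7.00, -10.55, -5.04,
              2.59, 5.60, 4.85, -5.13, -4.87),
    improvement_pct = c(32.1, NA, 7.7, 41.7, NA, 38.7,
                        10.7, 10.7, 10.7, 52.0, NA),
    n_patients = c(8L, 4L, 1L, 2L, 4L, 6L, 4L, 4L, 4L, 5L, 4L),
    target_type = c("tip of the electrode", "tip of the electrode",
                    "tip of the electrode", "active contacts",
                    "tip of the electrode", "tip of the electrode",
                    "active contacts", "active contacts", "active contacts",
                    "tip of the electrode", "tip of the electrode"),
    stringsAsFactors = FALSE
  )
}

#' Expand bilateral targets to one row per hemisphere
#'
#' @param targets a data.frame as returned by [builtin_targets()].
#' @return the same frame with twice the rows, a `side` column
#'   (`"L"`/`"R"`), and `mni_x` signed (negative = left).
#' @export
expand_hemispheres <- function(targets) {
  stopifnot(all(c("name", "mni_x", "mni_y", "mni_z") %in% names(targets)))
  left <- targets
  left$mni_x <- -abs(targets$mni_x)
  left$side <- "L"
  right <- targets
  right$mni_x <- abs(targets$mni_x)
  right$side <- "R"
  out <- rbind(right, left)
  out[order(match(out$name, targets$name)), , drop = FALSE]
}

#' Build a spherical stimulation proxy at a coordinate
#'
#' A binary sphere of `radius` mm voxelized on the template grid, wrapped in
#' a [stimulation_record()] with amplitude 1 so amplitude normalization is a
#' no-op. This is the declared stand-in for the stimulation field around a
#' published target coordinate.
#'
#' @param center world mm coordinate (length 3), inside the grid.
#' @param radius sphere radius in mm, > 0.
#' @param template a [mask_volume()] grid template.
#' @param stim_id,cohort identifiers for the resulting record.
#' @param improvement_pct reported improvement to attach, or `NA`.
#' @return a [stimulation_record()].
#' @export
sphere_stimulation <- function(center, radius, template, stim_id = "sphere",
                               cohort = "literature", improvement_pct = NA_real_) {
  mask <- sphere_mask(center, radius, template)   # errors if center outside grid
  stimulation_record(stim_id = stim_id, patient_id = stim_id, cohort = cohort,
                     masks = list(mask), amplitude = 1,
                     improvement_pct = if (is.finite(improvement_pct)) improvement_pct else NULL)
}

#' Score literature targets against a fitted tract model
#'
#' For every target, a bilateral pair of spheres at the (+/-x) MNI
#' coordinates is built on the template grid; the weighted overlap of the
#' target with the fitted tract is the aggregate fiber T-score of that
#' sphere pair (left + right OR-combined, amplitude 1). Targets with a
#' reported improvement are then correlated with their overlaps and a
#' permutation p is attached; targets without a reported improvement are
#' scored but excluded from the correlation.
#'
#' @param targets data.frame as from [builtin_targets()] (unsigned `mni_x`).
#' @param tract the [tractogram()] the model is indexed against.
#' @param model a [fiber_score_model()].
#' @param template a [mask_volume()] grid template covering the coordinates.
#' @param radius sphere radius in mm (default 3).
#' @inheritParams permutation_p
#' @param max_step resampling step for connectivity (default: half the
#'   template's smallest voxel edge).
#' @return a `prediction_result` over the targets with known improvement,
#'   with the full per-target overlap table (all rows, including `NA`
#'   improvements) attached as `$target_scores`.
#' @export
score_literature_targets <- function(targets, tract, model, template,
                                     radius = 3, n_perm = 1000, seed = 1,
                                     method = c("pearson", "spearman"),
                                     max_step = NULL) {
  stopifnot(inherits(tract, "tractogram"), inherits(model, "fiber_score_model"),
            inherits(template, "mask_volume"))
  if (!identical(tract$ids, model$fiber_ids)) {
    stopf("model fiber order does not match the tractogram")
  }
  records <- lapply(seq_len(nrow(targets)), function(i) {
    row <- targets[i, ]
    masks <- list(
      sphere_mask(c(abs(row$mni_x), row$mni_y, row$mni_z), radius, template),
      sphere_mask(c(-abs(row$mni_x), row$mni_y, row$mni_z), radius, template)
    )
    stimulation_record(stim_id = row$name, patient_id = row$name,
                       cohort = "literature", masks = masks, amplitude = 1,
                       improvement_pct = row$improvement_pct)
  })
  cohort <- cohort_table(records, name = "literature", space = tract$space)
  inc <- compute_incidence(tract, cohort, max_step = max_step)
  sc <- aggregate_scores(inc, model, cohort)
  imp <- improvements(cohort)
  known <- is.finite(imp)
  if (sum(known) < 3) stopf("fewer than 3 targets carry a reported improvement")
  res <- permutation_p(sc$score[known], imp[known], n_perm = n_perm,
                       seed = seed, method = match.arg(method))
  res$target_scores <- data.frame(name = targets$name,
                                  overlap_score = sc$score,
                                  improvement_pct = imp,
                                  stringsAsFactors = FALSE)
  res
}

#' Export targets as CSV and as a sphere-per-target NIfTI label volume
#'
#' @param targets data.frame as from [builtin_targets()].
#' @param csv_path output CSV path (`NULL` to skip).
#' @param nifti_path output NIfTI path (`NULL` to skip); voxels of the i-th
#'   target's bilateral spheres receive label i.
#' @param template,radius grid and sphere radius for the label volume.
#' @return invisibly, a list of the written paths.
#' @export
export_targets <- function(targets, csv_path = NULL, nifti_path = NULL,
                           template = NULL, radius = 3) {
  if (!is.null(csv_path)) {
    utils::write.csv(targets, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(nifti_path)) {
    stopifnot(inherits(template, "mask_volume"))
    lab <- array(0L, dim = dim(template$data))
    for (i in seq_len(nrow(targets))) {
      row <- targets[i, ]
      for (sgn in c(1, -1)) {
        sm <- sphere_mask(c(sgn * abs(row$mni_x), row$mni_y, row$mni_z),
                          radius, template)
        lab[sm$data == 1L] <- i
      }
    }
    img <- RNifti::asNifti(lab)
    RNifti::sform(img) <- structure(template$affine, code = 2L)
    RNifti::writeNifti(img, nifti_path)
  }
  invisible(list(csv = csv_path, nifti = nifti_path))
}
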