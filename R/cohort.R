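#' Construct a stimulation record
#'
#' One stimulation setting: one or more binary volumes (one per active
#' electrode/hemisphere), the total stimulation amplitude, and the clinical
#' outcome. The outcome variable is percent Y-BOCS improvement,
#' `100 * (baseline - postop) / baseline`; it is signed and unclamped, so a
#' worsening patient carries a negative value.
#'
#' @param stim_id unique stimulation identifier.
#' @param patient_id patient identifier (several records may share one
#'   patient, e.g. one per activated contact pair).
#' @param cohort cohort label.
#' @param masks list of [mask_volume()] objects (may be empty for
#'   bookkeeping-only tables).
#' @param amplitude total stimulation amplitude (volts or milliamps), > 0.
#' @param baseline_ybocs,postop_ybocs Y-BOCS scores (>= 0), or `NA`.
#' @param improvement_pct percent improvement; derived from the scores when
#'   `NULL`/`NA`. When both the scores and the value are supplied they must
#'   agree to 1e-9.
#' @return an object of class `stimulation_record`.
#' @export
stimulation_record <- function(stim_id, patient_id, cohort, masks = list(),
                               amplitude, baseline_ybocs = NA_real_,
                               postop_ybocs = NA_real_, improvement_pct = NULL) {
  stopifnot(is.list(masks))
  for (m in masks) stopifnot(inherits(m, "mask_volume"))
  amplitude <- as.numeric(amplitude)
  if (!is.finite(amplitude) || amplitude <= 0) {
    stopf("record '%s': amplitude must be a positive number", stim_id)
  }
  baseline_ybocs <- as.numeric(baseline_ybocs)
  postop_ybocs <- as.numeric(postop_ybocs)
  if (is.finite(baseline_ybocs) && baseline_ybocs < 0) stopf("record '%s': baseline_ybocs < 0", stim_id)
  if (is.finite(postop_ybocs) && postop_ybocs < 0) stopf("record '%s': postop_ybocs < 0", stim_id)
  derived <- if (is.finite(baseline_ybocs) && is.finite(postop_ybocs)) {
    if (baseline_ybocs == 0) stopf("record '%s': baseline Y-BOCS is 0; percent improvement undefined", stim_id)
    100 * (baseline_ybocs - postop_ybocs) / baseline_ybocs
  } else NA_real_
  if (is.null(improvement_pct) || !is.finite(as.numeric(improvement_pct))) {
    improvement_pct <- derived
  } else {
    improvement_pct <- as.numeric(improvement_pct)
    if (is.finite(derived) && abs(improvement_pct - derived) > 1e-9) {
      stopf("record '%s': improvement_pct (%.6f) disagrees with 100*(baseline-postop)/baseline (%.6f)",
            stim_id, improvement_pct, derived)
    }
  }
  structure(list(stim_id = as.character(stim_id),
                 patient_id = as.character(patient_id),
                 cohort = as.character(cohort),
                 masks = masks,
                 amplitude = amplitude,
                 baseline_ybocs = baseline_ybocs,
                 postop_ybocs = postop_ybocs,
                 improvement_pct = improvement_pct),
            class = "stimulation_record")
}

#' Construct a cohort table
#'
#' @param records list of [stimulation_record()] objects with unique
#'   `stim_id`s.
#' @param name cohort name.
#' @param space space label shared by all the records' masks and any
#'   tractogram the cohort is analysed against.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(records, name = "cohort", space = "synthetic") {
  stopifnot(is.list(records))
  for (r in records) stopifnot(inherits(r, "stimulation_record"))
  ids <- vapply(records, function(r) r$stim_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate stim_ids in cohort '%s': %s", name,
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records, name = name, space = space),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table '%s': %d stimulations, %d patients, space '%s'\n",
              x$name, length(x$records),
              length(unique(vapply(x$records, function(r) r$patient_id, character(1)))),
              x$space))
  invisible(x)
}

#' @export
length.cohort_table <- function(x) length(x$records)

#' Per-stimulation field accessors
#' @param cohort a [cohort_table()].
#' @return numeric (or character) vector aligned with the record order.
#' @export
improvements <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  vapply(cohort$records, function(r) r$improvement_pct, numeric(1))
}

#' @rdname improvements
#' @export
amplitudes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  vapply(cohort$records, function(r) r$amplitude, numeric(1))
}

#' @rdname improvements
#' @export
stim_ids <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  vapply(cohort$records, function(r) r$stim_id, character(1))
}

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  data.frame(
    stim_id = stim_ids(x),
    patient_id = vapply(x$records, function(r) r$patient_id, character(1)),
    cohort = vapply(x$records, function(r) r$cohort, character(1)),
    amplitude = amplitudes(x),
    baseline_ybocs = vapply(x$records, function(r) r$baseline_ybocs, numeric(1)),
    postop_ybocs = vapply(x$records, function(r) r$postop_ybocs, numeric(1)),
    improvement_pct = improvements(x),
    n_masks = vapply(x$records, function(r) length(r$masks), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Load a cohort table from CSV
#'
#' Required columns: `stim_id`, `patient_id`, `cohort`, `amplitude`, and
#' either `improvement_pct` or both `baseline_ybocs` and `postop_ybocs`.
#' An optional `mask_paths` column holds ';'-separated NIfTI paths relative
#' to `mask_dir`; when present and nonempty every referenced mask is loaded.
#' The CSV dialect is fixed: comma separator, '.' decimal point, UTF-8,
#' mandatory header row.
#'
#' @param csv_path path to the cohort CSV.
#' @param mask_dir directory the `mask_paths` entries are relative to;
#'   `NULL` allows only records without masks.
#' @param name cohort name (default: file name without extension).
#' @param space space label for the cohort.
#' @return a [cohort_table()].
#' @export
load_cohort <- function(csv_path, mask_dir = NULL, name = NULL, space = "synthetic") {
  if (!file.exists(csv_path)) stopf("cohort CSV not found: %s", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("stim_id", "patient_id", "cohort", "amplitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) stopf("cohort CSV %s lacks required columns: %s",
                                  csv_path, paste(missing_cols, collapse = ", "))
  has_imp <- "improvement_pct" %in% names(df)
  has_scores <- all(c("baseline_ybocs", "postop_ybocs") %in% names(df))
  if (!has_imp && !has_scores) {
    stopf("cohort CSV %s needs either improvement_pct or baseline_ybocs+postop_ybocs", csv_path)
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    masks <- list()
    if ("mask_paths" %in% names(df) && !is.na(row$mask_paths) && nzchar(row$mask_paths)) {
      rels <- strsplit(row$mask_paths, ";", fixed = TRUE)[[1]]
      masks <- lapply(rels, function(rel) {
        p <- if (is.null(mask_dir)) rel else file.path(mask_dir, rel)
        if (!file.exists(p)) stopf("record '%s': mask file not found: %s", row$stim_id, p)
        read_mask(p)
      })
    }
    stimulation_record(
      stim_id = row$stim_id, patient_id = row$patient_id, cohort = row$cohort,
      masks = masks, amplitude = row$amplitude,
      baseline_ybocs = if (has_scores) row$baseline_ybocs else NA_real_,
      postop_ybocs = if (has_scores) row$postop_ybocs else NA_real_,
      improvement_pct = if (has_imp) row$improvement_pct else NULL
    )
  })
  cohort_table(records, name = name %||% tools::file_path_sans_ext(basename(csv_path)),
               space = space)
}

#' Write a cohort table to CSV
#'
#' Masks are written as NIfTI files next to the CSV (under
#' `<stem>_masks/`) and referenced through the `mask_paths` column, so the
#' table round-trips through [load_cohort()].
#'
#' @param cohort a [cohort_table()].
#' @param csv_path output CSV path.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(cohort, csv_path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  df$n_masks <- NULL
  stem <- tools::file_path_sans_ext(basename(csv_path))
  mask_dir <- file.path(dirname(csv_path), paste0(stem, "_masks"))
  mask_paths <- character(length(cohort$records))
  for (i in seq_along(cohort$records)) {
    r <- cohort$records[[i]]
    if (length(r$masks)) {
      if (!dir.exists(mask_dir)) dir.create(mask_dir, recursive = TRUE)
      rels <- sprintf("%s_mask%02d.nii.gz", r$stim_id, seq_along(r$masks))
      for (j in seq_along(r$masks)) write_mask(r$masks[[j]], file.path(mask_dir, rels[j]))
      mask_paths[i] <- paste(file.path(paste0(stem, "_masks"), rels), collapse = ";")
    }
  }
  df$mask_paths <- mask_paths
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}
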