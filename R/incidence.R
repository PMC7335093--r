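#' Resample a streamline to a maximum step length
#'
#' Subdivides every segment longer than `max_step` into equal parts so that no
#' two consecutive vertices are more than `max_step` mm apart. Original
#' vertices are preserved, the geometric path (and hence arc length) is
#' unchanged, and a polyline already satisfying the bound is returned as-is.
#' This guarantees that connectivity testing against a voxel grid cannot skip
#' a volume between vertices.
#'
#' @param points numeric matrix (n x 3) of vertices in mm, n >= 2.
#' @param max_step maximum allowed segment length in mm, > 0.
#' @return resampled vertex matrix.
#' @export
resample_streamline <- function(points, max_step) {
  assert_points_matrix(points)
  if (!is.numeric(max_step) || length(max_step) != 1 || max_step <= 0) {
    stopf("max_step must be a single positive length in mm")
  }
  n <- nrow(points)
  seg <- points[-1, , drop = FALSE] - points[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (all(len <= max_step)) return(points)
  nsub <- pmax(1L, as.integer(ceiling(len / max_step - 1e-12)))
  total <- sum(nsub) + 1L
  out <- matrix(0, total, 3)
  pos <- 1L
  for (i in seq_len(n - 1)) {
    k <- nsub[i]
    frac <- seq_len(k) / k
    out[pos, ] <- points[i, ]
    if (k > 1) {
      out[(pos + 1):(pos + k - 1), ] <-
        matrix(points[i, ], k - 1, 3, byrow = TRUE) + outer(frac[-k], seg[i, ])
    }
    pos <- pos + k
  }
  out[total, ] <- points[n, ]
  out
}

#' Construct an incidence matrix
#'
#' @param entries binary fiber x stimulation matrix (base logical matrix or a
#'   sparse `Matrix` pattern/logical matrix).
#' @param fiber_ids,stim_ids ordered row/column labels.
#' @return an object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(entries, fiber_ids, stim_ids) {
  if (nrow(entries) != length(fiber_ids) || ncol(entries) != length(stim_ids)) {
    stopf("entries dimensions (%d x %d) do not match label counts (%d fibers, %d stims)",
          nrow(entries), ncol(entries), length(fiber_ids), length(stim_ids))
  }
  if (anyDuplicated(fiber_ids)) stopf("fiber_ids must be unique")
  if (anyDuplicated(stim_ids)) stopf("stim_ids must be unique")
  entries <- methods::as(methods::as(Matrix::Matrix(entries, sparse = TRUE), "lMatrix"), "CsparseMatrix")
  structure(list(entries = entries,
                 fiber_ids = as.integer(fiber_ids),
                 stim_ids = as.character(stim_ids)),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d fibers x %d stimulations, %d connected pairs\n",
              length(x$fiber_ids), length(x$stim_ids), Matrix::nnzero(x$entries)))
  invisible(x)
}

#' Fiber-stimulation connectivity
#'
#' Decides, for every (fiber, stimulation) pair, whether the fiber is
#' connected to the stimulation volume: entry (f, s) is 1 iff at least one
#' vertex of fiber f, after resampling to `max_step`, falls inside a support
#' voxel of ANY mask of stimulation s (multiple masks per stimulation —
#' bilateral electrodes — are OR-combined). Voxel membership is
#' nearest-voxel rounding of the inverse-affine image of the vertex.
#'
#' @param tract a [tractogram()].
#' @param cohort a [cohort_table()] whose `space` matches the tractogram's.
#' @param max_step resampling step in mm; default (and enforced maximum) is
#'   half the smallest voxel edge over all masks, so no voxel can be skipped
#'   between vertices.
#' @return an [incidence_matrix()] with rows in tractogram fiber order and
#'   columns in cohort record order. A stimulation whose masks have empty
#'   support yields a column of zeros with a warning.
#' @export
compute_incidence <- function(tract, cohort, max_step = NULL) {
  stopifnot(inherits(tract, "tractogram"), inherits(cohort, "cohort_table"))
  if (!identical(tract$space, cohort$space)) {
    stopf("space mismatch: tractogram is '%s' but cohort '%s' is '%s'",
          tract$space, cohort$name, cohort$space)
  }
  all_masks <- unlist(lapply(cohort$records, function(r) r$masks), recursive = FALSE)
  if (length(all_masks) == 0) stopf("cohort '%s' has no masks to test against", cohort$name)
  min_edge <- min(vapply(all_masks, function(m) min(voxel_edges(m)), numeric(1)))
  if (is.null(max_step)) max_step <- min_edge / 2
  if (max_step > min_edge + 1e-12) {
    stopf("max_step (%g mm) exceeds the smallest voxel edge (%g mm)", max_step, min_edge)
  }

  nf <- length(tract$streamlines)
  ns <- length(cohort$records)
  if (nf == 0) {
    return(incidence_matrix(Matrix::Matrix(FALSE, 0, ns, sparse = TRUE),
                            integer(0), stim_ids(cohort)))
  }
  res <- lapply(tract$streamlines, resample_streamline, max_step = max_step)
  npts <- vapply(res, nrow, integer(1))
  pts <- do.call(rbind, res)
  fidx <- rep.int(seq_len(nf), npts)
  # per-fiber bounding boxes for cheap pre-filtering against mask boxes
  lo <- t(vapply(res, function(p) c(min(p[, 1]), min(p[, 2]), min(p[, 3])), numeric(3)))
  hi <- t(vapply(res, function(p) c(max(p[, 1]), max(p[, 2]), max(p[, 3])), numeric(3)))

  ii <- integer(0); jj <- integer(0)
  for (s in seq_len(ns)) {
    rec <- cohort$records[[s]]
    connected <- rep(FALSE, nf)
    if (length(rec$masks) && all(vapply(rec$masks, mask_support_size, numeric(1)) == 0)) {
      warnf("stimulation '%s' has empty mask support; column is all zeros", rec$stim_id)
    }
    for (m in rec$masks) {
      if (mask_support_size(m) == 0) next
      box <- mask_world_box(m)
      cand <- which(!connected &
                      hi[, 1] >= box[1, 1] & lo[, 1] <= box[2, 1] &
                      hi[, 2] >= box[1, 2] & lo[, 2] <= box[2, 2] &
                      hi[, 3] >= box[1, 3] & lo[, 3] <= box[2, 3])
      if (!length(cand)) next
      sel <- fidx %in% cand
      hit <- mask_contains(m, pts[sel, , drop = FALSE])
      if (any(hit)) connected[unique(fidx[sel][hit])] <- TRUE
    }
    hits <- which(connected)
    ii <- c(ii, hits)
    jj <- c(jj, rep.int(s, length(hits)))
  }
  ent <- Matrix::sparseMatrix(i = ii, j = jj, dims = c(nf, ns))
  incidence_matrix(ent, tract$ids, stim_ids(cohort))
}

# world-space axis-aligned bounding box of a mask's support (with half-voxel
# margin so nearest-voxel rounding at the rim is covered)
mask_world_box <- function(mask) {
  idx <- which(mask$data == 1L, arr.ind = TRUE) - 1
  corners <- rbind(
    apply_affine(mask$affine, idx)
  )
  margin <- max(voxel_edges(mask))
  rbind(apply(corners, 2, min) - margin, apply(corners, 2, max) + margin)
}

#' Export an incidence matrix as sparse triplets
#'
#' Writes a TSV with columns `fiber_id`, `stim_id`, `value` (always 1) —
#' one row per connected pair.
#'
#' @param inc an [incidence_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_incidence_tsv <- function(inc, path) {
  stopifnot(inherits(inc, "incidence_matrix"))
  tr <- Matrix::summary(inc$entries)
  df <- data.frame(fiber_id = inc$fiber_ids[tr$i],
                   stim_id = inc$stim_ids[tr$j],
                   value = 1L)
  df <- df[order(df$fiber_id, df$stim_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dense binary form of an incidence matrix
#' @param inc an [incidence_matrix()].
#' @return base integer matrix with fiber/stim dimnames (small instances only).
#' @export
incidence_dense <- function(inc) {
  stopifnot(inherits(inc, "incidence_matrix"))
  m <- as.matrix(inc$entries) * 1L
  dimnames(m) <- list(inc$fiber_ids, inc$stim_ids)
  m
}
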