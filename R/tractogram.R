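#' Construct a tractogram
#'
#' A tractogram is an ordered collection of streamlines (3D polylines) in
#' world millimetre coordinates (RAS convention), each carrying a stable
#' integer ID. All geometry in the package lives in one declared world frame,
#' labelled by `space`.
#'
#' @param streamlines list of numeric matrices, each with >= 2 rows and 3
#'   columns (x, y, z in mm).
#' @param ids integer vector of unique streamline IDs, one per streamline.
#'   Defaults to `seq_along(streamlines)`.
#' @param space character label for the reference space, e.g.
#'   `"MNI152NLin2009bAsym"` or `"synthetic"`.
#' @param fiber_scalar optional numeric vector, one value per streamline
#'   (e.g. a fitted t-score carried along for export).
#' @return an object of class `tractogram`: a list with elements
#'   `streamlines`, `ids`, `space` and optionally `fiber_scalar`.
#' @examples
#' tr <- tractogram(list(cbind(c(0, 10), c(0, 0), c(0, 0))), space = "synthetic")
#' n_streamlines(tr)
#' @export
tractogram <- function(streamlines, ids = seq_along(streamlines),
                       space = "synthetic", fiber_scalar = NULL) {
  if (!is.list(streamlines)) stopf("streamlines must be a list of point matrices")
  for (i in seq_along(streamlines)) {
    s <- streamlines[[i]]
    assert_points_matrix(s, sprintf("streamline %d", i))
    if (nrow(s) < 2) stopf("streamline %d has fewer than 2 points", i)
  }
  ids <- as.integer(ids)
  if (length(ids) != length(streamlines)) stopf("ids must match the number of streamlines")
  if (anyDuplicated(ids)) stopf("streamline IDs must be unique within a tractogram")
  if (!is.character(space) || length(space) != 1 || !nzchar(space)) {
    stopf("space must be a nonempty string")
  }
  if (!is.null(fiber_scalar)) {
    if (length(fiber_scalar) != length(streamlines)) {
      stopf("fiber_scalar must have one value per streamline (%d != %d)",
            length(fiber_scalar), length(streamlines))
    }
    fiber_scalar <- as.numeric(fiber_scalar)
  }
  structure(list(streamlines = streamlines, ids = ids, space = space,
                 fiber_scalar = fiber_scalar),
            class = "tractogram")
}

#' Number of streamlines in a tractogram
#' @param x a `tractogram`.
#' @return integer count.
#' @export
n_streamlines <- function(x) {
  stopifnot(inherits(x, "tractogram"))
  length(x$streamlines)
}

#' Arc lengths of all streamlines
#' @param x a `tractogram`.
#' @return numeric vector of polyline arc lengths in mm.
#' @export
streamline_lengths <- function(x) {
  stopifnot(inherits(x, "tractogram"))
  vapply(x$streamlines, polyline_length, numeric(1))
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines in space '%s'\n",
              length(x$streamlines), x$space))
  if (length(x$streamlines)) {
    np <- vapply(x$streamlines, nrow, integer(1))
    cat(sprintf("  points per streamline: %d-%d (median %g)\n",
                min(np), max(np), stats::median(np)))
  }
  if (!is.null(x$fiber_scalar)) cat("  carries a per-fiber scalar\n")
  invisible(x)
}

#' Subset a tractogram by streamline ID
#' @param x a `tractogram`.
#' @param ids IDs to keep, in the order given.
#' @return a `tractogram` with the selected streamlines.
#' @export
subset_tractogram <- function(x, ids) {
  stopifnot(inherits(x, "tractogram"))
  idx <- match(as.integer(ids), x$ids)
  if (anyNA(idx)) stopf("unknown streamline IDs: %s",
                        paste(ids[is.na(idx)], collapse = ", "))
  tractogram(x$streamlines[idx], ids = x$ids[idx], space = x$space,
             fiber_scalar = if (!is.null(x$fiber_scalar)) x$fiber_scalar[idx])
}

#' Concatenate tractograms sharing one space
#' @param ... `tractogram` objects with disjoint ID sets and equal `space`.
#' @return a single `tractogram`.
#' @export
bind_tractograms <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, logical(1), "tractogram")))
  spaces <- unique(vapply(parts, function(p) p$space, character(1)))
  if (length(spaces) != 1) stopf("tractograms live in different spaces: %s",
                                 paste(spaces, collapse = ", "))
  ids <- unlist(lapply(parts, function(p) p$ids))
  scal <- lapply(parts, function(p) p$fiber_scalar)
  has_scal <- !vapply(scal, is.null, logical(1))
  fiber_scalar <- if (all(has_scal)) unlist(scal) else NULL
  tractogram(do.call(c, lapply(parts, function(p) p$streamlines)),
             ids = ids, space = spaces, fiber_scalar = fiber_scalar)
}
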