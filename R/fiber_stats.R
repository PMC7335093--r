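#' Fit mass-univariate fiber T-scores
#'
#' For every fiber, a two-sample t-test contrasts the clinical improvements
#' of stimulations connected to the fiber against those unconnected to it.
#' The signed t-value is the fiber's predictive "weight": a fiber connected
#' predominantly to good responders scores positive (the connected-group mean
#' enters the numerator first). These per-fiber statistics are deliberately
#' not corrected for multiple testing and no per-fiber p-values are computed:
#' they form a predictive model, not a significance map.
#'
#' A fiber is valid only when both groups hold at least `min_per_group`
#' stimulations; invalid fibers carry a t-value of 0 and are flagged rather
#' than dropped, so fiber indexing stays stable across cohorts (required for
#' cross-prediction). A fiber with zero pooled variance but unequal group
#' means is rejected as invalid with a warning.
#'
#' @param inc an [incidence_matrix()].
#' @param improvements numeric vector of percent improvements aligned with
#'   `inc`'s stimulation order.
#' @param min_per_group minimum group size per side, >= 2.
#' @param var_equal `TRUE` (default) for the classical pooled-variance
#'   Student statistic; `FALSE` for the Welch statistic.
#' @return an object of class `fiber_score_model` with fields `fiber_ids`,
#'   `t_values`, `n_connected`, `valid`, `min_per_group`, `n_stims`,
#'   `var_equal` and `provenance`.
#' @export
fit_fiber_scores <- function(inc, improvements, min_per_group = 2L,
                             var_equal = TRUE) {
  stopifnot(inherits(inc, "incidence_matrix"))
  improvements <- as.numeric(improvements)
  ns <- length(inc$stim_ids)
  nf <- length(inc$fiber_ids)
  if (length(improvements) != ns) {
    stopf("improvements has length %d but the incidence matrix has %d stimulations",
          length(improvements), ns)
  }
  if (!all(is.finite(improvements))) stopf("improvements must be finite")
  if (!is_count(min_per_group) || min_per_group < 2) {
    stopf("min_per_group must be an integer >= 2")
  }
  min_per_group <- as.integer(min_per_group)

  e <- inc$entries * 1          # numeric sparse for arithmetic
  n1 <- as.numeric(Matrix::rowSums(e))
  n2 <- ns - n1
  valid <- n1 >= min_per_group & n2 >= min_per_group
  t_values <- numeric(nf)

  if (stats::var(improvements) == 0) {
    warnf("all improvements are equal; every fiber is invalid")
    valid[] <- FALSE
  } else if (any(valid)) {
    # center first: t is shift-invariant and the moment sums are far better
    # conditioned around 0
    imp0 <- improvements - mean(improvements)
    s1 <- as.numeric(e %*% imp0)
    q1 <- as.numeric(e %*% imp0^2)
    S <- sum(imp0)
    Q <- sum(imp0^2)
    m1 <- s1 / n1
    m2 <- (S - s1) / n2
    ss1 <- pmax(q1 - n1 * m1^2, 0)        # within-group sums of squares
    ss2 <- pmax((Q - q1) - n2 * m2^2, 0)
    if (var_equal) {
      sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    } else {
      v1 <- ss1 / pmax(n1 - 1, 1)
      v2 <- ss2 / pmax(n2 - 1, 1)
      se <- sqrt(v1 / n1 + v2 / n2)
    }
    t <- (m1 - m2) / se
    degenerate <- valid & se <= 0 & abs(m1 - m2) > 1e-12
    if (any(degenerate)) {
      warnf("%d fiber(s) have zero pooled variance with unequal means; flagged invalid",
            sum(degenerate))
      valid[degenerate] <- FALSE
    }
    zero_diff <- valid & se <= 0
    t[zero_diff] <- 0
    bad <- valid & !is.finite(t)
    if (any(bad)) {
      warnf("%d fiber(s) yielded non-finite t; flagged invalid", sum(bad))
      valid[bad] <- FALSE
    }
    t_values[valid] <- t[valid]
  }

  structure(list(fiber_ids = inc$fiber_ids,
                 t_values = t_values,
                 n_connected = as.integer(n1),
                 valid = valid,
                 min_per_group = min_per_group,
                 n_stims = as.integer(ns),
                 var_equal = var_equal,
                 provenance = sprintf(
                   "%s two-sample t on %d stimulations, min_per_group=%d",
                   if (var_equal) "pooled" else "Welch", ns, min_per_group)),
            class = "fiber_score_model")
}

#' @export
print.fiber_score_model <- function(x, ...) {
  cs <- count_signed(x)
  cat(sprintf("fiber_score_model: %d fibers (%d valid; %d positive, %d negative)\n",
              length(x$fiber_ids), sum(x$valid), cs[["n_positive"]], cs[["n_negative"]]))
  cat(sprintf("  %s\n", x$provenance))
  invisible(x)
}

#' Count positive and negative fibers
#'
#' Counts valid fibers with strictly positive and strictly negative t-values
#' (the study-level bookkeeping of "positive" vs "negative" tracts selected
#' from the connectome). Zero-t and invalid fibers enter neither count.
#'
#' @param model a [fiber_score_model()].
#' @return named integer vector `c(n_positive=, n_negative=)`.
#' @export
count_signed <- function(model) {
  stopifnot(inherits(model, "fiber_score_model"))
  c(n_positive = sum(model$valid & model$t_values > 0),
    n_negative = sum(model$valid & model$t_values < 0))
}

#' Select the top fraction of discriminative fibers
#'
#' Returns the `ceiling(fraction * n)` fibers with the largest |t| among
#' valid fibers of the requested sign, where n is the number of valid fibers
#' of that sign. Ties at the cut are broken by ascending fiber ID, so the
#' selection is deterministic. This set is for display/export (the "top 20%
#' predictive fibers" view); score aggregation always uses all valid fibers.
#'
#' @param model a [fiber_score_model()].
#' @param fraction proportion in (0, 1].
#' @param sign `"positive"`, `"negative"` or `"absolute"`.
#' @return integer vector of selected fiber IDs (in selection order: largest
#'   |t| first). Empty, with a warning, when no valid fiber has the sign.
#' @export
top_fraction <- function(model, fraction = 0.2,
                         sign = c("positive", "negative", "absolute")) {
  stopifnot(inherits(model, "fiber_score_model"))
  sign <- match.arg(sign)
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    stopf("fraction must be in (0, 1]")
  }
  keep <- switch(sign,
                 positive = model$valid & model$t_values > 0,
                 negative = model$valid & model$t_values < 0,
                 absolute = model$valid & model$t_values != 0)
  if (!any(keep)) {
    warnf("no valid fibers of sign '%s'", sign)
    return(integer(0))
  }
  ids <- model$fiber_ids[keep]
  mag <- abs(model$t_values[keep])
  k <- as.integer(ceiling(fraction * sum(keep)))
  ord <- order(-mag, ids)
  ids[ord][seq_len(k)]
}

#' Persist a fiber-score model
#'
#' Writes the per-fiber table as TSV (`fiber_id`, `t_value`, `n_connected`,
#' `valid`) plus a JSON header (`<path>.json`) carrying `min_per_group`,
#' `n_stims`, `var_equal` and `provenance`, so a model fitted on one cohort
#' re-applies to another bit-identically after [read_fiber_scores()].
#'
#' @param model a [fiber_score_model()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_scores <- function(model, path) {
  stopifnot(inherits(model, "fiber_score_model"))
  df <- data.frame(fiber_id = model$fiber_ids,
                   t_value = sprintf("%.17g", model$t_values),
                   n_connected = model$n_connected,
                   valid = as.integer(model$valid))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  header <- list(min_per_group = model$min_per_group, n_stims = model$n_stims,
                 var_equal = model$var_equal, provenance = model$provenance)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiber_scores
#' @return `read_fiber_scores()`: the reconstructed [fiber_score_model()].
#' @export
read_fiber_scores <- function(path) {
  if (!file.exists(path)) stopf("fiber score file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t")
  hdr_path <- paste0(path, ".json")
  if (!file.exists(hdr_path)) stopf("fiber score header not found: %s", hdr_path)
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  structure(list(fiber_ids = as.integer(df$fiber_id),
                 t_values = as.numeric(df$t_value),
                 n_connected = as.integer(df$n_connected),
                 valid = df$valid == 1L,
                 min_per_group = as.integer(hdr$min_per_group),
                 n_stims = as.integer(hdr$n_stims),
                 var_equal = isTRUE(hdr$var_equal),
                 provenance = as.character(hdr$provenance)),
            class = "fiber_score_model")
}
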