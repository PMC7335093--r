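#' Aggregate fiber T-scores under each stimulation volume
#'
#' For each stimulation, sums the t-values of all valid connected fibers
#' (positive and negative alike) and divides by the stimulation amplitude.
#' The normalization accounts for larger stimulation volumes mechanically
#' collecting more fibers. For multi-electrode records whose volumes entered
#' the incidence matrix as separate masks of one record, the OR-combined
#' incidence already sums across targets before normalization.
#'
#' @param inc an [incidence_matrix()] (fiber order must match the model's).
#' @param model a [fiber_score_model()].
#' @param cohort a [cohort_table()] aligned with `inc`'s stimulation order.
#' @return an `aggregate_scores` data.frame with columns `stim_id`,
#'   `raw_sum`, `score` (= `raw_sum / amplitude`) and `amplitude`.
#' @export
aggregate_scores <- function(inc, model, cohort) {
  stopifnot(inherits(inc, "incidence_matrix"),
            inherits(model, "fiber_score_model"),
            inherits(cohort, "cohort_table"))
  if (!identical(inc$fiber_ids, model$fiber_ids)) {
    stopf("fiber order of the incidence matrix does not match the model")
  }
  if (!identical(inc$stim_ids, stim_ids(cohort))) {
    stopf("stimulation order of the incidence matrix does not match the cohort")
  }
  amp <- amplitudes(cohort)
  bad <- which(!is.finite(amp) | amp <= 0)
  if (length(bad)) {
    stopf("non-positive amplitude for record(s): %s",
          paste(stim_ids(cohort)[bad], collapse = ", "))
  }
  w <- model$t_values * as.numeric(model$valid)
  raw <- as.numeric(Matrix::crossprod(inc$entries * 1, w))
  out <- data.frame(stim_id = inc$stim_ids, raw_sum = raw,
                    score = raw / amp, amplitude = amp,
                    stringsAsFactors = FALSE)
  class(out) <- c("aggregate_scores", "data.frame")
  out
}

score_vector <- function(scores) {
  if (inherits(scores, "aggregate_scores")) scores$score else as.numeric(scores)
}

#' Correlate aggregate scores with clinical improvements
#'
#' @param scores an `aggregate_scores` object or a numeric vector.
#' @param improvements aligned numeric outcome vector.
#' @param method `"pearson"` (default; the scatterplot R of the analysis) or
#'   `"spearman"`.
#' @return the correlation coefficient.
#' @export
correlate <- function(scores, improvements, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- score_vector(scores)
  y <- as.numeric(improvements)
  if (length(x) != length(y)) stopf("scores and improvements have different lengths")
  if (length(x) < 3) stopf("correlation requires at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values in correlation input")
  if (stats::var(x) == 0) stopf("scores have zero variance; correlation undefined")
  if (stats::var(y) == 0) stopf("improvements have zero variance; correlation undefined")
  stats::cor(x, y, method = method)
}

#' Permutation p-value for a score-improvement correlation
#'
#' Monte-Carlo permutation inference: the improvement vector is randomly
#' permuted `n_perm` times (the stimulation geometry, hence the scores, stays
#' fixed — permuting outcomes is the exchangeable null) and the add-one
#' estimator `p = (1 + #{r_perm at least as extreme}) / (n_perm + 1)` is
#' returned, two-sided by default, so p is never exactly 0 and has resolution
#' `1/(n_perm + 1)`.
#'
#' @inheritParams correlate
#' @param n_perm number of random permutations, >= 100.
#' @param seed integer seed; recorded in the result so runs reproduce
#'   bit-identically.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return an object of class `prediction_result`: list with `r`, `p_perm`,
#'   `n_perm`, `method`, `alternative`, `seed`, `scores`, `improvements`.
#' @export
permutation_p <- function(scores, improvements, n_perm = 1000, seed = 1,
                          method = c("pearson", "spearman"),
                          alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is_count(n_perm) || n_perm < 100) stopf("n_perm must be an integer >= 100")
  x <- score_vector(scores)
  y_obs <- y <- as.numeric(improvements)
  r_obs <- correlate(x, y, method = method)
  if (method == "spearman") {   # rank once; permutation of ranks == rank of permutation
    x <- rank(x); y <- rank(y)
  }
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stats::cor(x, sample(y)), numeric(1))
  })
  exceed <- switch(alternative,
                   two.sided = sum(abs(r_perm) >= abs(r_obs)),
                   greater = sum(r_perm >= r_obs),
                   less = sum(r_perm <= r_obs))
  structure(list(r = r_obs,
                 p_perm = (1 + exceed) / (n_perm + 1),
                 n_perm = as.integer(n_perm),
                 method = method,
                 alternative = alternative,
                 seed = as.integer(seed),
                 scores = scores,
                 improvements = y_obs),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: R = %.3f, permutation p = %.4g (%s, %s, %d permutations, seed %d)\n",
              x$r, x$p_perm, x$method, x$alternative, x$n_perm, x$seed))
  invisible(x)
}

#' Cross-cohort outcome prediction
#'
#' Fits the fiber-score model exclusively on the training cohort, then
#' evaluates aggregate scores, correlation and permutation p exclusively on
#' the test cohort. No test information flows into the model: the fit sees
#' only `train_inc` and the training improvements.
#'
#' @param train_inc,train_cohort training incidence matrix and cohort.
#' @param test_inc,test_cohort test incidence matrix and cohort; both
#'   incidence matrices must be indexed against the same tractogram fiber
#'   order.
#' @param min_per_group passed to [fit_fiber_scores()].
#' @inheritParams permutation_p
#' @param var_equal passed to [fit_fiber_scores()].
#' @return a `prediction_result` (see [permutation_p()]) with the fitted
#'   model attached as `$model`.
#' @export
cross_predict <- function(train_inc, train_cohort, test_inc, test_cohort,
                          min_per_group = 2L, n_perm = 1000, seed = 1,
                          method = c("pearson", "spearman"),
                          alternative = c("two.sided", "greater", "less"),
                          var_equal = TRUE) {
  stopifnot(inherits(train_inc, "incidence_matrix"),
            inherits(test_inc, "incidence_matrix"))
  if (!identical(train_inc$fiber_ids, test_inc$fiber_ids)) {
    stopf("train and test incidence matrices index different fiber orders")
  }
  model <- fit_fiber_scores(train_inc, improvements(train_cohort),
                            min_per_group = min_per_group, var_equal = var_equal)
  sc <- aggregate_scores(test_inc, model, test_cohort)
  res <- permutation_p(sc, improvements(test_cohort), n_perm = n_perm,
                       seed = seed, method = method, alternative = alternative)
  res$model <- model
  res
}

#' Compare improvements of low-scoring vs high-scoring stimulations
#'
#' Classical pooled two-sample t-test between improvements of stimulations
#' with aggregate score below `cutoff` ("near-zero" stimulations barely
#' touching the tract) and the remaining ones. Orientation is low minus
#' high: when high-scoring stimulations improve more, t is negative. The
#' p-value is the classical Student p (this subgroup contrast is the one
#' analysis not given a permutation p). The cutoff applies to whichever
#' score vector is passed — amplitude-normalized `$score` when an
#' `aggregate_scores` or `prediction_result` object is given.
#'
#' @param result a `prediction_result`, `aggregate_scores`, or numeric score
#'   vector.
#' @param improvements aligned outcomes; taken from `result` when it is a
#'   `prediction_result`.
#' @param cutoff score threshold separating the groups.
#' @return list with `t_statistic`, `p_value`, `group_sizes` (low, high) and
#'   `group_means`.
#' @export
low_high_comparison <- function(result, improvements = NULL, cutoff) {
  if (inherits(result, "prediction_result")) {
    x <- score_vector(result$scores)
    y <- result$improvements
  } else {
    x <- score_vector(result)
    y <- as.numeric(improvements)
  }
  if (length(x) != length(y)) stopf("scores and improvements have different lengths")
  low <- x < cutoff
  if (!any(low) || all(low)) {
    stopf("cutoff %g leaves one group empty; achievable cutoffs lie in (%g, %g]",
          cutoff, min(x), max(x))
  }
  y1 <- y[low]; y2 <- y[!low]
  n1 <- length(y1); n2 <- length(y2)
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    t_stat <- 0
    p <- 1
  } else {
    t_stat <- (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  }
  list(t_statistic = t_stat, p_value = p,
       group_sizes = c(low = n1, high = n2),
       group_means = c(low = mean(y1), high = mean(y2)))
}

#' Serialize a prediction result to JSON
#'
#' Writes `r`, `p_perm`, `n_perm`, `seed`, `method`, `alternative` and the
#' per-stimulation scatter data (stim_id, score, improvement) so every
#' reported number is recomputable and the scatterplot is re-plottable.
#'
#' @param result a `prediction_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(result, path) {
  stopifnot(inherits(result, "prediction_result"))
  sc <- result$scores
  scatter <- if (inherits(sc, "aggregate_scores")) {
    data.frame(stim_id = sc$stim_id, raw_sum = sc$raw_sum, score = sc$score,
               amplitude = sc$amplitude, improvement = result$improvements)
  } else {
    data.frame(score = score_vector(sc), improvement = result$improvements)
  }
  jsonlite::write_json(
    list(r = result$r, p_perm = result$p_perm, n_perm = result$n_perm,
         seed = result$seed, method = result$method,
         alternative = result$alternative, data = scatter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
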