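# Metric suite, cross-validation aggregation, score-consistency analysis and
# the post-hoc candidate-screening rules.

#' Regression metrics: RMSE, Spearman correlation, R-squared
#'
#' Spearman is the Pearson correlation of average ranks (equivalent to the
#' textbook rank-difference formula when there are no ties). By default the
#' coefficient of determination uses the standard denominator
#' \eqn{\sum (Y_i - \bar Y)^2}; \code{printed_denominator = TRUE} switches to
#' the variant \eqn{\sum (y_i - \bar Y)^2} that mixes the predictions with
#' the mean of the actual values, kept for exact-formula comparison.
#'
#' @param actual,predicted numeric vectors of equal length (>= 2).
#' @param printed_denominator use the non-standard R-squared denominator.
#' @return named numeric vector \code{c(rmse, spearman, r2)}.
#' @export
regression_metrics <- function(actual, predicted, printed_denominator = FALSE) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2) stop("need at least 2 observations")
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) stop("non-finite values")
  rmse <- sqrt(mean((actual - predicted)^2))
  denom <- if (printed_denominator) sum((predicted - mean(actual))^2)
           else sum((actual - mean(actual))^2)
  if (denom == 0) stop("zero variance in the R-squared denominator")
  spearman <- if (stats::sd(predicted) == 0) NA_real_
              else stats::cor(actual, predicted, method = "spearman")
  r2 <- 1 - sum((actual - predicted)^2) / denom
  c(rmse = rmse, spearman = spearman, r2 = r2)
}

#' Classification metrics at a probability cutoff
#'
#' Confusion-matrix metrics (accuracy, precision, recall, F1) at the given
#' cutoff on the positive-class probability, plus threshold-free AUROC (rank
#' statistic: the probability that a random positive outranks a random
#' negative, with half credit for ties) and AUPR (area under the
#' precision-recall step curve).
#'
#' @param labels 0/1 vector.
#' @param probs positive-class probabilities.
#' @param cutoff decision cutoff (a sample is called positive when its
#'   probability strictly exceeds the cutoff).
#' @return named numeric vector \code{c(accuracy, precision, recall, f1,
#'   auroc, aupr)}.
#' @export
classification_metrics <- function(labels, probs, cutoff = 0.5) {
  if (length(labels) != length(probs)) stop("length mismatch")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC/AUPR undefined: only one class present")
  yhat <- as.integer(probs > cutoff)
  tp <- sum(yhat == 1 & labels == 1)
  fp <- sum(yhat == 1 & labels == 0)
  fn <- sum(yhat == 0 & labels == 1)
  tn <- sum(yhat == 0 & labels == 0)
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    auroc = auroc_rank(labels, probs), aupr = aupr_step(labels, probs))
}

# Mann-Whitney formulation with average ranks (ties get half credit)
auroc_rank <- function(labels, probs) {
  r <- rank(probs)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall step curve, grouping tied scores
aupr_step <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  labels <- labels[ord]
  probs <- probs[ord]
  n1 <- sum(labels)
  # cumulative counts at each distinct threshold
  last_of_group <- c(probs[-1] != probs[-length(probs)], TRUE)
  ctp <- cumsum(labels)[last_of_group]
  cn <- seq_along(labels)[last_of_group]
  prec <- ctp / cn
  rec <- ctp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Aggregate per-fold evaluation reports
#'
#' @param reports list (one per fold) of per-task metric lists as produced by
#'   \code{\link{evaluate_predictions}}.
#' @return list with per-task \code{mean}, \code{variance} (sample variance
#'   across folds) and \code{ci_halfwidth} (t-based 95 percent half-widths
#'   for plotting).
#' @export
aggregate_cv <- function(reports) {
  if (length(reports) < 2) stop("need at least two folds to aggregate")
  tasks <- names(reports[[1]])
  if (!all(vapply(reports, function(r) identical(names(r), tasks), logical(1))))
    stop("per-fold reports have mismatched task rosters")
  k <- length(reports)
  agg <- function(f) {
    out <- list()
    for (t in tasks) {
      m <- do.call(rbind, lapply(reports, function(r) r[[t]]))
      out[[t]] <- apply(m, 2, f)
    }
    out
  }
  list(mean = agg(mean), variance = agg(stats::var),
       ci_halfwidth = agg(function(x) stats::qt(0.975, k - 1) * stats::sd(x) / sqrt(k)),
       n_folds = k)
}

#' Evaluate per-task predictions against observed values
#'
#' @param pred per-task prediction list (\code{\link{predict_symmetrized}}).
#' @param samples combination data.frame holding the observed scores/labels.
#' @param tasks list of \code{\link{task_spec}}.
#' @return named list: per task, a named metric vector.
#' @export
evaluate_predictions <- function(pred, samples, tasks) {
  targets <- task_targets(samples, tasks)
  out <- list()
  for (t in tasks) {
    out[[t$name]] <- if (t$kind == "regression") {
      regression_metrics(targets[[t$name]], pred[[t$name]])
    } else {
      # single-class folds leave the threshold-free metrics undefined
      tryCatch(classification_metrics(targets[[t$name]], pred[[t$name]][, 2]),
               error = function(e) c(accuracy = NA_real_, precision = NA_real_,
                                     recall = NA_real_, f1 = NA_real_,
                                     auroc = NA_real_, aupr = NA_real_))
    }
  }
  out
}

#' Count synergy scores exceeding a threshold
#'
#' The support count of a combination is the number of its five synergy
#' scores strictly greater than the threshold (default 5); higher support
#' marks a more confident synergistic call.
#'
#' @param scores numeric vector of the five synergy scores; if named, all of
#'   \code{loewe}, \code{bliss}, \code{zip}, \code{hsa}, \code{s} must be
#'   present.
#' @param threshold support threshold.
#' @return integer in 0..5.
#' @export
count_support <- function(scores, threshold = 5) {
  if (!is.null(names(scores))) {
    miss <- setdiff(REGRESSION_TASKS, names(scores))
    if (length(miss)) stop("missing scores: ", paste(miss, collapse = ", "))
    scores <- scores[REGRESSION_TASKS]
  } else if (length(scores) != length(REGRESSION_TASKS)) {
    stop(sprintf("expected %d scores, got %d", length(REGRESSION_TASKS), length(scores)))
  }
  if (any(!is.finite(scores))) stop("non-finite synergy score")
  sum(scores > threshold)
}

#' Pairwise Pearson correlation of the five synergy scores
#'
#' @param scores numeric matrix (samples x 5 tasks) or data.frame.
#' @param subset optional logical mask selecting the samples (e.g. the
#'   synergistic ones).
#' @return 5 x 5 symmetric correlation matrix with unit diagonal.
#' @export
pairwise_score_correlation <- function(scores, subset = NULL) {
  m <- as.matrix(scores)
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  if (nrow(m) < 2) stop("subset too small for correlation")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(m)[which(v == 0)[1]]
    if (is.null(bad)) bad <- as.character(which(v == 0)[1])
    stop(sprintf("zero variance in task '%s' over the subset", bad))
  }
  stats::cor(m)
}

#' Screening rule for candidate drug combinations
#'
#' @param kind one of \code{"support_count"} (keep rows whose support count
#'   at \code{threshold} is at least \code{min_support}),
#'   \code{"prob_threshold"} (keep rows whose synergy-positive probability
#'   exceeds \code{threshold}), \code{"all_scores_threshold"} (keep rows with
#'   all five predicted scores above \code{threshold}) and
#'   \code{"ddi_exclude"} (drop rows whose adverse-DDI probability exceeds
#'   \code{threshold}).
#' @param threshold rule threshold.
#' @param min_support minimum support count (support_count rule only).
#' @return list of class \code{"screen_rule"}.
#' @export
screen_rule <- function(kind = c("support_count", "prob_threshold",
                                 "all_scores_threshold", "ddi_exclude"),
                        threshold = 5, min_support = 5L) {
  kind <- match.arg(kind)
  stopifnot(is.finite(threshold))
  structure(list(kind = kind, threshold = threshold,
                 min_support = as.integer(min_support)),
            class = "screen_rule")
}

#' Screen predicted combinations by a conjunction of rules
#'
#' Applies the rules in order as a conjunction of filters, preserving the
#' input row order; surviving rows are annotated with their support count
#' (number of the five predicted scores above the support threshold, default
#' 5). Typical use mirrors the published screening protocol: keep
#' combinations with synergy probability above 0.99, or with all five
#' predicted scores above 30, then drop those whose predicted adverse-DDI
#' probability is high.
#'
#' @param predictions data.frame with columns \code{pred_loewe},
#'   \code{pred_bliss}, \code{pred_zip}, \code{pred_hsa}, \code{pred_s},
#'   \code{prob_synergy} and (for \code{ddi_exclude}) \code{prob_ddi}.
#' @param rules list of \code{\link{screen_rule}} objects.
#' @param support_threshold threshold used for the annotated support column.
#' @return the filtered data.frame with an added \code{support} column.
#' @export
screen_candidates <- function(predictions, rules = list(), support_threshold = 5) {
  score_cols <- paste0("pred_", REGRESSION_TASKS)
  need <- function(cols) {
    miss <- setdiff(cols, names(predictions))
    if (length(miss)) stop("predictions table missing columns: ",
                           paste(miss, collapse = ", "))
  }
  need(score_cols)
  S <- as.matrix(predictions[, score_cols])
  support <- rowSums(S > support_threshold)
  keep <- rep(TRUE, nrow(predictions))
  for (r in rules) {
    keep <- keep & switch(r$kind,
      support_count = rowSums(S > r$threshold) >= r$min_support,
      prob_threshold = { need("prob_synergy"); predictions$prob_synergy > r$threshold },
      all_scores_threshold = rowSums(S > r$threshold) == ncol(S),
      ddi_exclude = { need("prob_ddi"); !(predictions$prob_ddi > r$threshold) })
  }
  out <- predictions[keep, , drop = FALSE]
  out$support <- as.integer(support[keep])
  out
}
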