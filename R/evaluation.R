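#' Three-class confusion matrix
#'
#' Tallies true versus predicted stage labels into a 3 x 3 integer matrix
#' with rows = true stage and columns = predicted stage, both in the order
#' pre-pubertal, pubertal, post-pubertal.
#'
#' @param true_labels,predicted_labels equal-length vectors of stage names.
#' @return Integer matrix of class `confusion_matrix` with dimnames set to
#'   [stage_levels()].
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  t_f <- as_stage(true_labels)
  p_f <- as_stage(predicted_labels)
  if (length(t_f) != length(p_f)) {
    stop("true and predicted label vectors must have equal length", call. = FALSE)
  }
  if (anyNA(t_f) || anyNA(p_f)) {
    stop("labels must all be one of the three stages (no unlabeled entries)",
         call. = FALSE)
  }
  cm <- table(true = t_f, predicted = p_f)
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(true = stage_levels(), predicted = stage_levels()))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix directly from counts
#'
#' @param counts 3 x 3 matrix of nonnegative integers (rows = true stage).
#' @return A `confusion_matrix` object.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must be a 3 x 3 matrix of nonnegative integers", call. = FALSE)
  }
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(true = stage_levels(), predicted = stage_levels()))
  structure(m, class = c("confusion_matrix", "matrix"))
}

# per-class one-vs-rest counts
ovr_counts <- function(cm, i) {
  total <- sum(cm)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- total - tp - fn - fp
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

# rank with ties sharing the better (smaller) rank; larger value = better
rank_best_first <- function(x) {
  r <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  r[ok] <- as.integer(rank(-x[ok], ties.method = "min"))
  r
}

#' Per-class one-vs-rest diagnostic measures
#'
#' Collapses the 3 x 3 confusion matrix to one-vs-rest counts per stage and
#' reports sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive
#' predictive value TP/(TP+FP), negative predictive value TN/(TN+FN) and
#' per-class accuracy (TP+TN)/total, each with a rank across the three
#' classes (1 = best; ties share the better rank). Measures with a zero
#' denominator are reported as `NA` ("undefined"), never as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return Data frame with one row per stage: the four counts, the five
#'   measures, and a `<measure>_rank` column for each.
#' @export
classwise_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  rows <- lapply(1:3, function(i) {
    k <- ovr_counts(cm, i)
    data.frame(
      stage = stage_levels()[i],
      tp = k[["tp"]], fp = k[["fp"]], fn = k[["fn"]], tn = k[["tn"]],
      sensitivity = safe_ratio(k[["tp"]], k[["tp"]] + k[["fn"]]),
      specificity = safe_ratio(k[["tn"]], k[["tn"]] + k[["fp"]]),
      ppv = safe_ratio(k[["tp"]], k[["tp"]] + k[["fp"]]),
      npv = safe_ratio(k[["tn"]], k[["tn"]] + k[["fn"]]),
      accuracy = (k[["tp"]] + k[["tn"]]) / total
    )
  })
  out <- do.call(rbind, rows)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    out[[paste0(m, "_rank")]] <- rank_best_first(out[[m]])
  }
  out
}

#' Overall accuracy
#'
#' @param cm a `confusion_matrix` with at least one observation.
#' @return Trace divided by total count.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) stop("confusion matrix is empty", call. = FALSE)
  sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa (unweighted, linear or quadratic weights)
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}.
#' Weighted variants discount disagreements by the distance between the
#' ordered stages: disagreement weight `|i-j|/(k-1)` (linear) or its square
#' (quadratic); `none` counts any disagreement fully. When the true classes
#' are balanced the unweighted expected agreement is exactly 1/3 whatever
#' the predicted marginals, so kappa = (accuracy - 1/3) / (2/3).
#'
#' @param cm a `confusion_matrix`.
#' @param weighting `"none"`, `"linear"` or `"quadratic"`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm, weighting = c("none", "linear", "quadratic")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  weighting <- match.arg(weighting)
  n <- sum(cm)
  if (n == 0) stop("confusion matrix is empty", call. = FALSE)
  k <- nrow(cm)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  v <- switch(weighting, none = (d > 0) * 1, linear = d, quadratic = d^2)
  p <- cm / n
  pe <- outer(rowSums(p), colSums(p))
  obs_dis <- sum(v * p)
  exp_dis <- sum(v * pe)
  if (exp_dis == 0) {
    stop("kappa undefined: expected agreement is 1 (degenerate marginals)",
         call. = FALSE)
  }
  1 - obs_dis / exp_dis
}

#' Altman interpretation band for a kappa value
#'
#' Conventional qualitative bands: `< 0.20` poor, `(0.20, 0.40]` fair,
#' `(0.40, 0.60]` moderate, `(0.60, 0.80]` good, `(0.80, 1.00]` very good.
#'
#' @param kappa number in `[-1, 1]`.
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`, `"very good"`.
#' @export
altman_band <- function(kappa) {
  check_number(kappa, "kappa", min = -1, max = 1)
  if (kappa <= 0.20) "poor"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "good"
  else "very good"
}

#' Full evaluation report from a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return List with `confusion` (counts), `classwise` (from
#'   [classwise_metrics()]), `overall_accuracy`, `kappa_unweighted`,
#'   `kappa_linear`, `kappa_quadratic` and `altman_band` (of the unweighted
#'   kappa).
#' @export
evaluation_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ku <- cohens_kappa(cm, "none")
  list(
    confusion = unclass(cm),
    classwise = classwise_metrics(cm),
    overall_accuracy = overall_accuracy(cm),
    kappa_unweighted = ku,
    kappa_linear = cohens_kappa(cm, "linear"),
    kappa_quadratic = cohens_kappa(cm, "quadratic"),
    altman_band = altman_band(ku)
  )
}
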