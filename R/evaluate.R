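#' Per-comparison error rate
#'
#' Fraction of genes declared DE on null data: the proportion of
#' (unadjusted) p-values at or below `alpha`.
#'
#' @param pvalues Numeric vector of p-values from a null run.
#' @param alpha Declaration threshold in (0, 1), default 0.05.
#' @return The empirical PCER.
#' @export
pcer <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  mean(pvalues <= alpha)
}

#' Confusion counts and error rates at a threshold
#'
#' Declares genes with `padj <= threshold` and reports TP, FP, TN, FN plus
#' `TPR = TP/P`, `FPR = FP/N` and `FDP = FP / max(1, FP + TP)` (the
#' max(1, .) guard makes the FDP 0 when nothing is declared). `TPR` is
#' reported as `NA` when the truth has no positives.
#'
#' @param padj Adjusted p-values.
#' @param truth Logical vector, `TRUE` for genuinely DE genes.
#' @param threshold Declaration threshold.
#' @return A list with `TP`, `FP`, `TN`, `FN`, `TPR`, `FPR`, `FDP`.
#' @export
confusion_and_rates <- function(padj, truth, threshold = 0.05) {
  if (length(padj) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  declared <- padj <= threshold
  TP <- sum(declared & truth); FP <- sum(declared & !truth)
  FN <- sum(!declared & truth); TN <- sum(!declared & !truth)
  P <- sum(truth); N <- sum(!truth)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       TPR = if (P > 0) TP / P else NA_real_,
       FPR = if (N > 0) FP / N else NA_real_,
       FDP = FP / max(1, FP + TP))
}

#' FDP-TPR curve
#'
#' Sweeps the declaration threshold over the distinct adjusted p-values in
#' ascending order (ties grouped into one point) and reports the false
#' discovery proportion and true positive rate of each nested rejection
#' set.
#'
#' @inheritParams confusion_and_rates
#' @return A data frame with columns `threshold`, `FDP`, `TPR`.
#' @export
fdp_tpr_curve <- function(padj, truth) {
  if (length(padj) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  th <- sort(unique(padj))
  pts <- t(vapply(th, function(t0) {
    cr <- confusion_and_rates(padj, truth, t0)
    c(FDP = cr$FDP, TPR = cr$TPR)
  }, numeric(2)))
  data.frame(threshold = th, FDP = pts[, "FDP"], TPR = pts[, "TPR"])
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC of the ROC built from `1 - padj` as the score,
#' tie-aware, computed in its equivalent rank (Mann-Whitney) form with
#' half-credit for ties.
#'
#' @inheritParams confusion_and_rates
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(padj, truth) {
  if (length(padj) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0 || nN == 0)
    stop("AUC needs at least one positive and one negative")
  score <- -padj
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - nP * (nP + 1) / 2) / (nP * nN)
}
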