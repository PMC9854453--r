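#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random presence outscores a random background
#' point, with ties counted one half; computed from average ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector; both classes required.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes are required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# sensitivity/specificity at a threshold (predicted presence iff score >= t)
sens_spec <- function(scores, labels, t) {
  pred <- scores >= t
  c(sens = sum(pred & labels == 1) / sum(labels == 1),
    spec = sum(!pred & labels == 0) / sum(labels == 0))
}

threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  # midpoints of sorted unique scores, plus ends so the all-1/all-0 maps
  # are reachable
  c(u[1] - 1e-9, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1e-9)
}

#' Maximum true skill statistic over thresholds
#'
#' Scans `TSS(t) = sensitivity(t) + specificity(t) - 1` over candidate
#' thresholds at the midpoints of sorted unique scores and returns the
#' maximum and its (lowest, on ties) threshold.
#'
#' @inheritParams auc
#' @return list with `tss` and `threshold`.
#' @export
tss_max <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("both classes are required to compute TSS")
  cand <- threshold_candidates(scores)
  tss <- vapply(cand, function(t) {
    ss <- sens_spec(scores, labels, t)
    ss[["sens"]] + ss[["spec"]] - 1
  }, numeric(1))
  best <- which(tss >= max(tss) - 1e-12)[1]   # ties -> lowest threshold
  list(tss = tss[best], threshold = cand[best])
}

#' Qualitative model-performance classes
#'
#' Standard verbal accuracy classes: AUC excellent above 0.90, good in
#' (0.80, 0.90], fair in (0.70, 0.80], poor below 0.60 — the band
#' \[0.60, 0.70\] has no conventional name and is labelled
#' `"unclassified (gap)"`; TSS excellent above 0.75, good in (0.40, 0.75],
#' poor at or below 0.40.
#'
#' @param auc AUC in \[0, 1\].
#' @param tss TSS in \[-1, 1\].
#' @return list with `auc_class`, `tss_class`.
#' @export
classify_performance <- function(auc, tss) {
  if (auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  if (tss < -1 || tss > 1) stop("tss must lie in [-1, 1]")
  auc_class <-
    if (auc > 0.90) "excellent"
    else if (auc > 0.80) "good"
    else if (auc > 0.70) "fair"
    else if (auc < 0.60) "poor"
    else "unclassified (gap)"
  tss_class <-
    if (tss > 0.75) "excellent"
    else if (tss > 0.40) "good"
    else "poor"
  list(auc_class = auc_class, tss_class = tss_class)
}
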