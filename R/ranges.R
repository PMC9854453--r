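#' The four binarization threshold rules
#' @export
threshold_methods <- function()
  c("SENS_EQ_SPEC", "MAX_TSS", "MEAN_OCC_PROB", "MIN_ROC_DIST")

#' Choose a binarization threshold
#'
#' Candidate thresholds are the midpoints of the sorted unique pooled
#' scores (plus the two just-outside endpoints, so the all-presence and
#' all-absence maps stay reachable); ties resolve to the lowest threshold.
#' Rules: `SENS_EQ_SPEC` minimizes |sensitivity - specificity|; `MAX_TSS`
#' maximizes sensitivity + specificity - 1; `MEAN_OCC_PROB` is the
#' arithmetic mean of the presence scores (no scan); `MIN_ROC_DIST`
#' minimizes the ROC-plot distance `sqrt((1-sens)^2 + (1-spec)^2)`.
#'
#' @param scores_presence,scores_background score vectors (both non-empty).
#' @param method one of [threshold_methods()].
#' @return threshold (numeric scalar).
#' @export
find_threshold <- function(scores_presence, scores_background,
                           method = threshold_methods()) {
  method <- match.arg(method)
  if (!length(scores_presence) || !length(scores_background))
    stop("both presence and background scores are required")
  if (method == "MEAN_OCC_PROB") return(mean(scores_presence))
  pooled <- c(scores_presence, scores_background)
  labels <- rep(c(1, 0), c(length(scores_presence),
                           length(scores_background)))
  cand <- threshold_candidates(pooled)
  crit <- vapply(cand, function(t) {
    ss <- sens_spec(pooled, labels, t)
    switch(method,
      SENS_EQ_SPEC = abs(ss[["sens"]] - ss[["spec"]]),
      MAX_TSS = -(ss[["sens"]] + ss[["spec"]] - 1),
      MIN_ROC_DIST = sqrt((1 - ss[["sens"]])^2 + (1 - ss[["spec"]])^2))
  }, numeric(1))
  cand[which(crit <= min(crit) + 1e-12)[1]]
}

#' Binarize a suitability surface
#'
#' Cells become 1 where suitability is at or above the threshold
#' (threshold-inclusive, so ties are deterministic); nodata propagates.
#'
#' @param suitability `rs_grid` of suitability scores.
#' @param threshold finite cut-off.
#' @param method label recording which rule produced the threshold.
#' @return an `rs_binary` grid (0/1/nodata) carrying `threshold_used` and
#'   `method`.
#' @export
binarize <- function(suitability, threshold, method = "MAX_TSS") {
  if (!is.finite(threshold)) stop("threshold must be finite")
  g <- grid_like(suitability, (suitability$values >= threshold) * 1)
  g$threshold_used <- threshold
  g$method <- method
  class(g) <- c("rs_binary", class(g))
  g
}

check_binary <- function(g) {
  v <- g$values
  if (any(!is.na(v) & v != 0 & v != 1))
    stop("binary range must contain only 0, 1 and nodata")
  invisible(g)
}

count_ones <- function(g) sum(g$values == 1, na.rm = TRUE)

#' Clip an initial range by a mask
#'
#' Cellwise AND of a binary prediction with a range mask (the stand-in for
#' clipping along a published expert range before seeding dispersal).
#'
#' @param current_binary binary range grid.
#' @param range_mask 0/1 `rs_grid`.
#' @export
clip_initial_range <- function(current_binary, range_mask) {
  stop_if_misaligned(current_binary, range_mask)
  check_binary(current_binary)
  v <- (current_binary$values == 1 & range_mask$values == 1) * 1
  v[is.na(current_binary$values)] <- NA_real_
  out <- grid_like(current_binary, v)
  out$threshold_used <- current_binary$threshold_used
  out$method <- current_binary$method
  class(out) <- class(current_binary)
  out
}

#' Range net change between two binary maps
#'
#' Gain/loss/stable cell counts and
#' `net_change_pct = 100 * (gain - loss) / current_cells`. The denominator
#' is the current range size (bounded below by -100); the mirror
#' stable-cell denominator degenerates as stability vanishes.
#'
#' @param current,future aligned binary range grids.
#' @return list of class `rs_change` with the counts and percentage.
#' @export
net_change <- function(current, future) {
  stop_if_misaligned(current, future)
  check_binary(current); check_binary(future)
  cur <- current$values == 1 & !is.na(current$values)
  fut <- future$values == 1 & !is.na(future$values)
  gain <- sum(fut & !cur); loss <- sum(cur & !fut)
  stable <- sum(cur & fut)
  if (stable + loss == 0) stop("current range is empty: net change undefined")
  structure(list(gain_cells = gain, loss_cells = loss, stable_cells = stable,
                 current_cells = stable + loss, future_cells = stable + gain,
                 net_change_pct = 100 * (gain - loss) / (stable + loss)),
            class = "rs_change")
}

#' Geographical range shift
#'
#' The percentage of the *future* range lying outside the current range:
#' `100 * (1 - |current ∩ future| / future_cells)`. The mirror statistic
#' (fraction of the current range abandoned) is attached as attribute
#' `shift_of_current`.
#'
#' @param current,future aligned binary range grids (future non-empty).
#' @export
range_shift <- function(current, future) {
  stop_if_misaligned(current, future)
  check_binary(current); check_binary(future)
  cur <- current$values == 1 & !is.na(current$values)
  fut <- future$values == 1 & !is.na(future$values)
  if (!sum(fut)) stop("future range is empty: shift undefined")
  stable <- sum(cur & fut)
  out <- 100 * (1 - stable / sum(fut))
  if (sum(cur))
    attr(out, "shift_of_current") <- 100 * (1 - stable / sum(cur))
  out
}

#' Interspecific range overlap
#'
#' Percentage of range A lying inside range B:
#' `100 * |A ∩ B| / |A|` (e.g. the share of the prey's range exposed to the
#' predator).
#'
#' @param range_a,range_b aligned binary range grids (A non-empty).
#' @export
species_overlap <- function(range_a, range_b) {
  stop_if_misaligned(range_a, range_b)
  check_binary(range_a); check_binary(range_b)
  a <- range_a$values == 1 & !is.na(range_a$values)
  b <- range_b$values == 1 & !is.na(range_b$values)
  if (!sum(a)) stop("range A is empty: overlap undefined")
  100 * sum(a & b) / sum(a)
}

#' Four-class change map
#'
#' 0 stable unsuitable, 1 loss, 2 stable suitable, 3 gain (the standard
#' grey/red/green/yellow map legend).
#' @param current,future aligned binary range grids.
#' @export
change_map <- function(current, future) {
  stop_if_misaligned(current, future)
  cur <- current$values == 1
  fut <- future$values == 1
  v <- ifelse(cur & fut, 2, ifelse(cur & !fut, 1, ifelse(fut, 3, 0)))
  v[is.na(current$values) | is.na(future$values)] <- NA_real_
  grid_like(current, v)
}

#' Summarize metric runs across a factorial
#'
#' Medians and standard deviations per group (typically per scenario, over
#' the GCM x threshold factorial). Single-run groups report SD = 0; empty
#' groups are omitted with a warning.
#'
#' @param runs data.frame of metric values.
#' @param value name of the value column.
#' @param by grouping column names.
#' @return data.frame with `median`, `sd` and `n` per group.
#' @export
summarize_across <- function(runs, value = "value",
                             by = c("species", "scenario", "metric")) {
  by <- intersect(by, names(runs))
  if (!nrow(runs)) {
    warning("no runs to summarize")
    return(data.frame())
  }
  key <- interaction(runs[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(runs, key), function(g) {
    v <- g[[value]]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    cbind(g[1, by, drop = FALSE],
          data.frame(median = stats::median(v),
                     sd = if (length(v) > 1) stats::sd(v) else 0,
                     n = length(v)))
  }))
  rownames(out) <- NULL
  out
}
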