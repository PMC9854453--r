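# Independent brute-force oracles. These deliberately use the dumbest
# correct formulation of each quantity and share no code with R/.

# AUC by O(n^2) pair counting, ties worth one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

oracle_sens_spec <- function(scores, labels, t) {
  pred <- scores >= t
  c(sens = mean(pred[labels == 1]), spec = mean(!pred[labels == 0]))
}

# candidate thresholds: midpoints of sorted unique scores plus the
# just-outside endpoints (same candidate set the package scans)
oracle_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  c(u[1] - 1e-9, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1e-9)
}

oracle_tss_scan <- function(scores, labels) {
  cand <- oracle_candidates(scores)
  best <- -Inf; best_t <- NA
  for (t in cand) {
    ss <- oracle_sens_spec(scores, labels, t)
    tss <- ss[["sens"]] + ss[["spec"]] - 1
    if (tss > best + 1e-12) { best <- tss; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

oracle_threshold <- function(sp, sb, method) {
  if (method == "MEAN_OCC_PROB") return(mean(sp))
  scores <- c(sp, sb); labels <- rep(c(1, 0), c(length(sp), length(sb)))
  cand <- oracle_candidates(scores)
  best <- Inf; best_t <- NA
  for (t in cand) {
    ss <- oracle_sens_spec(scores, labels, t)
    crit <- switch(method,
      SENS_EQ_SPEC = abs(ss[["sens"]] - ss[["spec"]]),
      MAX_TSS = -(ss[["sens"]] + ss[["spec"]] - 1),
      MIN_ROC_DIST = sqrt((1 - ss[["sens"]])^2 + (1 - ss[["spec"]])^2))
    if (crit < best - 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

# exact nearest-class-cell distance by exhaustive all-pairs search
oracle_dist_to_class <- function(landuse_values, class_code, cell_size) {
  d <- dim(landuse_values)
  targets <- which(landuse_values == class_code, arr.ind = TRUE)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    best <- Inf
    for (t in seq_len(nrow(targets))) {
      dd <- sqrt((i - targets[t, 1])^2 + (j - targets[t, 2])^2) * cell_size
      if (dd < best) best <- dd
    }
    out[i, j] <- best
  }
  out
}

# exact maximum independent set size over all subsets (n <= 15)
oracle_thin_optimum <- function(x, y, min_dist) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in seq(a + 1, length(idx))) {
          if (d2[idx[a], idx[b]] < min_dist^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# BFS reachability: cells within graph distance T steps of the seeds,
# edges joining suitable cells whose centres lie within `radius` cells
oracle_bfs_reach <- function(initial, suitable, radius_cells, steps) {
  d <- dim(initial)
  rows <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  cols <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  frontier <- which(initial & suitable)
  reached <- logical(prod(d)); reached[frontier] <- TRUE
  for (s in seq_len(steps)) {
    nxt <- integer(0)
    for (cell in which(reached)) {
      cand <- which(suitable & !reached)
      if (!length(cand)) next
      d2 <- (rows[cand] - rows[cell])^2 + (cols[cand] - cols[cell])^2
      nxt <- c(nxt, cand[d2 <= radius_cells^2])
    }
    reached[unique(nxt)] <- TRUE
  }
  reached_m <- matrix(FALSE, d[1], d[2]); reached_m[reached] <- TRUE
  reached_m & suitable
}

# small fixture builders -------------------------------------------------

tiny_grid <- function(values, cell = 1000) rs_grid(values, cell, c(0, 0))

# occurrence table from bare coordinates
pts <- function(x, y, unc = 0, year = 2015) {
  data.frame(id = sprintf("p%03d", seq_along(x)), x = x, y = y,
             year = year, uncertainty_m = unc, stringsAsFactors = FALSE)
}

# random 0/1 grid pair sharing geometry, possibly with nodata
random_binary_pair <- function(n, p_na = 0.05) {
  mk <- function() {
    v <- matrix(rbinom(n * n, 1, 0.4), n, n)
    v[matrix(runif(n * n) < p_na, n, n)] <- NA
    g <- tiny_grid(v)
    class(g) <- c("rs_binary", class(g))
    g
  }
  list(a = mk(), b = mk())
}
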