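#' @useDynLib riversdm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis rexp runif rnorm quantile
NULL

# Evaluate expr with a private RNG stream: the global .Random.seed is
# restored afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer seed is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Smoothed Gaussian random field
#'
#' White noise convolved with an isotropic Gaussian kernel whose standard
#' deviation is `corr_len` cells; `corr_len = 0` returns the white noise
#' unchanged. Edges are renormalized by the in-bounds kernel mass.
#'
#' @param n_rows,n_cols field size in cells.
#' @param corr_len spatial correlation length in cells (kernel sd).
#' @return numeric matrix, approximately zero mean and unit variance.
#' @keywords internal
gaussian_field <- function(n_rows, n_cols, corr_len) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_len <= 0) return(z)
  r <- max(1L, ceiling(3 * corr_len))
  off <- -r:r
  k <- exp(-(off^2) / (2 * corr_len^2))
  smooth1d <- function(m, along_rows) {
    if (!along_rows) m <- t(m)
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m)); wt <- matrix(0, n, ncol(m))
    for (i in seq_along(off)) {
      s <- off[i]
      src <- seq_len(n) + s
      ok <- src >= 1L & src <= n
      acc[ok, ] <- acc[ok, ] + k[i] * m[src[ok], ]
      wt[ok, ] <- wt[ok, ] + k[i]
    }
    out <- acc / wt
    if (!along_rows) t(out) else out
  }
  z <- smooth1d(smooth1d(z, TRUE), FALSE)
  (z - mean(z)) / stats::sd(z)
}

default_predictor_ranges <- function() {
  list(bio3  = c(30, 60),    # isothermality (%)
       bio4  = c(300, 700),  # temperature seasonality (sd x 100)
       bio8  = c(5, 25),     # mean temperature of wettest quarter (degC)
       bio9  = c(0, 20),     # mean temperature of driest quarter (degC)
       bio15 = c(10, 60),    # precipitation seasonality (%)
       bio19 = c(100, 500),  # precipitation of coldest quarter (mm)
       elevation = c(0, 2500))
}

#' Generate a synthetic riverine landscape
#'
#' Builds a seeded landscape bundle with known ground truth: correlated
#' continuous predictors (bioclimate-like layers plus elevation), a 6-class
#' land-use layer (1 forest, 2 grassland, 3 farmland, 4 urban, 5 water,
#' 6 barren) obtained by equal-quantile binning of a smooth field, a
#' connected one-cell-wide river crossing the grid, a two-basin partition
#' split by a ridge line, and dam cells on the river. The generating logistic
#' coefficients (`truth_beta`) default to a range-restricted specialist
#' (intercept -3, so roughly a sixth of the river buffer is highly suitable)
#' responding positively to isothermality and winter precipitation and
#' negatively to temperature seasonality — the directions that matter for
#' semi-aquatic mammals.
#'
#' @param n_rows,n_cols grid size in cells (>= 8).
#' @param cell_size cell edge (m); default 1000.
#' @param seed integer seed (required).
#' @param corr_len spatial correlation length in cells.
#' @param predictor_ranges named list of `c(min, max)` per predictor.
#' @param truth_beta named coefficients of the generating logistic model;
#'   must include `intercept`, other names must match predictors.
#' @param n_dams number of dam cells to place on the river.
#' @return an object of class `rs_landscape`.
#' @export
make_landscape <- function(n_rows = 32, n_cols = 32, cell_size = 1000,
                           seed, corr_len = 2,
                           predictor_ranges = default_predictor_ranges(),
                           truth_beta = c(intercept = -3, bio3 = 2,
                                          bio4 = -2, bio19 = 2),
                           n_dams = 2) {
  if (missing(seed)) stop("seed is required")
  if (n_rows < 8 || n_cols < 8) stop("landscape must be at least 8x8 cells")
  if (!"intercept" %in% names(truth_beta))
    stop("truth_beta must contain an 'intercept' entry")
  extra <- setdiff(setdiff(names(truth_beta), "intercept"),
                   names(predictor_ranges))
  if (length(extra))
    stop("truth_beta names missing from predictors: ",
         paste(extra, collapse = ", "))
  with_seed(seed, {
    g0 <- function(v) rs_grid(v, cell_size, c(0, 0))
    predictors <- lapply(predictor_ranges, function(rng) {
      f <- gaussian_field(n_rows, n_cols, corr_len)
      f <- (f - min(f)) / (max(f) - min(f))     # -> [0, 1]
      g0(rng[1] + f * (rng[2] - rng[1]))
    })
    # land use: quantile-bin a fresh smooth field so all six classes occur
    lf <- gaussian_field(n_rows, n_cols, corr_len)
    qs <- quantile(lf, probs = seq(0, 1, length.out = 7))
    lu <- matrix(as.numeric(cut(lf, qs, include.lowest = TRUE, labels = FALSE)),
                 n_rows, n_cols)
    # river: 4-connected meandering path from the west to the east edge
    # (vertical runs up to 2 cells per column give a realistically long
    # channel, hence a usable analysis buffer even on small grids)
    river <- matrix(0, n_rows, n_cols)
    r <- sample(seq(max(2L, n_rows %/% 4), n_rows - max(1L, n_rows %/% 4)), 1)
    for (cc in seq_len(n_cols)) {
      river[r, cc] <- 1
      if (cc < n_cols) {
        step <- sample(-2:2, 1, prob = c(0.15, 0.2, 0.3, 0.2, 0.15))
        r2 <- min(max(r + step, 1L), n_rows)
        if (r2 != r)                       # keep the path 4-connected
          river[seq(min(r, r2), max(r, r2)), cc] <- 1
        r <- r2
      }
    }
    # basins: ridge line (smoothly wiggling column boundary) splits the grid
    wig <- round(cumsum(sample(-1:1, n_rows, replace = TRUE)) / 2)
    bnd <- pmin(pmax(n_cols %/% 2 + wig, 2L), n_cols - 2L)
    basin <- matrix(2, n_rows, n_cols)
    for (i in seq_len(n_rows)) basin[i, seq_len(bnd[i])] <- 1
    # dams: cells on the river, spread along it
    dam <- matrix(0, n_rows, n_cols)
    rc <- which(river == 1, arr.ind = TRUE)
    rc <- rc[order(rc[, 2], rc[, 1]), , drop = FALSE]
    if (n_dams > 0 && nrow(rc) > 2) {
      pick <- unique(round(seq(2, nrow(rc) - 1, length.out = n_dams)))
      dam[rc[pick, , drop = FALSE]] <- 1
    }
    structure(
      list(predictors = predictors, landuse = g0(lu), river_mask = g0(river),
           basin_id = g0(basin), dam_mask = g0(dam),
           truth_beta = truth_beta, seed = as.integer(seed)),
      class = "rs_landscape")
  })
}

#' @export
print.rs_landscape <- function(x, ...) {
  d <- dim(x$predictors[[1]]$values)
  cat(sprintf(
    "<rs_landscape> %d x %d cells, %d predictors (%s), seed %d\n",
    d[1], d[2], length(x$predictors),
    paste(names(x$predictors), collapse = ", "), x$seed))
  invisible(x)
}

#' True habitat suitability of a synthetic landscape
#'
#' Evaluates the generating logistic model per cell:
#' `suitability = plogis(intercept + sum_j beta_j * z_j)` where `z_j` is the
#' predictor standardized over the analysis region (the river buffer).
#' Cells outside the buffer are nodata.
#'
#' @param bundle an `rs_landscape`.
#' @param beta optional coefficient override (same format as `truth_beta`).
#' @param buffer_m river buffer radius in metres (default 1000).
#' @return suitability `rs_grid` with values in \[0, 1\] inside the buffer.
#' @export
simulate_truth <- function(bundle, beta = NULL, buffer_m = 1000) {
  beta <- if (is.null(beta)) bundle$truth_beta else beta
  if (!"intercept" %in% names(beta))
    stop("beta must contain an 'intercept' entry")
  vars <- setdiff(names(beta), "intercept")
  missing_vars <- setdiff(vars, names(bundle$predictors))
  if (length(missing_vars))
    stop("beta names a predictor not in the bundle: ",
         paste(missing_vars, collapse = ", "))
  buf <- river_buffer(bundle$river_mask, buffer_m)
  inside <- buf$values == 1
  eta <- matrix(beta[["intercept"]], nrow(inside), ncol(inside))
  for (v in vars) {
    vals <- bundle$predictors[[v]]$values
    mu <- mean(vals[inside]); sdv <- stats::sd(vals[inside])
    z <- if (is.na(sdv) || sdv == 0) 0 * vals else (vals - mu) / sdv
    eta <- eta + beta[[v]] * z
  }
  p <- plogis(eta)
  p[!inside] <- NA_real_
  grid_like(bundle$river_mask, p)
}

#' Sample presence-only occurrence records from a truth surface
#'
#' Each record's cell is drawn (with replacement — repeat surveys of the
#' same reach are the norm in field data) with probability proportional to
#' true suitability; the point is jittered uniformly within its cell and
#' assigned a positional uncertainty radius from a truncated exponential
#' model. Under the defaults (mean 120 m, cap 600 m) roughly one record in
#' eight exceeds the 250 m accuracy cut-off, so downstream filtering is
#' always exercised.
#'
#' @param truth suitability `rs_grid` (nodata outside the analysis region).
#' @param n number of records (>= 1; requires at least one cell with
#'   positive suitability).
#' @param uncertainty_mean,uncertainty_max truncated-exponential uncertainty
#'   model (metres).
#' @param seed integer seed (required).
#' @param years inclusive sampling period for record years.
#' @return data.frame with columns `id, x, y, year, uncertainty_m`.
#' @export
sample_occurrences <- function(truth, n, uncertainty_mean = 120,
                               uncertainty_max = 600, seed,
                               years = c(2013, 2020)) {
  if (missing(seed)) stop("seed is required")
  if (n < 1) stop("n must be >= 1")
  ok <- which(!is.na(truth$values) & truth$values > 0)
  if (!length(ok))
    stop("no cells with positive suitability to sample from")
  with_seed(seed, {
    cells <- sample(ok, n, replace = TRUE, prob = truth$values[ok])
    rc <- arrayInd(cells, dim(truth$values))
    cs <- truth$cell_size
    x <- truth$origin[1] + (rc[, 2] - 1) * cs + runif(n) * cs
    y <- truth$origin[2] + (rc[, 1] - 1) * cs + runif(n) * cs
    data.frame(
      id = sprintf("occ%05d", seq_len(n)),
      x = x, y = y,
      year = sample(seq(years[1], years[2]), n, replace = TRUE),
      uncertainty_m = pmin(rexp(n, rate = 1 / uncertainty_mean),
                           uncertainty_max),
      stringsAsFactors = FALSE)
  })
}

scenario_levels <- function() {
  list(climate = c("RCP2.6", "RCP8.5"),
       landuse = c("A2", "B1"),
       gcm = c("CCSM4", "IPSL-CM5A-LR", "MIROC-ESM-CHEM"))
}

#' Project a landscape to a future scenario
#'
#' Deterministic perturbation of a current landscape standing in for a
#' 2050 climate/land-use forecast. Each continuous predictor receives an
#' additive change `sd_j * magnitude * (0.6 * direction_j + 0.4 * gradient)`
#' where the magnitude scales with climate-scenario severity (RCP8.5 >
#' RCP2.6), the per-predictor direction and the gradient orientation depend
#' on the GCM label, and land-use classes are reassigned on a fraction of
#' cells scaling with land-use-scenario severity (A2 > B1). The output is a
#' pure function of (bundle, scenario labels, bundle seed).
#'
#' @param bundle an `rs_landscape`.
#' @param climate `"RCP2.6"` or `"RCP8.5"`.
#' @param landuse `"A2"` (pessimistic) or `"B1"` (optimistic).
#' @param gcm one of `"CCSM4"`, `"IPSL-CM5A-LR"`, `"MIROC-ESM-CHEM"`.
#' @param magnitude optional override of the climate perturbation magnitude
#'   (in predictor-sd units); `0` returns the bundle unchanged apart from
#'   land use, which is also frozen when `landuse_fraction = 0`.
#' @param landuse_fraction optional override of the reassigned-cell fraction.
#' @return a future `rs_landscape`, aligned with the input.
#' @export
make_future <- function(bundle, climate = c("RCP2.6", "RCP8.5"),
                        landuse = c("A2", "B1"),
                        gcm = c("CCSM4", "IPSL-CM5A-LR", "MIROC-ESM-CHEM"),
                        magnitude = NULL, landuse_fraction = NULL) {
  climate <- match.arg(climate)
  landuse <- match.arg(landuse)
  gcm <- match.arg(gcm)
  lev <- scenario_levels()
  ci <- match(climate, lev$climate)
  li <- match(landuse, lev$landuse)
  gi <- match(gcm, lev$gcm)
  if (is.null(magnitude))
    magnitude <- c("RCP2.6" = 0.4, "RCP8.5" = 1.2)[[climate]]
  if (is.null(landuse_fraction))
    landuse_fraction <- c(A2 = 0.15, B1 = 0.05)[[landuse]]
  d <- dim(bundle$landuse$values)
  theta <- (gi - 1) * 2 * pi / 3
  gx <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  gy <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  grad <- sin(theta) * (gx - (d[2] + 1) / 2) / d[2] +
          cos(theta) * (gy - (d[1] + 1) / 2) / d[1]
  out <- bundle
  for (j in seq_along(bundle$predictors)) {
    g <- bundle$predictors[[j]]
    sdv <- stats::sd(g$values)
    dir_j <- cos(theta + 0.9 * j)     # GCM-dependent per-predictor direction
    delta <- sdv * magnitude * (0.6 * dir_j + 0.4 * grad)
    out$predictors[[j]] <- grid_like(g, g$values + delta)
  }
  if (landuse_fraction > 0) {
    n_cells <- prod(d)
    n_flip <- round(landuse_fraction * n_cells)
    if (n_flip > 0) {
      lu <- bundle$landuse$values
      with_seed(bundle$seed + 7919L * gi + 104729L * li + 1299709L * ci, {
        flip <- sample.int(n_cells, n_flip)
        lu[flip] <- sample(1:6, n_flip, replace = TRUE)
      })
      out$landuse <- grid_like(bundle$landuse, lu)
    }
  }
  out
}
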