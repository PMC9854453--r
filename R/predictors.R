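# minimum cell-centre distance (m) from every cell to a set of target cells
min_dist_to_cells <- function(grid, target_idx) {
  d <- dim(grid$values)
  cs <- grid$cell_size
  ys <- grid$origin[2] + (seq_len(d[1]) - 0.5) * cs
  xs <- grid$origin[1] + (seq_len(d[2]) - 0.5) * cs
  best <- matrix(Inf, d[1], d[2])
  for (t in seq_len(nrow(target_idx))) {
    dy2 <- (ys - ys[target_idx[t, 1]])^2
    dx2 <- (xs - xs[target_idx[t, 2]])^2
    best <- pmin(best, outer(dy2, dx2, "+"))
  }
  sqrt(best)
}

#' Euclidean distance to a land-use class
#'
#' Converts a categorical land-use layer to a continuous predictor: each
#' cell's value is the exact cell-centre-to-cell-centre Euclidean distance
#' (metres) to the nearest cell of `class_code` (0 on class cells).
#'
#' @param landuse `rs_grid` of integer class codes.
#' @param class_code class to measure distance to.
#' @return distance `rs_grid` in metres.
#' @export
distance_to_class <- function(landuse, class_code) {
  idx <- which(!is.na(landuse$values) & landuse$values == class_code,
               arr.ind = TRUE)
  if (!nrow(idx))
    stop(sprintf("class %s is absent from the land-use raster", class_code))
  grid_like(landuse, min_dist_to_cells(landuse, idx))
}

pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

#' Terrain slope (degrees) by Horn's 3x3 stencil
#'
#' Gradient components use Horn's weighted differences on the 3x3
#' neighbourhood; edge cells use replicated (available) neighbours, so edge
#' slopes are one-sided approximations.
#'
#' @param elev elevation `rs_grid` (metres).
#' @export
terrain_slope <- function(elev) {
  v <- pad_replicate(elev$values)
  nr <- nrow(elev$values); nc <- ncol(elev$values)
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  # storage row + 1 = north; column + 1 = east
  dzdx <- ((v[i + 1, j + 1] + 2 * v[i, j + 1] + v[i - 1, j + 1]) -
           (v[i + 1, j - 1] + 2 * v[i, j - 1] + v[i - 1, j - 1])) /
    (8 * elev$cell_size)
  dzdy <- ((v[i + 1, j - 1] + 2 * v[i + 1, j] + v[i + 1, j + 1]) -
           (v[i - 1, j - 1] + 2 * v[i - 1, j] + v[i - 1, j + 1])) /
    (8 * elev$cell_size)
  grid_like(elev, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

#' Terrain roughness (3x3 max - min elevation)
#' @param elev elevation `rs_grid` (metres).
#' @export
terrain_roughness <- function(elev) {
  v <- pad_replicate(elev$values)
  nr <- nrow(elev$values); nc <- ncol(elev$values)
  hi <- matrix(-Inf, nr, nc); lo <- matrix(Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    w <- v[2:(nr + 1) + di, 2:(nc + 1) + dj]
    hi <- pmax(hi, w); lo <- pmin(lo, w)
  }
  grid_like(elev, hi - lo)
}

#' River buffer mask
#'
#' Cells whose centre lies within `radius_m` of any river cell centre
#' (the 1 km analysis clip around the hydrographic network, by default).
#'
#' @param river_mask `rs_grid` of 0/1.
#' @param radius_m buffer radius in metres.
#' @return 0/1 `rs_grid`.
#' @export
river_buffer <- function(river_mask, radius_m = 1000) {
  if (radius_m < 0) stop("radius_m must be >= 0")
  idx <- which(!is.na(river_mask$values) & river_mask$values == 1,
               arr.ind = TRUE)
  if (!nrow(idx)) stop("river mask is empty")
  dist <- min_dist_to_cells(river_mask, idx)
  grid_like(river_mask, (dist <= radius_m) * 1)
}

#' The 14-variable semi-aquatic-mammal predictor preset
#'
#' Returns the named 14-variable configuration (six bioclimate layers,
#' slope, elevation and the six land-use distances) conventionally
#' retained after collinearity screening for Iberian semi-aquatic
#' mammals. A preset, not a hard-coded outcome: `vif_select()` still runs
#' on whatever is supplied.
#' @param name preset name (only `"paper14"`).
#' @export
predictor_preset <- function(name = "paper14") {
  if (name != "paper14") stop("unknown predictor preset: ", name)
  c("bio3", "bio4", "bio8", "bio9", "bio15", "bio19",
    "slope", "elevation",
    "dist_forest", "dist_grassland", "dist_farmland",
    "dist_urban", "dist_water", "dist_barren")
}

landuse_class_names <- function() {
  c("forest", "grassland", "farmland", "urban", "water", "barren")
}

#' Build the predictor stack for a landscape
#'
#' Assembles the analysis layers from a landscape bundle: its continuous
#' predictors, slope and roughness derived from elevation (when present),
#' and the six distance-to-land-use-class transforms; the analysis mask is
#' the river buffer. Land-use classes absent from the raster are skipped
#' with a warning.
#'
#' @param bundle an `rs_landscape`.
#' @param buffer_m river buffer radius (m).
#' @return an `rs_stack`: list with named `layers` and 0/1 `mask`.
#' @export
build_predictor_stack <- function(bundle, buffer_m = 1000) {
  layers <- bundle$predictors
  if ("elevation" %in% names(layers)) {
    layers$slope <- terrain_slope(layers$elevation)
    layers$roughness <- terrain_roughness(layers$elevation)
  }
  cls <- landuse_class_names()
  for (k in seq_along(cls)) {
    nm <- paste0("dist_", cls[k])
    if (any(bundle$landuse$values == k, na.rm = TRUE))
      layers[[nm]] <- distance_to_class(bundle$landuse, k)
    else
      warning(sprintf("land-use class %d (%s) absent; %s layer skipped",
                      k, cls[k], nm))
  }
  structure(list(layers = layers,
                 mask = river_buffer(bundle$river_mask, buffer_m)),
            class = "rs_stack")
}

#' Restrict a stack to named layers
#' @param stack an `rs_stack`.
#' @param keep layer names to retain (in `keep` order where present).
#' @export
subset_stack <- function(stack, keep) {
  keep <- intersect(keep, names(stack$layers))
  stack$layers <- stack$layers[keep]
  stack
}

#' Extract feature values at occurrence points
#'
#' Looks up every stack layer at each point's containing cell. Points that
#' fall outside the grid, on a masked cell or on any nodata cell are
#' dropped with a warning (the dropped count is kept as an attribute).
#'
#' @param stack an `rs_stack`.
#' @param presences,background occurrence tables (labels 1 and 0).
#' @return data.frame `id, label, <layer columns>` of class `rs_features`,
#'   with attributes `layers` and `n_dropped`.
#' @export
extract_features <- function(stack, presences, background) {
  mk <- function(tab, label) {
    tab <- as_occurrence_table(tab)[, c("id", "x", "y")]
    tab$label <- rep(label, nrow(tab))
    tab
  }
  pts <- rbind(mk(presences, 1), mk(background, 0))
  vals <- sapply(stack$layers, function(g) extract_at(g, pts$x, pts$y))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(pts))
  colnames(vals) <- names(stack$layers)
  inside <- extract_at(stack$mask, pts$x, pts$y)
  ok <- !is.na(inside) & inside == 1 & rowSums(is.na(vals)) == 0
  n_drop <- sum(!ok)
  if (n_drop > 0)
    warning(sprintf("%d point(s) on masked or nodata cells dropped", n_drop))
  out <- data.frame(id = pts$id[ok], label = pts$label[ok],
                    vals[ok, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, layers = names(stack$layers), n_dropped = n_drop,
            class = c("rs_features", "data.frame"))
}

feature_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), c("id", "label")), drop = FALSE])
}

vif_of <- function(X) {
  # VIF_j = 1 / (1 - R2_j) with R2_j from OLS of column j on the others
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    yj <- X[, j]
    if (stats::sd(yj) == 0) return(Inf)
    if (p == 1L) return(1)
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor selection
#'
#' Repeatedly drops the layer with the largest VIF (`1 / (1 - R^2)` of that
#' layer regressed on all other retained layers) while the maximum exceeds
#' `threshold`. Constant layers carry infinite VIF and are dropped first,
#' with a warning. Ties break towards the first-listed layer; survivors are
#' returned in input order.
#'
#' @param table an `rs_features` table (VIF is computed on the combined
#'   presence + background rows) or a plain numeric matrix.
#' @param threshold VIF cut-off (default 5).
#' @return character vector of retained layer names.
#' @export
vif_select <- function(table, threshold = 5) {
  X <- if (is.matrix(table)) table else feature_matrix(table)
  if (ncol(X) < 2) stop("need at least 2 candidate layers")
  if (nrow(X) <= ncol(X)) stop("need more rows than layers")
  keep <- colnames(X)
  if (is.null(keep)) keep <- paste0("V", seq_len(ncol(X)))
  colnames(X) <- keep
  const <- vapply(keep, function(nm) stats::sd(X[, nm]) == 0, logical(1))
  if (any(const)) {
    warning("constant layer(s) dropped (infinite VIF): ",
            paste(keep[const], collapse = ", "))
    keep <- keep[!const]
  }
  while (length(keep) >= 2) {
    v <- vif_of(X[, keep, drop = FALSE])
    if (max(v) <= threshold) break
    keep <- keep[-which.max(v)]
  }
  keep
}
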