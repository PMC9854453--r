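#' Occurrence tables
#'
#' Occurrences are plain data.frames with columns
#' `id, x, y, year, uncertainty_m` (projected metres; uncertainty is a
#' positional radius). `as_occurrence_table()` validates the contract.
#'
#' @param df a data.frame.
#' @return the validated data.frame.
#' @export
as_occurrence_table <- function(df) {
  need <- c("id", "x", "y", "year", "uncertainty_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("occurrence ids must be unique")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("occurrence coordinates must be finite")
  if (any(df$uncertainty_m < 0)) stop("uncertainty_m must be non-negative")
  df
}

#' Filter occurrences by positional uncertainty
#'
#' Retains records whose uncertainty radius is *strictly* below
#' `max_radius_m` (the conventional "less than 250 m" accuracy rule).
#' Record order is preserved; idempotent.
#'
#' @param occ occurrence table.
#' @param max_radius_m accuracy cut-off in metres (default 250).
#' @export
filter_uncertainty <- function(occ, max_radius_m = 250) {
  if (max_radius_m <= 0) stop("max_radius_m must be positive")
  occ <- as_occurrence_table(occ)
  occ[occ$uncertainty_m < max_radius_m, , drop = FALSE]
}

# squared-distance matrix of a point set (planar metres)
pairwise_dist2 <- function(x, y) {
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  dx * dx + dy * dy
}

#' Spatially thin occurrence records
#'
#' Enforces a species-specific minimum inter-record distance (e.g. 2 km for
#' a poor disperser, 20 km for a wide-ranging one) by a randomized removal
#' heuristic in the style of spThin: while any pair lies closer than
#' `min_dist_m`, delete one member of the *closest* conflicting pair
#' (random tie-break). The heuristic is restarted `reps` times and the run
#' retaining the most records wins. Euclidean distance on projected metres.
#'
#' @param occ occurrence table.
#' @param min_dist_m minimum allowed pairwise distance (m).
#' @param reps number of randomized restarts (default 100).
#' @param seed integer seed (required; output is deterministic given it).
#' @export
thin_occurrences <- function(occ, min_dist_m, reps = 100, seed) {
  if (missing(seed)) stop("seed is required")
  if (min_dist_m <= 0) stop("min_dist_m must be positive")
  if (reps < 1) stop("reps must be >= 1")
  occ <- as_occurrence_table(occ)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  d2 <- pairwise_dist2(occ$x, occ$y)
  lim2 <- min_dist_m^2
  # conflicting pairs once, sorted by distance: removals never create new
  # conflicts, so the closest surviving pair is always the first alive pair
  # in this order and each restart is a single sweep.
  conf <- which(upper.tri(d2) & d2 < lim2, arr.ind = TRUE)
  if (!nrow(conf)) return(occ)
  ord <- order(d2[conf])
  conf <- conf[ord, , drop = FALSE]
  dsort <- d2[conf]
  k <- nrow(conf)
  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(reps)) {
      alive <- rep(TRUE, n)
      i <- 1L
      while (i <= k) {
        if (alive[conf[i, 1]] && alive[conf[i, 2]]) {
          # tie group: alive pairs sharing the current minimal distance
          j <- i
          while (j < k && dsort[j + 1L] == dsort[i]) j <- j + 1L
          grp <- i:j
          grp <- grp[alive[conf[grp, 1]] & alive[conf[grp, 2]]]
          pick <- if (length(grp) == 1L) grp else
            grp[sample.int(length(grp), 1)]
          victim <- conf[pick, sample(1:2, 1)]
          alive[victim] <- FALSE
        } else i <- i + 1L
      }
      if (is.null(best) || sum(alive) > sum(best)) best <- alive
    }
    occ[best, , drop = FALSE]
  })
}

#' Sample background (pseudo-absence) points
#'
#' Places `n` points uniformly over the accessible area: cells are drawn
#' with replacement from the mask and each point is jittered uniformly
#' within its cell (two records may share a cell).
#'
#' @param accessible_mask `rs_grid` of 0/1 (1 = accessible).
#' @param n number of points (default 10000).
#' @param seed integer seed (required).
#' @return occurrence table with `uncertainty_m = 0` and `year = NA`.
#' @export
sample_background <- function(accessible_mask, n = 10000, seed) {
  if (missing(seed)) stop("seed is required")
  if (n < 1) stop("n must be >= 1")
  ok <- which(!is.na(accessible_mask$values) & accessible_mask$values == 1)
  if (!length(ok)) stop("accessible mask is empty")
  with_seed(seed, {
    cells <- ok[sample.int(length(ok), n, replace = TRUE)]
    rc <- arrayInd(cells, dim(accessible_mask$values))
    cs <- accessible_mask$cell_size
    data.frame(
      id = sprintf("bg%06d", seq_len(n)),
      x = accessible_mask$origin[1] + (rc[, 2] - 1) * cs + runif(n) * cs,
      y = accessible_mask$origin[2] + (rc[, 1] - 1) * cs + runif(n) * cs,
      year = NA_integer_,
      uncertainty_m = 0,
      stringsAsFactors = FALSE)
  })
}

#' Checkerboard2 spatial cross-validation folds
#'
#' Assigns each point to one of four folds from two nested checkerboards:
#' `fold = 2 * parity(coarse block) + parity(fine block)`, where a block's
#' parity is `(block_row + block_col) mod 2` and block indices come from
#' floor division of grid-relative coordinates by the block edge
#' (`fine_cells` / `coarse_cells` raster cells; half-open intervals, so
#' boundary points belong to the upper/right block).
#'
#' @param points occurrence table.
#' @param grid reference `rs_grid` supplying origin and cell size.
#' @param coarse_cells,fine_cells block edge lengths in raster cells
#'   (`coarse_cells > fine_cells >= 1`).
#' @return data.frame `id, fold` with `fold` in 0..3.
#' @export
checkerboard2 <- function(points, grid, coarse_cells = 8, fine_cells = 2) {
  points <- as_occurrence_table(points)
  if (!(coarse_cells > fine_cells && fine_cells >= 1))
    stop("need coarse_cells > fine_cells >= 1")
  d <- dim(grid$values)
  rel_x <- points$x - grid$origin[1]
  rel_y <- points$y - grid$origin[2]
  inside <- rel_x >= 0 & rel_y >= 0 &
    rel_x < d[2] * grid$cell_size & rel_y < d[1] * grid$cell_size
  if (any(!inside))
    stop("points outside the grid: ",
         paste(points$id[!inside], collapse = ", "))
  parity <- function(block_edge_m) {
    bx <- floor(rel_x / block_edge_m)
    by <- floor(rel_y / block_edge_m)
    (bx + by) %% 2
  }
  fold <- 2 * parity(coarse_cells * grid$cell_size) +
    parity(fine_cells * grid$cell_size)
  data.frame(id = points$id, fold = as.integer(fold),
             stringsAsFactors = FALSE)
}

#' Read/write occurrence CSV
#' @param occ occurrence table.
#' @param path CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as_occurrence_table(occ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  as_occurrence_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
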