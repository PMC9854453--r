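#' Dispersal configuration
#'
#' Parameters of the cellular-automaton range projection: annual dispersal
#' distance (reference values: 2 km for the poor-dispersing prey, 20 km for
#' the wide-ranging predator), reproductive maturity in steps before a cell
#' can seed colonization, number of yearly steps to the projection horizon,
#' and the barrier policy (`"none"`; `"cells_block"` — the straight segment
#' between source and target centres must not cross a barrier cell;
#' `"basins_and_dams"` — source and target must share a basin unless a
#' dam-free river path connects them).
#'
#' @param dispersal_distance_m per-step colonization radius (m).
#' @param maturity_steps steps since colonization before a cell is a source.
#' @param n_steps number of steps (years).
#' @param barrier_mode barrier policy.
#' @param stochastic colonize with probability `p_colonize` per attempt
#'   instead of deterministically (off by default; the automaton is then
#'   seeded).
#' @param p_colonize per-step colonization probability in stochastic mode.
#' @param seed integer seed (only used in stochastic mode).
#' @export
dispersal_config <- function(dispersal_distance_m, maturity_steps = 1,
                             n_steps = 1,
                             barrier_mode = c("none", "cells_block",
                                              "basins_and_dams"),
                             stochastic = FALSE, p_colonize = 1,
                             seed = NULL) {
  barrier_mode <- match.arg(barrier_mode)
  if (dispersal_distance_m <= 0) stop("dispersal_distance_m must be > 0")
  if (maturity_steps < 1) stop("maturity_steps must be >= 1")
  if (n_steps < 1) stop("n_steps must be >= 1")
  structure(list(dispersal_distance_m = dispersal_distance_m,
                 maturity_steps = as.integer(maturity_steps),
                 n_steps = as.integer(n_steps),
                 barrier_mode = barrier_mode, stochastic = stochastic,
                 p_colonize = p_colonize, seed = seed),
            class = "rs_dispersal_config")
}

# 8-connected component labels over TRUE cells; NA elsewhere
label_components <- function(mask) {
  d <- dim(mask)
  comp <- matrix(NA_integer_, d[1], d[2])
  nxt <- 0L
  for (start in which(mask)) {
    if (!is.na(comp[start])) next
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      rc <- arrayInd(cell, d)
      for (di in -1:1) for (dj in -1:1) {
        r <- rc[1] + di; c <- rc[2] + dj
        if (r >= 1 && r <= d[1] && c >= 1 && c <= d[2] &&
            mask[r, c] && is.na(comp[r, c])) {
          comp[r, c] <- nxt
          queue <- c(queue, (c - 1L) * d[1] + r)
        }
      }
    }
  }
  comp
}

# does the straight segment between two cell centres cross a barrier cell?
segment_blocked <- function(r1, c1, r2, c2, barrier) {
  n <- max(2L, 4L * max(abs(r2 - r1), abs(c2 - c1)) + 1L)
  ts <- seq(0, 1, length.out = n)
  rr <- round(r1 + ts * (r2 - r1))
  cc <- round(c1 + ts * (c2 - c1))
  any(barrier[cbind(rr, cc)])
}

#' Dispersal-constrained range projection (cellular automaton)
#'
#' MigClim-style deterministic automaton. Each yearly step: (1) occupied
#' cells unsuitable this step are decolonized (age reset); (2) cells with
#' age >= `maturity_steps` act as sources; (3) every unoccupied suitable
#' cell whose centre lies within the dispersal distance of a source centre
#' and is admissible under the barrier policy is colonized at age 1;
#' (4) surviving occupied cells age by one. Initial cells start at age
#' `maturity_steps` so the current range can seed colonization immediately.
#'
#' @param initial binary range grid seeding the simulation.
#' @param suitability_steps a binary suitability grid, or a list of one per
#'   step (a single grid is recycled over all steps).
#' @param config an [dispersal_config()].
#' @param basin_id integer `rs_grid` of basin labels (for
#'   `"basins_and_dams"`).
#' @param dam_mask 0/1 `rs_grid` of dam/barrier cells.
#' @param river_mask 0/1 `rs_grid` of river cells (for the dam-free
#'   river-path exception in `"basins_and_dams"`).
#' @return list with `final` (binary grid), `counts` (per-step data.frame:
#'   step, occupied, colonized, decolonized) and `age` (integer grid).
#' @export
disperse <- function(initial, suitability_steps, config,
                     basin_id = NULL, dam_mask = NULL, river_mask = NULL) {
  check_binary(initial)
  if (is_rs_grid(suitability_steps)) suitability_steps <-
      list(suitability_steps)
  if (!length(suitability_steps)) stop("at least one suitability step needed")
  for (s in suitability_steps) stop_if_misaligned(initial, s)
  if (length(suitability_steps) == 1L)
    suitability_steps <- rep(suitability_steps, config$n_steps)
  if (length(suitability_steps) != config$n_steps)
    stop("need one suitability map, or one per step")
  d <- dim(initial$values)
  cs <- initial$cell_size
  if (config$barrier_mode == "basins_and_dams") {
    if (is.null(basin_id) || is.null(dam_mask) || is.null(river_mask))
      stop("basins_and_dams needs basin_id, dam_mask and river_mask")
    stop_if_misaligned(initial, basin_id, dam_mask, river_mask)
    river_open <- !is.na(river_mask$values) & river_mask$values == 1 &
      !(dam_mask$values %in% 1)
    rcomp <- label_components(river_open)
    basin <- basin_id$values
  } else if (config$barrier_mode == "cells_block") {
    if (is.null(dam_mask)) stop("cells_block needs dam_mask (barrier cells)")
    stop_if_misaligned(initial, dam_mask)
    barrier <- !is.na(dam_mask$values) & dam_mask$values == 1
  }
  admissible <- switch(config$barrier_mode,
    none = function(src, tgt) TRUE,
    basins_and_dams = function(src, tgt) {
      if (identical(basin[src], basin[tgt])) return(TRUE)
      !is.na(rcomp[src]) && !is.na(rcomp[tgt]) &&
        rcomp[src] == rcomp[tgt]
    },
    cells_block = function(src, tgt) {
      a <- arrayInd(src, d); b <- arrayInd(tgt, d)
      !segment_blocked(a[1], a[2], b[1], b[2], barrier)
    })
  run <- function() {
    occupied <- !is.na(initial$values) & initial$values == 1
    age <- matrix(0L, d[1], d[2])
    age[occupied] <- config$maturity_steps
    lim2 <- (config$dispersal_distance_m / cs)^2  # in cell units
    rows <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
    cols <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    counts <- data.frame(step = integer(), occupied = integer(),
                         colonized = integer(), decolonized = integer())
    for (t in seq_len(config$n_steps)) {
      suit <- !is.na(suitability_steps[[t]]$values) &
        suitability_steps[[t]]$values == 1
      deco <- occupied & !suit
      occupied[deco] <- FALSE
      age[deco] <- 0L
      sources <- which(occupied & age >= config$maturity_steps)
      newly <- integer(0)
      if (length(sources)) {
        cand <- which(!occupied & suit)
        if (length(cand)) {
          sr <- rows[sources]; sc <- cols[sources]
          for (cell in cand) {
            d2 <- (rows[cell] - sr)^2 + (cols[cell] - sc)^2
            near <- sources[d2 <= lim2]
            ok <- FALSE
            for (s in near) if (admissible(s, cell)) { ok <- TRUE; break }
            if (ok && (!config$stochastic ||
                       stats::runif(1) < config$p_colonize))
              newly <- c(newly, cell)
          }
        }
      }
      age[occupied] <- age[occupied] + 1L
      occupied[newly] <- TRUE
      age[newly] <- 1L
      counts <- rbind(counts, data.frame(
        step = t, occupied = sum(occupied),
        colonized = length(newly), decolonized = sum(deco)))
    }
    final <- grid_like(initial, occupied * 1)
    final$values[is.na(initial$values) &
                   is.na(suitability_steps[[config$n_steps]]$values)] <-
      NA_real_
    class(final) <- c("rs_binary", class(final))
    list(final = final, counts = counts, age = grid_like(initial, age))
  }
  if (config$stochastic) {
    if (is.null(config$seed)) stop("stochastic mode needs a seed")
    with_seed(config$seed, run())
  } else run()
}

#' Unlimited (dispersal-free) projection
#'
#' Identity pass-through of a future binary map, the comparator used to
#' quantify how much the dispersal constraint withholds.
#' @param future_binary binary range grid.
#' @export
unlimited_projection <- function(future_binary) {
  check_binary(future_binary)
  future_binary
}
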