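#' Default (demo-scale) run configuration
#'
#' A complete, JSON-serializable configuration for the end-to-end pipeline
#' on a synthetic landscape: two species — a poor-dispersing, basin-bound
#' prey (desman-like) and a wide-ranging predator (otter-like) — projected
#' over the full 2 climate x 2 land-use x 3 GCM scenario factorial and all
#' four binarization thresholds. Every reference parameter is surfaced
#' here; desk-scale values (grid size, background count, thinning
#' distances) are deliberately smaller than the field-scale defaults of the
#' individual functions, which retain the reference values (10,000
#' background points, 2/20 km thinning and dispersal).
#'
#' @param seed integer master seed.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    landscape = list(n_rows = 32, n_cols = 32, cell_size = 1000,
                     corr_len = 2, n_dams = 2),
    buffer_m = 1000,
    background_n = 2000,
    uncertainty_max_m = 250,
    thin_reps = 10,
    vif_threshold = 5,
    folds = list(coarse_cells = 8, fine_cells = 2),
    algorithms = c("GLM", "GAM", "GBM", "RF", "MAXENT"),
    learners = list(RF = list(ntree = 60), GBM = list(n_trees = 120)),
    maxent = list(knots_per_var = 10),
    min_auc = 0.70,
    thresholds = threshold_methods(),
    scenarios = list(climate = c("RCP2.6", "RCP8.5"),
                     landuse = c("A2", "B1"),
                     gcm = c("CCSM4", "IPSL-CM5A-LR", "MIROC-ESM-CHEM")),
    horizon_years = 30,
    species = list(
      prey = list(name = "prey",
                  truth_beta = c(intercept = -3, bio3 = 2, bio4 = -2,
                                 bio19 = 2),
                  n_occurrences = 600, thinning_m = 300,
                  dispersal_m = 2000, maturity_steps = 1,
                  barrier_mode = "basins_and_dams"),
      predator = list(name = "predator",
                      truth_beta = c(intercept = -3, bio3 = 2, bio9 = 2,
                                     bio8 = 2),
                      n_occurrences = 600, thinning_m = 300,
                      dispersal_m = 20000, maturity_steps = 1,
                      barrier_mode = "none")))
}

#' Validate a run configuration
#'
#' Structural checks only (labels from the closed factorial, positive
#' distances, counts); an empty character vector means valid.
#'
#' @param config a run configuration list (see [default_run_config()]).
#' @return character vector of findings.
#' @export
validate_config <- function(config) {
  findings <- character()
  bad <- function(fmt, ...) findings <<- c(findings, sprintf(fmt, ...))
  lev <- scenario_levels()
  for (cl in config$scenarios$climate)
    if (!cl %in% lev$climate)
      bad("scenarios.climate: '%s' not in {%s}", cl,
          paste(lev$climate, collapse = ", "))
  for (lu in config$scenarios$landuse)
    if (!lu %in% lev$landuse)
      bad("scenarios.landuse: '%s' not in {%s}", lu,
          paste(lev$landuse, collapse = ", "))
  for (g in config$scenarios$gcm)
    if (!g %in% lev$gcm)
      bad("scenarios.gcm: '%s' not in {%s}", g,
          paste(lev$gcm, collapse = ", "))
  for (th in config$thresholds)
    if (!th %in% threshold_methods())
      bad("thresholds: '%s' not a known rule", th)
  for (alg in config$algorithms)
    if (!alg %in% sdm_algorithms())
      bad("algorithms: '%s' unknown", alg)
  if (!is.null(config$background_n) && config$background_n < 1)
    bad("background_n must be >= 1")
  if (!is.null(config$uncertainty_max_m) && config$uncertainty_max_m <= 0)
    bad("uncertainty_max_m must be positive")
  for (sp in config$species) {
    if (is.null(sp$thinning_m) || sp$thinning_m <= 0)
      bad("species '%s': thinning_m must be positive", sp$name %||% "?")
    if (is.null(sp$dispersal_m) || sp$dispersal_m <= 0)
      bad("species '%s': dispersal_m must be positive", sp$name %||% "?")
    if (!is.null(sp$maturity_steps) && sp$maturity_steps < 1)
      bad("species '%s': maturity_steps must be >= 1", sp$name %||% "?")
    if (!is.null(sp$barrier_mode) &&
        !sp$barrier_mode %in% c("none", "cells_block", "basins_and_dams"))
      bad("species '%s': unknown barrier_mode '%s'", sp$name %||% "?",
          sp$barrier_mode)
  }
  findings
}

# deterministic 31-bit polynomial hash of a JSON-serialized object
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

fit_species <- function(config, bundle, stack, sp, seed) {
  truth <- simulate_truth(bundle, beta = sp$truth_beta,
                          buffer_m = config$buffer_m)
  occ <- sample_occurrences(truth, sp$n_occurrences, seed = seed)
  occ_f <- filter_uncertainty(occ, config$uncertainty_max_m %||% 250)
  occ_t <- thin_occurrences(occ_f, sp$thinning_m,
                            reps = config$thin_reps %||% 100,
                            seed = seed + 1)
  bg <- sample_background(stack$mask, config$background_n, seed = seed + 2)
  feats <- extract_features(stack, occ_t, bg)
  keep <- vif_select(feats, config$vif_threshold %||% 5)
  stack_sel <- subset_stack(stack, keep)
  feats <- feats[, c("id", "label", keep)]
  attr(feats, "layers") <- keep
  folds <- checkerboard2(rbind(occ_t[names(bg)], bg), stack$mask,
                         config$folds$coarse_cells,
                         config$folds$fine_cells)
  tuning <- tune_maxent(feats,
                        knots_per_var = config$maxent$knots_per_var %||% 10)
  models <- fit_all(feats, folds, algorithms = config$algorithms,
                    maxent_config = tuning$best,
                    configs = config$learners %||% list(), seed = seed + 3)
  ens <- build_ensemble(models, config$min_auc %||% 0.70)
  current <- predict_suitability(ens, stack_sel)
  # evaluation scores for thresholding: ensemble predictions at the data
  p_all <- predict_ensemble(ens, feature_matrix(feats))
  list(truth = truth, occurrences = occ, thinned = occ_t, background = bg,
       features = feats, retained = keep, folds = folds, tuning = tuning,
       models = models, ensemble = ens, stack = stack_sel,
       current_suitability = current,
       scores_presence = p_all[feats$label == 1],
       scores_background = p_all[feats$label == 0])
}

#' Run the full pipeline from a configuration
#'
#' Executes, per species: synthetic truth -> occurrence sampling ->
#' uncertainty filter -> thinning -> background -> checkerboard folds ->
#' VIF selection -> Maxent tuning + five-algorithm fit -> AUC-weighted
#' ensemble; then, per scenario x GCM: future projection, binarization
#' under every threshold rule, dispersal-constrained automaton, and range
#' net-change/shift metrics; finally interspecific overlaps and the
#' per-scenario median/SD summary. All artifacts are written under
#' `out_dir` (text rasters, CSV tables, JSON manifest); a failure in one
#' species/scenario branch is recorded and the rest continues.
#'
#' @param config run configuration (see [default_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return the run manifest (invisibly also written as JSON), including the
#'   metrics and summary tables.
#' @export
run_all <- function(config = default_run_config(), out_dir = tempfile("run")) {
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid configuration:\n  ", paste(findings, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("riversdm")),
                   seed = config$seed, stages = list(), outputs = character(),
                   failures = list())
  note <- function(path) manifest$outputs <<- c(manifest$outputs, path)
  seed <- config$seed
  ls_cfg <- config$landscape
  bundle <- make_landscape(ls_cfg$n_rows, ls_cfg$n_cols, ls_cfg$cell_size,
                           seed = seed, corr_len = ls_cfg$corr_len,
                           n_dams = ls_cfg$n_dams %||% 2)
  stack <- build_predictor_stack(bundle, config$buffer_m)
  range_mask <- stack$mask      # stand-in for an expert/published range
  fits <- list(); metrics <- list()
  sp_names <- vapply(config$species, function(s) s$name, character(1))
  for (si in seq_along(config$species)) {
    sp <- config$species[[si]]
    sp_dir <- file.path(out_dir, sp$name)
    dir.create(sp_dir, showWarnings = FALSE)
    res <- tryCatch(
      fit_species(config, bundle, stack, sp, seed + 100 * si),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failures[[sp$name]] <- conditionMessage(res)
      next
    }
    fits[[sp$name]] <- res
    write_occurrences(res$thinned, file.path(sp_dir, "occurrences_thinned.csv"))
    note(file.path(sp_dir, "occurrences_thinned.csv"))
    utils::write.csv(res$folds, file.path(sp_dir, "folds.csv"),
                     row.names = FALSE)
    note(file.path(sp_dir, "folds.csv"))
    utils::write.csv(res$tuning$table, file.path(sp_dir, "maxent_tuning.csv"),
                     row.names = FALSE)
    note(file.path(sp_dir, "maxent_tuning.csv"))
    ev <- do.call(rbind, lapply(res$models, function(m)
      cbind(algorithm = m$algorithm, m$fold_scores)))
    utils::write.csv(ev, file.path(sp_dir, "evaluation.csv"),
                     row.names = FALSE)
    note(file.path(sp_dir, "evaluation.csv"))
    write_asc(res$current_suitability,
              file.path(sp_dir, "suitability_current.asc"))
    note(file.path(sp_dir, "suitability_current.asc"))
    manifest$stages[[sp$name]] <- list(
      occurrences = nrow(res$occurrences),
      after_uncertainty_filter =
        nrow(filter_uncertainty(res$occurrences,
                                config$uncertainty_max_m %||% 250)),
      after_thinning = nrow(res$thinned),
      retained_predictors = res$retained,
      mean_auc = vapply(res$models, `[[`, 0, "mean_auc"),
      ensemble_members = vapply(res$ensemble$members, `[[`, "", "algorithm"))
    # current binary maps per threshold
    fits[[sp$name]]$current_binary <- list()
    for (th in config$thresholds) {
      thr <- find_threshold(res$scores_presence, res$scores_background, th)
      cb <- clip_initial_range(binarize(res$current_suitability, thr, th),
                               range_mask)
      fits[[sp$name]]$current_binary[[th]] <- cb
    }
    # scenario projections
    for (cl in config$scenarios$climate) for (lu in config$scenarios$landuse) {
      scen <- sprintf("%s-LUC.%s", cl, lu)
      for (gcm in config$scenarios$gcm) {
        cell <- tryCatch({
          fut_bundle <- make_future(bundle, cl, lu, gcm)
          fut_stack <- subset_stack(
            build_predictor_stack(fut_bundle, config$buffer_m),
            res$retained)
          fut_suit <- predict_suitability(res$ensemble, fut_stack)
          out <- list(suitability = fut_suit, final = list())
          for (th in config$thresholds) {
            cb <- fits[[sp$name]]$current_binary[[th]]
            fb <- binarize(fut_suit, cb$threshold_used, th)
            dcfg <- dispersal_config(
              dispersal_distance_m = sp$dispersal_m,
              maturity_steps = sp$maturity_steps %||% 1,
              n_steps = config$horizon_years %||% 30,
              barrier_mode = sp$barrier_mode %||% "none")
            sim <- disperse(cb, fb, dcfg, basin_id = bundle$basin_id,
                            dam_mask = bundle$dam_mask,
                            river_mask = bundle$river_mask)
            # a fully collapsed (or empty-current) range leaves a metric
            # undefined: record NA rather than failing the branch
            nc <- tryCatch(net_change(cb, sim$final)$net_change_pct,
                           error = function(e) NA_real_)
            sh <- tryCatch(as.numeric(range_shift(cb, sim$final)),
                           error = function(e) NA_real_)
            metrics[[length(metrics) + 1L]] <- data.frame(
              species = sp$name, scenario = scen, gcm = gcm, threshold = th,
              metric = c("net_change_pct", "shift_pct"),
              value = c(nc, sh))
            out$final[[th]] <- sim$final
          }
          out
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          manifest$failures[[paste(sp$name, scen, gcm, sep = "/")]] <-
            conditionMessage(cell)
        } else {
          fits[[sp$name]]$future[[scen]][[gcm]] <- cell
        }
      }
    }
  }
  # interspecific overlap (first species' range inside the second's)
  if (length(fits) >= 2) {
    a <- fits[[sp_names[1]]]; b <- fits[[sp_names[2]]]
    for (th in config$thresholds) {
      ov <- tryCatch(species_overlap(a$current_binary[[th]],
                                     b$current_binary[[th]]),
                     error = function(e) NA_real_)
      metrics[[length(metrics) + 1L]] <- data.frame(
        species = sp_names[1], scenario = "current", gcm = "none",
        threshold = th, metric = "overlap_pct", value = ov)
    }
    for (scen in names(a$future)) for (gcm in names(a$future[[scen]])) {
      if (is.null(b$future[[scen]][[gcm]])) next
      for (th in config$thresholds) {
        fa <- a$future[[scen]][[gcm]]$final[[th]]
        fb <- b$future[[scen]][[gcm]]$final[[th]]
        if (is.null(fa) || is.null(fb)) next
        ov <- tryCatch(species_overlap(fa, fb), error = function(e) NA_real_)
        metrics[[length(metrics) + 1L]] <- data.frame(
          species = sp_names[1], scenario = scen, gcm = gcm, threshold = th,
          metric = "overlap_pct", value = ov)
      }
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else data.frame()
  if (nrow(metrics)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    note(file.path(out_dir, "metrics.csv"))
    summary <- summarize_across(metrics, value = "value",
                                by = c("species", "scenario", "metric"))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    note(file.path(out_dir, "summary.csv"))
    manifest$summary <- summary
  }
  manifest$metrics <- metrics
  keep <- manifest
  keep$metrics <- NULL; keep$summary <- NULL
  jsonlite::write_json(keep, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  manifest$out_dir <- out_dir
  invisible(manifest)
}
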