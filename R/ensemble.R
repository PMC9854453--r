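#' Fit the five-algorithm ensemble with spatial cross-validation
#'
#' For each algorithm, runs 4-fold cross-validation over the supplied
#' (checkerboard) fold assignment — train on three folds, score the held-out
#' fold by AUC and maximum TSS — then refits on all data. The Maxent-style
#' learner uses the AICc-tuned configuration (tuned here when not given).
#' Folds lacking either class are skipped with a warning; an algorithm with
#' no usable fold is dropped with a warning.
#'
#' @param table an `rs_features` table.
#' @param folds data.frame `id, fold` (folds 0-3), e.g. from
#'   [checkerboard2()].
#' @param algorithms subset of [sdm_algorithms()].
#' @param maxent_config list(`feature_classes`, `reg_mult`); `NULL` tunes by
#'   [tune_maxent()].
#' @param configs named list of per-algorithm config overrides.
#' @param seed integer seed for the stochastic learners.
#' @return list of `rs_fitted_model` objects (config, fitted learner,
#'   per-fold scores, mean AUC/TSS).
#' @export
fit_all <- function(table, folds, algorithms = sdm_algorithms(),
                    maxent_config = NULL, configs = list(), seed = 1) {
  fold <- folds$fold[match(table$id, folds$id)]
  if (any(is.na(fold)))
    stop("fold assignment missing for some records")
  if (length(setdiff(unique(fold), 0:3)))
    stop("folds must be labelled 0-3")
  X <- feature_matrix(table)
  y <- table$label
  if (is.null(maxent_config) && "MAXENT" %in% algorithms)
    maxent_config <- tune_maxent(table)$best
  models <- list()
  for (alg in algorithms) {
    cfg <- configs[[alg]] %||% list()
    if (alg == "MAXENT") cfg <- utils::modifyList(maxent_config, cfg)
    scores <- data.frame(fold = integer(), auc = numeric(),
                         tss = numeric())
    for (f in 0:3) {
      te <- fold == f; tr <- !te
      if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
        warning(sprintf("%s: fold %d lacks a class; skipped", alg, f))
        next
      }
      m <- fit_learner(alg, X[tr, , drop = FALSE], y[tr], cfg,
                       seed = seed + f)
      p <- predict_learner(m, X[te, , drop = FALSE])
      scores <- rbind(scores, data.frame(
        fold = f, auc = auc(p, y[te]), tss = tss_max(p, y[te])$tss))
    }
    if (!nrow(scores)) {
      warning(sprintf("%s: no usable fold; model rejected", alg))
      next
    }
    final <- fit_learner(alg, X, y, cfg, seed = seed)
    models[[alg]] <- structure(
      list(algorithm = alg, config = cfg, learner = final,
           fold_scores = scores,
           mean_auc = mean(scores$auc), mean_tss = mean(scores$tss)),
      class = "rs_fitted_model")
  }
  if (!length(models)) stop("every algorithm was rejected")
  models
}

#' @export
print.rs_fitted_model <- function(x, ...) {
  cat(sprintf("<rs_fitted_model> %s: mean AUC %.3f, mean TSS %.3f (%d folds)\n",
              x$algorithm, x$mean_auc, x$mean_tss, nrow(x$fold_scores)))
  invisible(x)
}

#' AUC-weighted ensemble of fitted models
#'
#' Keeps the models whose cross-validated mean AUC passes the gate
#' (default 0.70) and combines their predictions as a weighted average with
#' the mean AUC values as weights.
#'
#' @param models list of `rs_fitted_model` (from [fit_all()]).
#' @param min_auc inclusion gate on mean AUC.
#' @return an `rs_ensemble` (members + weights).
#' @export
build_ensemble <- function(models, min_auc = 0.70) {
  aucs <- vapply(models, function(m) m$mean_auc, numeric(1))
  pass <- aucs >= min_auc
  if (!any(pass))
    stop(sprintf(
      "no model passes the AUC >= %.2f gate (mean AUCs: %s)", min_auc,
      paste(sprintf("%s=%.3f", vapply(models, `[[`, "", "algorithm"), aucs),
            collapse = ", ")))
  structure(list(members = models[pass], weights = aucs[pass],
                 min_auc = min_auc),
            class = "rs_ensemble")
}

#' @export
print.rs_ensemble <- function(x, ...) {
  cat(sprintf("<rs_ensemble> %d member(s): %s\n", length(x$members),
              paste(sprintf("%s (w=%.3f)",
                            vapply(x$members, `[[`, "", "algorithm"),
                            x$weights), collapse = ", ")))
  invisible(x)
}

#' Predict ensemble suitability for a feature matrix
#' @param ensemble an `rs_ensemble`.
#' @param newX feature matrix.
#' @export
predict_ensemble <- function(ensemble, newX) {
  preds <- vapply(ensemble$members,
                  function(m) predict_learner(m$learner, newX),
                  numeric(nrow(as.matrix(newX))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  drop(preds %*% ensemble$weights) / sum(ensemble$weights)
}

#' Project a model or ensemble over a predictor stack
#'
#' Builds the per-cell feature matrix for every cell inside the stack's
#' analysis mask and returns the suitability surface as a grid (nodata
#' outside the mask).
#'
#' @param model an `rs_ensemble` or `rs_learner`.
#' @param stack an `rs_stack`.
#' @return suitability `rs_grid` in \[0, 1\].
#' @export
predict_suitability <- function(model, stack) {
  inside <- which(!is.na(stack$mask$values) & stack$mask$values == 1)
  Xc <- vapply(stack$layers, function(g) g$values[inside],
               numeric(length(inside)))
  if (is.null(dim(Xc))) Xc <- matrix(Xc, nrow = length(inside))
  colnames(Xc) <- names(stack$layers)
  p <- if (inherits(model, "rs_ensemble")) predict_ensemble(model, Xc)
       else predict_learner(model, Xc)
  v <- matrix(NA_real_, nrow(stack$mask$values), ncol(stack$mask$values))
  v[inside] <- p
  grid_like(stack$mask, v)
}

#' Permutation variable importance of an ensemble
#'
#' `importance_j = mean over permutations of
#' max(0, 1 - cor(pred_original, pred_with_j_permuted))`. Variables that no
#' member uses keep importance 0; constant ensemble predictions make the
#' correlation undefined and are reported as 0 with a warning.
#'
#' @param ensemble an `rs_ensemble`.
#' @param table an `rs_features` table to evaluate on.
#' @param permutations number of permutations per variable.
#' @param seed integer seed.
#' @return data.frame `variable, importance`, in layer order.
#' @export
variable_importance <- function(ensemble, table, permutations = 5, seed = 1) {
  if (permutations < 1) stop("permutations must be >= 1")
  X <- feature_matrix(table)
  p0 <- predict_ensemble(ensemble, X)
  if (stats::sd(p0) == 0) {
    warning("constant ensemble predictions; importance undefined, set to 0")
    return(data.frame(variable = colnames(X),
                      importance = 0, stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(X)), function(j) {
      mean(vapply(seq_len(permutations), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        pj <- predict_ensemble(ensemble, Xp)
        if (stats::sd(pj) == 0) 1 else
          max(0, 1 - stats::cor(p0, pj))
      }, numeric(1)))
    }, numeric(1))
    data.frame(variable = colnames(X), importance = imp,
               stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
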