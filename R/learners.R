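sdm_algorithms <- function() c("GLM", "GAM", "GBM", "RF", "MAXENT")

#' Default learner configurations
#'
#' Named, overridable settings for the five ensemble algorithms: logistic
#' GLM with linear + quadratic terms; GAM with a modest thin-plate smooth
#' per variable; gradient-boosted shallow trees with shrinkage and early
#' stopping on a held-out fraction; a class-balanced probability random
#' forest; and the Maxent-style penalized logistic learner (configuration
#' normally supplied by [tune_maxent()]).
#'
#' @param algorithm one of `"GLM", "GAM", "GBM", "RF", "MAXENT"`.
#' @export
learner_defaults <- function(algorithm) {
  switch(algorithm,
    GLM = list(),
    GAM = list(k = 5),
    GBM = list(n_trees = 200, depth = 2, shrinkage = 0.1,
               bag_fraction = 0.7, val_fraction = 0.2, min_node = 10),
    RF  = list(ntree = 100, max_depth = 12, min_node = 5,
               class_balance = TRUE),
    MAXENT = list(feature_classes = "LQ", reg_mult = 1, knots_per_var = 10,
                  lambda_base = NULL),
    stop("unknown algorithm: ", algorithm))
}

#' Fit one suitability learner
#'
#' Common entry point for the five algorithms; all learners consume a
#' numeric feature matrix with named columns and a 0/1 presence label, and
#' predict on the probability scale via [predict_learner()].
#'
#' @param algorithm one of [sdm_algorithms()].
#' @param X feature matrix (named columns).
#' @param y 0/1 labels.
#' @param config settings (see [learner_defaults()]); missing entries take
#'   defaults.
#' @param seed integer seed for the stochastic learners (GBM, RF).
#' @return an `rs_learner`.
#' @export
fit_learner <- function(algorithm, X, y, config = list(), seed = 1) {
  algorithm <- match.arg(algorithm, sdm_algorithms())
  config <- utils::modifyList(learner_defaults(algorithm), config)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both presences and background points are required")
  fit <- switch(algorithm,
    GLM = fit_glm_learner(X, y),
    GAM = fit_gam_learner(X, y, config),
    GBM = fit_gbm_learner(X, y, config, seed),
    RF  = fit_rf_learner(X, y, config, seed),
    MAXENT = fit_maxent_learner(X, y, config))
  structure(list(algorithm = algorithm, config = config, fit = fit,
                 vars = colnames(X)),
            class = "rs_learner")
}

#' @rdname fit_learner
#' @param model an `rs_learner`.
#' @param newX feature matrix to score.
#' @return suitability in \[0, 1\].
#' @export
predict_learner <- function(model, newX) {
  newX <- as.matrix(newX)
  miss <- setdiff(model$vars, colnames(newX))
  if (length(miss))
    stop("prediction features missing: ", paste(miss, collapse = ", "))
  newX <- newX[, model$vars, drop = FALSE]
  p <- switch(model$algorithm,
    GLM = predict_glm_learner(model$fit, newX),
    GAM = as.numeric(mgcv::predict.gam(model$fit,
                                       as.data.frame(newX),
                                       type = "response")),
    GBM = predict_gbm_learner(model$fit, newX),
    RF  = predict_rf_learner(model$fit, newX),
    MAXENT = predict(model$fit$maxent,
                     expand_features(model$fit$recipe, newX)))
  pmin(pmax(as.numeric(p), 0), 1)
}

## --- GLM: logistic with linear + quadratic terms ------------------------

fit_glm_learner <- function(X, y) {
  Xd <- cbind(X, `colnames<-`(X^2, paste0(colnames(X), "_sq")))
  df <- data.frame(Xd, check.names = FALSE)
  df$.y <- y
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(Xd)), collapse = " + ")))
  suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
}

predict_glm_learner <- function(fit, newX) {
  Xd <- cbind(newX, `colnames<-`(newX^2, paste0(colnames(newX), "_sq")))
  as.numeric(stats::predict(fit, data.frame(Xd, check.names = FALSE),
                            type = "response"))
}

## --- GAM: per-variable smooths ------------------------------------------

fit_gam_learner <- function(X, y, config) {
  df <- data.frame(X, check.names = FALSE)
  terms <- vapply(colnames(X), function(v) {
    ku <- length(unique(X[, v]))
    if (ku < 4) sprintf("`%s`", v)
    else sprintf("s(`%s`, k = %d)", v, min(config$k, ku - 1))
  }, character(1))
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  mgcv::gam(fml, data = df, family = stats::binomial(), method = "REML")
}

## --- GBM: logistic gradient boosting on shallow trees -------------------

fit_gbm_learner <- function(X, y, config, seed) {
  with_seed(seed, {
    n <- nrow(X)
    val <- sample.int(n, max(1L, round(config$val_fraction * n)))
    tr <- setdiff(seq_len(n), val)
    p0 <- mean(y[tr])
    f0 <- stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6))
    Fall <- rep(f0, n)
    trees <- list(); leaf_values <- list()
    best_dev <- Inf; best_iter <- 0L
    dev_of <- function(idx) -2 * binomial_loglik(y[idx],
                                                 stats::plogis(Fall[idx]))
    for (m in seq_len(config$n_trees)) {
      bag <- sort(sample(tr, max(2L * config$min_node,
                                 round(config$bag_fraction * length(tr)))))
      p <- stats::plogis(Fall[bag])
      r <- y[bag] - p
      tree <- cpp_tree_fit(X[bag, , drop = FALSE], r,
                           seq_along(bag) - 1L,
                           config$depth, config$min_node, ncol(X),
                           sample.int(.Machine$integer.max, 1))
      leaf_bag <- cpp_tree_leaf(tree, X[bag, , drop = FALSE])
      # Newton leaf values for the logistic loss
      num <- tapply(r, leaf_bag, sum)
      den <- tapply(p * (1 - p), leaf_bag, sum)
      gamma <- pmin(pmax(num / pmax(den, 1e-10), -4), 4)
      leaf_all <- cpp_tree_leaf(tree, X)
      step <- gamma[as.character(leaf_all)]
      step[is.na(step)] <- 0
      Fall <- Fall + config$shrinkage * as.numeric(step)
      trees[[m]] <- tree
      leaf_values[[m]] <- gamma
      dv <- dev_of(val)
      if (dv < best_dev - 1e-9) { best_dev <- dv; best_iter <- m }
      if (m - best_iter >= 25L) break    # early stopping patience
    }
    list(f0 = f0, shrinkage = config$shrinkage,
         trees = trees[seq_len(best_iter)],
         leaf_values = leaf_values[seq_len(best_iter)])
  })
}

predict_gbm_learner <- function(fit, newX) {
  Fv <- rep(fit$f0, nrow(newX))
  for (m in seq_along(fit$trees)) {
    leaf <- cpp_tree_leaf(fit$trees[[m]], newX)
    step <- fit$leaf_values[[m]][as.character(leaf)]
    step[is.na(step)] <- 0
    Fv <- Fv + fit$shrinkage * as.numeric(step)
  }
  stats::plogis(Fv)
}

## --- RF: class-balanced probability forest ------------------------------

fit_rf_learner <- function(X, y, config, seed) {
  with_seed(seed, {
    pos <- which(y == 1); neg <- which(y == 0)
    n_bal <- min(length(pos), length(neg))
    mtry <- max(1L, floor(sqrt(ncol(X))))
    trees <- lapply(seq_len(config$ntree), function(t) {
      boot <- if (config$class_balance)
        c(sample(pos, n_bal, replace = TRUE),
          sample(neg, n_bal, replace = TRUE))
      else sample.int(length(y), length(y), replace = TRUE)
      cpp_tree_fit(X, y, boot - 1L, config$max_depth, config$min_node,
                   mtry, sample.int(.Machine$integer.max, 1))
    })
    list(trees = trees)
  })
}

predict_rf_learner <- function(fit, newX) {
  preds <- vapply(fit$trees, function(tr) cpp_tree_predict(tr, newX),
                  numeric(nrow(newX)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

## --- MAXENT: expansion + penalized logistic -----------------------------

fit_maxent_learner <- function(X, y, config) {
  recipe <- feature_expansion(X, config$feature_classes,
                              config$knots_per_var)
  design <- expand_features(recipe, X)
  list(recipe = recipe,
       maxent = fit_maxent_like(design, y, config$reg_mult,
                                config$lambda_base))
}
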