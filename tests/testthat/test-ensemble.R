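# learner that predicts a constant probability: a Maxent-style fit with all
# coefficients zero and intercept qlogis(p)
const_learner <- function(p, vars = c("x1", "x2")) {
  Xd <- matrix(0, 2, length(vars), dimnames = list(NULL, vars))
  recipe <- feature_expansion(Xd, "L")
  maxent <- structure(
    list(b0 = qlogis(p), beta = rep(0, length(vars)), k = 0L,
         loglik = 0, fitted = NULL, keep = rep(TRUE, length(vars)),
         center = rep(0, length(vars)), scale = rep(1, length(vars)),
         reg_mult = 1, lambda = 1),
    class = "rs_maxent")
  structure(list(algorithm = "MAXENT", config = list(),
                 fit = list(recipe = recipe, maxent = maxent), vars = vars),
            class = "rs_learner")
}

fake_model <- function(mean_auc, p) {
  structure(list(algorithm = "MAXENT", config = list(),
                 learner = const_learner(p),
                 fold_scores = data.frame(fold = 0:3, auc = mean_auc,
                                          tss = 0.5),
                 mean_auc = mean_auc, mean_tss = 0.5),
            class = "rs_fitted_model")
}

newX <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x1", "x2")))

test_that("the AUC gate and AUC weighting work as specified", {
  # all below the gate: rejected with a diagnostic
  expect_error(build_ensemble(list(fake_model(0.6, 0.3),
                                   fake_model(0.69, 0.4))),
               "no model passes")
  # single passing member: ensemble == that member
  e1 <- build_ensemble(list(fake_model(0.9, 0.3), fake_model(0.5, 0.9)))
  expect_identical(length(e1$members), 1L)
  expect_equal(predict_ensemble(e1, newX), rep(0.3, 10))
  # equal weights average the predictions: (0.2 + 0.6) / 2 = 0.4
  e2 <- build_ensemble(list(fake_model(0.8, 0.2), fake_model(0.8, 0.6)))
  expect_equal(predict_ensemble(e2, newX), rep(0.4, 10))
  # unequal weights: (0.9 * 1 + 0.7 * 0) / 1.6 = 0.5625
  e3 <- build_ensemble(list(fake_model(0.9, plogis(40)),
                            fake_model(0.7, plogis(-40))))
  expect_equal(predict_ensemble(e3, newX), rep(0.5625, 10),
               tolerance = 1e-9)
})

test_that("cross-validated fitting scores every algorithm on every fold", {
  b <- make_landscape(16, 16, seed = 21)
  tr <- simulate_truth(b)
  st <- build_predictor_stack(b)
  occ <- sample_occurrences(tr, 200, seed = 1)
  bg <- sample_background(st$mask, 800, seed = 2)
  ft <- extract_features(st, occ, bg)
  fo <- checkerboard2(rbind(occ[names(bg)], bg), st$mask, 8, 2)
  mods <- fit_all(ft, fo, configs = list(RF = list(ntree = 30),
                                         GBM = list(n_trees = 60)),
                  seed = 7)
  expect_setequal(names(mods), c("GLM", "GAM", "GBM", "RF", "MAXENT"))
  for (m in mods) {
    expect_identical(sort(m$fold_scores$fold), 0:3)
    expect_true(all(m$fold_scores$auc >= 0 & m$fold_scores$auc <= 1))
    expect_true(all(abs(m$fold_scores$tss) <= 1))
    # strong-signal world: every algorithm beats chance comfortably
    expect_gt(m$mean_auc, 0.6)
  }
  # predictions stay probabilities and the ensemble stays inside the
  # member envelope
  ens <- build_ensemble(mods, min_auc = 0)
  X <- riversdm:::feature_matrix(ft)
  preds <- sapply(ens$members, function(m) predict_learner(m$learner, X))
  pe <- predict_ensemble(ens, X)
  expect_true(all(pe >= 0 & pe <= 1))
  expect_true(all(pe >= apply(preds, 1, min) - 1e-12))
  expect_true(all(pe <= apply(preds, 1, max) + 1e-12))
  # the weighted mean is exactly sum(w p) / sum(w)
  expect_equal(pe, drop(preds %*% ens$weights) / sum(ens$weights))
})

test_that("label permutation removes the signal for every algorithm", {
  b <- make_landscape(16, 16, seed = 22)
  tr <- simulate_truth(b)
  st <- build_predictor_stack(b)
  occ <- sample_occurrences(tr, 150, seed = 1)
  bg <- sample_background(st$mask, 600, seed = 2)
  ft <- extract_features(st, occ, bg)
  fo <- checkerboard2(rbind(occ[names(bg)], bg), st$mask, 8, 2)
  # permuting labels within the table (3-seed module-scale null check)
  for (s in 1:3) {
    set.seed(s)
    ftp <- ft; ftp$label <- sample(ft$label)
    mods <- suppressWarnings(
      fit_all(ftp, fo, algorithms = c("GLM", "RF", "MAXENT"),
              maxent_config = list(feature_classes = "L", reg_mult = 1),
              configs = list(RF = list(ntree = 30)), seed = s))
    for (m in mods) expect_lt(abs(m$mean_auc - 0.5), 0.13)
  }
})

test_that("permutation importance singles out the generating variable", {
  set.seed(9)
  X <- matrix(rnorm(1200), 400, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- rbinom(400, 1, plogis(3 * X[, 1]))
  ft <- data.frame(id = as.character(1:400), label = y, X,
                   check.names = FALSE)
  class(ft) <- c("rs_features", "data.frame")
  m <- fit_learner("MAXENT", X, y,
                   list(feature_classes = "L", reg_mult = 1))
  fm <- structure(list(algorithm = "MAXENT", config = list(), learner = m,
                       fold_scores = data.frame(fold = 0:3, auc = 0.9,
                                                tss = 0.6),
                       mean_auc = 0.9, mean_tss = 0.6),
                  class = "rs_fitted_model")
  ens <- build_ensemble(list(fm))
  imp <- variable_importance(ens, ft, permutations = 3, seed = 5)
  expect_identical(imp$variable[which.max(imp$importance)], "x1")
  expect_true(all(imp$importance >= 0))
  # deterministic under the permutation seed
  expect_identical(imp, variable_importance(ens, ft, permutations = 3,
                                            seed = 5))
  # a variable with zero coefficient in every member has importance 0
  if (m$fit$maxent$beta[2] == 0)
    expect_equal(imp$importance[imp$variable == "x2"], 0)
})

test_that("constant predictions yield zero importance with a warning", {
  ens <- build_ensemble(list(fake_model(0.9, 0.4)))
  ft <- data.frame(id = as.character(1:10), label = rep(c(1, 0), 5),
                   x1 = rnorm(10), x2 = rnorm(10), check.names = FALSE)
  class(ft) <- c("rs_features", "data.frame")
  expect_warning(imp <- variable_importance(ens, ft, permutations = 2,
                                            seed = 1),
                 "constant")
  expect_true(all(imp$importance == 0))
})
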