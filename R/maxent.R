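#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)`; undefined (rejected)
#' when `n <= k + 1`.
#'
#' @param loglik model log-likelihood.
#' @param k number of (non-zero) parameters.
#' @param n sample size.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

binomial_loglik <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# One L1 path over a descending lambda grid on the standardized design.
# Standardizing first and penalizing every column equally is the same as
# penalizing raw columns proportionally to their training sd.
maxent_path <- function(design, labels, reg_mults, lambda_base = NULL) {
  X <- as.matrix(design)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  keep <- scale > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
              scale[keep], "/")
  if (ncol(Xs) == 1L) Xs <- cbind(Xs, .pad = 0)   # glmnet needs >= 2 cols
  if (is.null(lambda_base)) {
    # data-driven base: 1/20 of the smallest penalty that zeroes every
    # coefficient, so the 0.5-4 multiplier grid spans clearly under- to
    # over-regularized fits at any prevalence
    lam_max <- max(abs(crossprod(Xs, labels - mean(labels)))) / length(labels)
    lambda_base <- lam_max / 20
  }
  lambdas <- sort(unique(reg_mults * lambda_base), decreasing = TRUE)
  path <- c(max(lambdas) * c(100, 10), lambdas)   # lead-in for path stability
  fit <- glmnet::glmnet(Xs, labels, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE)
  list(fit = fit, Xs = Xs, keep = keep, center = center, scale = scale,
       lambdas = lambdas, lambda_base = lambda_base)
}

maxent_at_reg <- function(path, reg_mult, labels) {
  maxent_at_lambda(path, reg_mult * path$lambda_base, labels)
}

maxent_at_lambda <- function(path, lambda, labels) {
  cf <- as.numeric(glmnet::coef.glmnet(path$fit, s = lambda, exact = FALSE))
  b0 <- cf[1]; beta <- cf[-1]
  beta <- beta[seq_len(sum(path$keep))]          # strip any padding column
  eta <- drop(path$Xs[, seq_len(sum(path$keep)), drop = FALSE] %*% beta) + b0
  p <- stats::plogis(eta)
  list(b0 = b0, beta = beta, fitted = p,
       k = sum(beta != 0), loglik = binomial_loglik(labels, p))
}

#' Maxent-style penalized presence/background logistic model
#'
#' L1-penalized logistic regression on an expanded feature design, the
#' maxnet-equivalent formulation of Maxent: the effective penalty on each
#' raw column is `reg_mult` times a base penalty scaled by that column's
#' training standard deviation (implemented by standardizing the design and
#' setting the lasso penalty to `reg_mult * lambda_base`). `k`, the count of
#' non-zero coefficients, is the parameter count used for AICc.
#'
#' @param design numeric design matrix (see [expand_features()]).
#' @param labels 0/1 vector (1 = presence, 0 = background); both classes
#'   required.
#' @param reg_mult regularization multiplier (reference grid 0.5–4).
#' @param lambda_base base lasso penalty the multiplier scales; by default
#'   data-driven (`lambda_max / 20`, where `lambda_max` is the smallest
#'   penalty that zeroes every coefficient), so the 0.5–4 grid spans
#'   clearly under- to over-penalized fits at any prevalence.
#' @return an `rs_maxent` fit with elements `b0, beta, k, loglik, fitted`.
#' @export
fit_maxent_like <- function(design, labels, reg_mult = 1,
                            lambda_base = NULL) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("both presences and background points are required")
  pth <- maxent_path(design, labels, reg_mult, lambda_base)
  at <- maxent_at_reg(pth, reg_mult, labels)
  structure(
    list(b0 = at$b0, beta = at$beta, k = at$k, loglik = at$loglik,
         fitted = at$fitted, keep = pth$keep,
         center = pth$center, scale = pth$scale,
         reg_mult = reg_mult, lambda = reg_mult * pth$lambda_base),
    class = "rs_maxent")
}

#' @export
predict.rs_maxent <- function(object, newdesign, ...) {
  X <- as.matrix(newdesign)[, object$keep, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center[object$keep]), 2,
              object$scale[object$keep], "/")
  stats::plogis(drop(Xs %*% object$beta) + object$b0)
}

#' Tune the Maxent-style learner by AICc over the 48-configuration grid
#'
#' Fits all 8 regularization multipliers (0.5 to 4 in 0.5 steps) crossed
#' with the 6 feature-class strings on the full training data and returns
#' the configuration with the lowest AICc. Ties break towards fewer
#' non-zero features, then the lower multiplier. Configurations whose fit
#' fails (or where `n <= k + 1` leaves AICc undefined) are recorded with
#' `NA` and excluded from selection; if every configuration fails the call
#' errors.
#'
#' @param table an `rs_features` table (or list with `label` and feature
#'   columns).
#' @param knots_per_var knots per variable for hinge/threshold features.
#' @param reg_grid regularization multipliers to test.
#' @param classes feature-class strings to test.
#' @param lambda_base see [fit_maxent_like()].
#' @return list with `best` (`feature_classes`, `reg_mult`) and `table`
#'   (one row per configuration: class, reg_mult, k, loglik, AICc).
#' @export
tune_maxent <- function(table, knots_per_var = 10,
                        reg_grid = seq(0.5, 4, by = 0.5),
                        classes = maxent_feature_classes(),
                        lambda_base = NULL) {
  X <- feature_matrix(table)
  y <- table$label
  n <- nrow(X)
  rows <- list()
  for (cl in classes) {
    res <- tryCatch({
      fe <- feature_expansion(X, cl, knots_per_var)
      design <- expand_features(fe, X)
      pth <- maxent_path(design, y, reg_grid, lambda_base)
      lapply(reg_grid, function(rm) {
        at <- maxent_at_reg(pth, rm, y)
        a <- if (n > at$k + 1) aicc(at$loglik, at$k, n) else NA_real_
        data.frame(feature_classes = cl, reg_mult = rm, k = at$k,
                   loglik = at$loglik, aicc = a)
      })
    }, error = function(e) {
      warning(sprintf("class %s failed: %s", cl, conditionMessage(e)))
      lapply(reg_grid, function(rm)
        data.frame(feature_classes = cl, reg_mult = rm, k = NA_integer_,
                   loglik = NA_real_, aicc = NA_real_))
    })
    rows <- c(rows, res)
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$aicc))
  if (!length(ok)) stop("all Maxent configurations failed")
  cand <- tab[ok, ]
  cand <- cand[order(cand$aicc, cand$k, cand$reg_mult), ]
  list(best = list(feature_classes = cand$feature_classes[1],
                   reg_mult = cand$reg_mult[1]),
       table = tab)
}
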