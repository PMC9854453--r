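#' The six Maxent feature-class strings
#' @export
maxent_feature_classes <- function() c("L", "LQ", "H", "LQH", "LQHP", "LQHPT")

#' Maxent-style feature expansion
#'
#' Builds an expansion recipe from training data and a feature-class string,
#' then applies it via [expand_features()]. Per included letter the design
#' gains: `L` the raw variables; `Q` their squares; `H` forward and reverse
#' hinges `max(0, +/-(x - k))` at `knots_per_var` evenly spaced interior
#' knots over each variable's *training* range; `P` all pairwise products;
#' `T` step indicators `1{x > k}` at the same knots. Knots and ranges are
#' frozen at recipe creation so projections reuse the training geometry.
#'
#' @param X numeric matrix of training features (named columns).
#' @param classes one of `"L", "LQ", "H", "LQH", "LQHP", "LQHPT"`.
#' @param knots_per_var knots per variable for hinge/threshold features.
#' @return an `rs_expansion` recipe.
#' @export
feature_expansion <- function(X, classes, knots_per_var = 10) {
  classes <- as.character(classes)
  if (!classes %in% maxent_feature_classes())
    stop("unknown feature class string: ", classes,
         " (expected one of ", paste(maxent_feature_classes(),
                                     collapse = ", "), ")")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  rng <- apply(X, 2, range)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    k <- seq(rng[1, j], rng[2, j], length.out = knots_per_var + 2)
    k[-c(1, knots_per_var + 2)]
  })
  names(knots) <- colnames(X)
  structure(list(classes = classes, vars = colnames(X),
                 knots = knots, knots_per_var = knots_per_var),
            class = "rs_expansion")
}

#' @rdname feature_expansion
#' @param recipe an `rs_expansion`.
#' @param newX matrix with the recipe's variables as columns.
#' @return numeric design matrix.
#' @export
expand_features <- function(recipe, newX) {
  newX <- as.matrix(newX)
  miss <- setdiff(recipe$vars, colnames(newX))
  if (length(miss))
    stop("expansion variables missing: ", paste(miss, collapse = ", "))
  X <- newX[, recipe$vars, drop = FALSE]
  letters_in <- strsplit(recipe$classes, "")[[1]]
  cols <- list()
  if ("L" %in% letters_in)
    for (v in recipe$vars) cols[[v]] <- X[, v]
  if ("Q" %in% letters_in)
    for (v in recipe$vars) cols[[paste0("q_", v)]] <- X[, v]^2
  if ("H" %in% letters_in)
    for (v in recipe$vars)
      for (i in seq_along(recipe$knots[[v]])) {
        k <- recipe$knots[[v]][i]
        cols[[sprintf("hf_%s_%d", v, i)]] <- pmax(0, X[, v] - k)
        cols[[sprintf("hr_%s_%d", v, i)]] <- pmax(0, k - X[, v])
      }
  if ("P" %in% letters_in && length(recipe$vars) >= 2) {
    vs <- recipe$vars
    for (a in seq_len(length(vs) - 1))
      for (b in seq(a + 1, length(vs)))
        cols[[sprintf("p_%s:%s", vs[a], vs[b])]] <- X[, vs[a]] * X[, vs[b]]
  }
  if ("T" %in% letters_in)
    for (v in recipe$vars)
      for (i in seq_along(recipe$knots[[v]])) {
        k <- recipe$knots[[v]][i]
        cols[[sprintf("t_%s_%d", v, i)]] <- as.numeric(X[, v] > k)
      }
  do.call(cbind, cols)
}
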