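#' Encode a 0-800 cognitive score into its three-level class
#'
#' `low` for scores below 200, `moderate` for 200 <= score < 400 and
#' `high` for scores of 400 and above.
#'
#' @param score Numeric vector of scores in `[0, 800]`.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
encode_score <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 800))
    stop("scores must lie in [0, 800]")
  lab <- ifelse(score < 200, "low", ifelse(score < 400, "moderate", "high"))
  factor(lab, levels = skill_levels)
}

# Standardize columns to zero mean / unit variance; constant columns get
# scale 1 so they map to 0 rather than NaN.
.fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Fit a regularized-logistic-regression feature selector
#'
#' Fits a multinomial logistic regression with an l1 or l2 penalty
#' (objective `E(X, Y) + lambda * ||w||`) on standardized features, ranks
#' features by the maximum absolute coefficient across the one-vs-rest
#' class coefficients, and retains those whose aggregated coefficient
#' magnitude is at least the mean aggregated magnitude (and nonzero) -
#' the usual model-based meta-transformation selection rule, under which
#' weak predictors with small coefficients are discarded.
#'
#' @param X Numeric feature matrix or data frame (subjects x features),
#'   with column names and no missing values.
#' @param y Class labels (factor or character); at least two classes.
#' @param penalty `"l1"` (lasso) or `"l2"` (ridge).
#' @param lambda Regularization strength (default 0.01).
#' @param seed RNG seed (the fit itself is deterministic; the seed fixes
#'   any downstream tie-breaking).
#' @return An object of class `selection_model` with the per-class
#'   coefficient matrix, aggregated scores, retained-feature mask and the
#'   standardization used.
#' @export
fit_selector <- function(X, y, penalty = c("l1", "l2"), lambda = 0.01,
                         seed = 1) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("`X` must have column (feature) names")
  if (anyNA(X)) stop("`X` must not contain missing values")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(y) < 2) stop("`y` must contain at least two classes")
  set.seed(as.integer(seed))
  sc <- .fit_scaler(X)
  Xs <- .apply_scaler(X, sc)
  # glmnet warns when a class has < 8 observations; with 10-fold CV on
  # small cohorts that is the expected regime, not a defect
  fit <- suppressWarnings(
    glmnet::glmnet(Xs, y, family = "multinomial",
                   alpha = if (penalty == "l1") 1 else 0,
                   lambda = lambda, standardize = FALSE))
  cf <- stats::coef(fit)
  coefs <- do.call(cbind, lapply(cf, function(m) as.numeric(m)[-1]))
  rownames(coefs) <- colnames(X)
  colnames(coefs) <- names(cf)
  score <- apply(abs(coefs), 1, max)
  if (all(score == 0))
    stop("all coefficients are zero at this lambda: no features retained (reduce `lambda`)")
  retained <- score > 0 & score >= mean(score)
  structure(list(penalty = penalty, lambda = lambda, coefficients = coefs,
                 score = score, retained_mask = retained,
                 threshold_rule = "max-over-classes |coef| >= mean aggregated |coef|",
                 feature_names = colnames(X), center = sc$center,
                 scale = sc$scale, classes = levels(y)),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> %s penalty, lambda = %g: %d / %d features retained\n",
              x$penalty, x$lambda, sum(x$retained_mask),
              length(x$retained_mask)))
  invisible(x)
}

#' Restrict a feature table to the selector's retained features
#'
#' @param X Feature matrix or data frame whose columns match the model's
#'   feature names (same names, same order).
#' @param model A [fit_selector()] result.
#' @return `X` restricted to the retained columns, order preserved.
#' @export
apply_selection <- function(X, model) {
  stopifnot(inherits(model, "selection_model"))
  Xm <- as.matrix(X)
  if (!identical(colnames(Xm), model$feature_names)) {
    bad <- c(setdiff(colnames(Xm), model$feature_names),
             setdiff(model$feature_names, colnames(Xm)))
    stop("feature names do not match the selection model; offending columns: ",
         paste(utils::head(unique(bad), 10), collapse = ", "))
  }
  Xm[, model$retained_mask, drop = FALSE]
}
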