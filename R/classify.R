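#' The comparison zoo of classifiers
#'
#' One specification per classifier row of the comparison tables, with the
#' documented hyperparameters: linear support vector classifier (l2
#' penalty, cost 1), random forest (200 trees), RBF-kernel SVC, K-nearest
#' neighbours (K = 15), a 40-node logistic-activation neural network with
#' weight-decay 0.001, a more heavily weight-decay-regularized network
#' variant, a fully-grown decision tree (minsplit 2, minbucket 1), an
#' RBF-kernel Gaussian process, Gaussian naive Bayes, l1-penalized
#' logistic regression (inverse regularization strength 1) and a
#' boosted-tree ensemble (depth-3 base learners).
#'
#' @param names Optional character vector selecting a subset by name.
#' @return Named list of `classifier_spec` objects.
#' @export
classifier_zoo <- function(names = NULL) {
  spec <- function(name, label, params, source_table = "Table 2") {
    structure(list(name = name, label = label, params = params,
                   source_table = source_table), class = "classifier_spec")
  }
  zoo <- list(
    linsvc = spec("linsvc", "Linear Support Vector (LinSVC)",
                  list(cost = 1)),
    rf     = spec("rf", "Random Forest (RF)", list(ntree = 200)),
    svc    = spec("svc", "Support Vector Classifier (SVC, RBF)",
                  list(cost = 1)),
    knn    = spec("knn", "K-Nearest Neighbor (KNN)", list(k = 15)),
    nn     = spec("nn", "Neural Network (NN)",
                  list(size = 40, decay = 0.001, maxit = 200)),
    nn_reg = spec("nn_reg", "Neural Network (heavy regularization)",
                  list(size = 40, decay = 0.05, maxit = 200)),
    dt     = spec("dt", "Decision Tree (DT)",
                  list(minsplit = 2, minbucket = 1, cp = 0)),
    gp     = spec("gp", "Gaussian Process (GP, RBF)", list()),
    gnb    = spec("gnb", "Gaussian Naive Bayes (GNB)", list()),
    lr_l1  = spec("lr_l1", "Logistic Regression (l1, C = 1)", list(C = 1)),
    boost  = spec("boost", "Boosted Trees (AB)",
                  list(nrounds = 50, max_depth = 3, eta = 0.3))
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(zoo))
    if (length(missing))
      stop("unknown classifier(s): ", paste(missing, collapse = ", "))
    zoo <- zoo[names]
  }
  zoo
}

# Train `spec` on (Xtr, ytr) and predict labels for Xte. Inputs are already
# standardized and feature-selected; seeds fix stochastic fits.
.fit_predict <- function(spec, Xtr, ytr, Xte, seed = 1) {
  set.seed(as.integer(seed))
  lv <- levels(ytr)
  p <- spec$params
  pred <- switch(spec$name,
    linsvc = {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = p$cost,
                        scale = FALSE)
      stats::predict(fit, Xte)
    },
    svc = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = p$cost,
                        scale = FALSE)
      stats::predict(fit, Xte)
    },
    rf = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = p$ntree)
      stats::predict(fit, Xte)
    },
    knn = {
      class::knn(Xtr, Xte, ytr, k = min(p$k, nrow(Xtr)))
    },
    nn = ,
    nn_reg = {
      fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = p$size,
                        decay = p$decay, maxit = p$maxit, softmax = TRUE,
                        MaxNWts = 100000, trace = FALSE)
      pr <- stats::predict(fit, Xte)
      factor(colnames(pr)[max.col(pr, ties.method = "first")], levels = lv)
    },
    dt = {
      dtr <- data.frame(Xtr, check.names = FALSE)
      dtr$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(
                            minsplit = p$minsplit, minbucket = p$minbucket,
                            cp = p$cp))
      stats::predict(fit, data.frame(Xte, check.names = FALSE),
                     type = "class")
    },
    gp = {
      fit <- suppressMessages(suppressWarnings(
        kernlab::gausspr(Xtr, ytr, kernel = "rbfdot")))
      kernlab::predict(fit, Xte)
    },
    gnb = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      stats::predict(fit, Xte)
    },
    lr_l1 = {
      fit <- glmnet::glmnet(Xtr, ytr, family = "multinomial", alpha = 1,
                            lambda = 1 / (p$C * nrow(Xtr)),
                            standardize = FALSE)
      factor(drop(stats::predict(fit, Xte, type = "class")), levels = lv)
    },
    boost = {
      dtrain <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr) - 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softmax", num_class = length(lv),
                      max_depth = p$max_depth, eta = p$eta, nthread = 1),
        data = dtrain, nrounds = p$nrounds, verbose = 0)
      idx <- stats::predict(fit, xgboost::xgb.DMatrix(Xte))
      factor(lv[idx + 1], levels = lv)
    },
    stop("unknown classifier spec: ", spec$name)
  )
  factor(as.character(pred), levels = lv)
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that class proportions
#' are preserved (indices within each class are shuffled, then dealt
#' round-robin).
#'
#' @param y Class labels.
#' @param k Number of folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  y <- factor(y)
  tab <- table(y)
  if (any(tab < k))
    stop(sprintf("class \"%s\" has only %d members (< k = %d); reduce k",
                 names(tab)[which.min(tab)], min(tab), k))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Compare classifiers under stratified k-fold cross-validation
#'
#' Runs every classifier of the zoo on identical stratified folds (paired
#' comparison). Within each training fold, features are standardized (mean
#' and scale fitted on the training fold only) and, when `select = TRUE`,
#' the regularized-logistic-regression selector is fitted on the training
#' fold and applied to both partitions - no information leaks from the
#' held-out fold. `leaky = TRUE` instead fits the selector once on the full
#' data set (the statistically optimistic variant, available for protocol
#' reproduction).
#'
#' @param X Feature matrix or data frame (subjects x named features).
#' @param y Class labels; every class needs at least `k` members.
#' @param zoo List of classifier specs (default [classifier_zoo()]).
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and stochastic fits.
#' @param select Apply feature selection inside each fold (default `TRUE`).
#' @param penalty,lambda Selector settings (see [fit_selector()]).
#' @param leaky Fit the selector on the whole data set instead of per fold.
#' @return Named list of `cv_report` objects (classifier label,
#'   hyperparameters, per-fold accuracies, mean accuracy, mean retained
#'   feature count, seed).
#' @export
run_comparison <- function(X, y, zoo = classifier_zoo(), k = 10, seed = 1,
                           select = TRUE, penalty = "l1", lambda = 0.01,
                           leaky = FALSE) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nrow(X) != length(y)) stop("`X` and `y` sizes differ")
  fold <- stratified_folds(y, k, seed)
  global_mask <- NULL
  if (select && leaky) {
    sel <- fit_selector(X, y, penalty, lambda, seed = seed)
    global_mask <- sel$retained_mask
  }
  acc <- matrix(NA_real_, k, length(zoo),
                dimnames = list(NULL, names(zoo)))
  n_kept <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    sc <- .fit_scaler(X[tr, , drop = FALSE])
    Xtr <- .apply_scaler(X[tr, , drop = FALSE], sc)
    Xte <- .apply_scaler(X[!tr, , drop = FALSE], sc)
    mask <- rep(TRUE, ncol(X))
    if (select) {
      if (leaky) {
        mask <- global_mask
      } else {
        mask <- tryCatch(
          fit_selector(X[tr, , drop = FALSE], y[tr], penalty, lambda,
                       seed = derive_seed(seed, f))$retained_mask,
          error = function(e) rep(TRUE, ncol(X)))
      }
    }
    n_kept[f] <- sum(mask)
    Xtr <- Xtr[, mask, drop = FALSE]
    Xte <- Xte[, mask, drop = FALSE]
    for (ci in seq_along(zoo)) {
      pr <- .fit_predict(zoo[[ci]], Xtr, y[tr], Xte,
                         seed = derive_seed(seed, f, ci))
      acc[f, ci] <- mean(pr == y[!tr])
    }
  }
  out <- lapply(seq_along(zoo), function(ci) {
    structure(list(classifier = names(zoo)[ci], label = zoo[[ci]]$label,
                   params = zoo[[ci]]$params, per_fold = acc[, ci],
                   mean_accuracy = mean(acc[, ci]), k = k, seed = seed,
                   mean_features_retained = mean(n_kept)),
              class = "cv_report")
  })
  names(out) <- names(zoo)
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean %d-fold accuracy %.3f (folds %s)\n",
              x$label, x$k, x$mean_accuracy,
              paste(sprintf("%.2f", x$per_fold), collapse = " ")))
  invisible(x)
}

#' Assemble a classifier-comparison table
#'
#' Rows are classifiers, columns are skill targets (one mean-CV-accuracy
#' column per element of `reports`), plus a logical `best_{skill}` column
#' flagging each column's maximum (the bold-equivalent marker).
#'
#' @param reports Either a single list of `cv_report`s or a named list of
#'   such lists, one per skill (e.g. `list(fa = ..., wm = ...)`).
#' @return A data frame.
#' @export
report_table <- function(reports) {
  if (length(reports) == 0) stop("`reports` is empty")
  if (inherits(reports[[1]], "cv_report")) reports <- list(accuracy = reports)
  labels <- vapply(reports[[1]], function(r) r$label, character(1))
  out <- data.frame(classifier = unname(labels), stringsAsFactors = FALSE)
  for (skill in names(reports)) {
    v <- vapply(reports[[skill]], function(r) r$mean_accuracy, numeric(1))
    out[[skill]] <- unname(v)
    best <- which.max(v)
    out[[paste0("best_", skill)]] <-
      seq_along(v) == if (length(best)) best else 0L
  }
  out
}

#' Write / read a comparison table losslessly
#'
#' Comma-delimited serialization with full (17 significant digit) numeric
#' precision, so `read_report_table(write_report_table(x)) == x`.
#'
#' @param tab Data frame from [report_table()].
#' @param path File path.
#' @return `read_report_table` returns the data frame.
#' @export
write_report_table <- function(tab, path) {
  fmt <- tab
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  utils::write.csv(fmt, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(tab))
    if (grepl("^best_", names(tab)[j])) tab[[j]] <- as.logical(tab[[j]])
  tab
}
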