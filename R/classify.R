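#' Classifier specification with hyperparameter grid
#'
#' Bundles a classifier kind with the grid searched by the inner
#' cross-validation loop.  Defaults (rows ordered simplest first, the
#' tie-break order): MLP hidden sizes \{2, 5, 10, 20, 40\}; linear-SVM
#' cost \{0.01, 0.1, 1, 10, 100\}; RBF-SVM cost crossed with kernel width
#' gamma \{1e-3, 1e-2, 0.1, 1, 10\}.
#'
#' @param kind `"mlp"`, `"svm_linear"` or `"svm_rbf"`.
#' @param grid Optional data frame of hyperparameter rows overriding the
#'   default (`hidden` for mlp; `cost` for svm_linear; `cost`, `gamma`
#'   for svm_rbf).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("mlp", "svm_linear", "svm_rbf"),
                            grid = NULL) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      mlp = data.frame(hidden = c(2, 5, 10, 20, 40)),
      svm_linear = data.frame(cost = c(0.01, 0.1, 1, 10, 100)),
      svm_rbf = expand.grid(gamma = 10^seq(-3, 1),
                            cost = c(0.01, 0.1, 1, 10, 100)))
  }
  grid <- as.data.frame(grid)
  if (nrow(grid) < 1L) stop("classifier_spec: grid must be nonempty")
  structure(list(kind = kind, grid = grid), class = "classifier_spec")
}

# Deterministic stratified k-fold assignment: within each class, indices
# are shuffled (seeded) and dealt round-robin, so every fold's class count
# differs from perfect proportionality by at most one instance.
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  if (any(table(labels) < k))
    stop("stratified_folds: every class needs at least ", k,
         " members for ", k, "-fold CV; sizes: ",
         paste(table(labels), collapse = ", "))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) which(fold == f))
}

# train-fitted z-score standardization; zero-sd columns pass unscaled
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(center = ctr, scale = sds)
}
apply_scaler <- function(x, sc)
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")

## -- tanh multi-layer perceptron ------------------------------------------
# Single hidden layer with hyperbolic-tangent activation and softmax
# output, cross-entropy objective with a small L2 penalty, trained by BFGS
# with analytic gradients.  Weight init is drawn from the supplied seed.
mlp_fit <- function(x, y, hidden, decay = 1e-3, maxit = 200, seed = 0) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- factor(y)
  lvls <- levels(y)
  k <- length(lvls); d <- ncol(x); h <- as.integer(hidden)
  yi <- as.integer(y)
  n <- nrow(x)
  onehot <- matrix(0, n, k); onehot[cbind(seq_len(n), yi)] <- 1
  n_par <- d * h + h + h * k + k
  unpack <- function(th) list(
    w1 = matrix(th[seq_len(d * h)], d, h),
    b1 = th[d * h + seq_len(h)],
    w2 = matrix(th[d * h + h + seq_len(h * k)], h, k),
    b2 = th[d * h + h + h * k + seq_len(k)])
  fwd <- function(p) {
    z <- tanh(sweep(x %*% p$w1, 2, p$b1, "+"))
    a2 <- sweep(z %*% p$w2, 2, p$b2, "+")
    a2 <- a2 - apply(a2, 1, max)
    e <- exp(a2)
    list(z = z, prob = e / rowSums(e))
  }
  obj <- function(th) {
    p <- unpack(th)
    f <- fwd(p)
    -sum(onehot * log(pmax(f$prob, 1e-12))) / n + decay * sum(th^2)
  }
  grd <- function(th) {
    p <- unpack(th)
    f <- fwd(p)
    dA2 <- (f$prob - onehot) / n                    # n x k
    gw2 <- crossprod(f$z, dA2)
    gb2 <- colSums(dA2)
    dZ <- (dA2 %*% t(p$w2)) * (1 - f$z^2)           # n x h
    gw1 <- crossprod(x, dZ)
    gb1 <- colSums(dZ)
    c(as.vector(gw1), gb1, as.vector(gw2), gb2) + 2 * decay * th
  }
  th0 <- with_seed(seed, stats::runif(n_par, -0.5, 0.5) / sqrt(d + 1))
  fit <- stats::optim(th0, obj, grd, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  structure(list(par = unpack(fit$par), levels = lvls),
            class = "eeg_mlp")
}

#' @export
predict.eeg_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  p <- object$par
  z <- tanh(sweep(x %*% p$w1, 2, p$b1, "+"))
  a2 <- sweep(z %*% p$w2, 2, p$b2, "+")
  factor(object$levels[max.col(a2, ties.method = "first")],
         levels = object$levels)
}

fit_classifier <- function(kind, params, x, y, seed) {
  y <- factor(y)
  switch(kind,
    mlp = mlp_fit(x, y, hidden = params$hidden, seed = seed),
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = params$cost,
                            scale = FALSE),
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = params$cost,
                         gamma = params$gamma, scale = FALSE),
    stop("unknown classifier kind: ", kind))
}

predict_classifier <- function(model, x) {
  if (inherits(model, "eeg_mlp")) predict(model, x)
  else predict(model, x)
}

# inner CV grid selection: returns the best grid row index (ties -> first,
# i.e. the simplest grid point by construction of the default grids)
select_grid_point <- function(spec, x, y, inner_folds, seed) {
  grid <- spec$grid
  if (nrow(grid) == 1L) return(1L)
  folds <- stratified_folds(y, inner_folds, seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(length(folds))
    for (f in seq_along(folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_len(nrow(x)), te)
      sc <- fit_scaler(x[tr, , drop = FALSE])
      xtr <- apply_scaler(x[tr, , drop = FALSE], sc)
      xte <- apply_scaler(x[te, , drop = FALSE], sc)
      model <- fit_classifier(spec$kind, grid[g, , drop = FALSE], xtr,
                              y[tr], seed = derive_seed(seed, g, f))
      acc[f] <- mean(predict_classifier(model, xte) == y[te])
    }
    scores[g] <- mean(acc)
  }
  which.max(scores)        # first maximum: simplest grid point wins ties
}

#' Nested cross-validated accuracy of one classifier on one feature subset
#'
#' Outer stratified `outer_folds`-fold cross-validation estimates
#' generalization accuracy; for each outer fold an inner stratified
#' `inner_folds`-fold loop on the training part alone selects the
#' hyperparameter grid point with the best mean inner accuracy (ties go to
#' the simplest grid point).  The winning configuration is refit on the
#' full outer-training part with z-score feature standardization fitted on
#' training data only, and scored on the held-out fold.  All fold
#' assignments and classifier initializations derive from `seed`, so the
#' result is reproducible.
#'
#' @param x Feature data frame or matrix (numeric columns; a
#'   [extract_feature_matrix()] result may be passed directly — its
#'   `source_id`/`label` columns are dropped).
#' @param labels Class labels, one per row; every class must have at least
#'   `outer_folds` members.
#' @param classifier A [classifier_spec()] (or kind string).
#' @param feature_subset Optional character vector of column names to use.
#' @param seed Integer seed.
#' @param outer_folds,inner_folds Fold counts (default 10 and 10).
#' @param aggregate `"mean_fold"` (mean of per-fold accuracies, default)
#'   or `"pooled"` (accuracy over all pooled outer predictions).
#' @return Accuracy in percent, with attributes `fold_accuracy`,
#'   `chosen_params` and `class_recall`.
#' @export
nested_cv_accuracy <- function(x, labels, classifier = "svm_linear",
                               feature_subset = NULL, seed = 0,
                               outer_folds = 10, inner_folds = 10,
                               aggregate = c("mean_fold", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  xm <- feature_columns(x, feature_subset)
  labels <- factor(labels)
  labels <- droplevels(labels)
  folds <- stratified_folds(labels, outer_folds, derive_seed(seed, 1))
  fold_acc <- numeric(length(folds))
  chosen <- vector("list", length(folds))
  pooled_pred <- factor(rep(NA, length(labels)), levels = levels(labels))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(xm)), te)
    g <- select_grid_point(classifier, xm[tr, , drop = FALSE], labels[tr],
                           inner_folds, derive_seed(seed, 2, f))
    sc <- fit_scaler(xm[tr, , drop = FALSE])
    model <- fit_classifier(classifier$kind,
                            classifier$grid[g, , drop = FALSE],
                            apply_scaler(xm[tr, , drop = FALSE], sc),
                            labels[tr], seed = derive_seed(seed, 3, f))
    pred <- predict_classifier(model,
                               apply_scaler(xm[te, , drop = FALSE], sc))
    fold_acc[f] <- mean(pred == labels[te])
    pooled_pred[te] <- pred
    chosen[[f]] <- classifier$grid[g, , drop = FALSE]
  }
  acc <- if (aggregate == "mean_fold") mean(fold_acc)
         else mean(pooled_pred == labels)
  recall <- vapply(levels(labels), function(cl)
    mean(pooled_pred[labels == cl] == cl), numeric(1))
  structure(100 * acc,
            fold_accuracy = 100 * fold_acc,
            chosen_params = chosen,
            class_recall = 100 * recall)
}

# extract the numeric feature columns (dropping id/label bookkeeping),
# optionally restricted to a named subset
feature_columns <- function(x, feature_subset = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  x <- x[setdiff(colnames(x), c("source_id", "label"))]
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(x))
    if (length(missing))
      stop("unknown feature name(s): ", paste(missing, collapse = ", "))
    x <- x[feature_subset]
  }
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (anyNA(xm)) stop("feature matrix contains missing values")
  xm
}
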