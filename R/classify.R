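#' Fit a centered PCA projection on training features
#'
#' Thin wrapper over [stats::prcomp()] (centering, no per-feature scaling)
#' that stores the projection so held-out rows can be transformed with the
#' training-set loadings only — the training/test separation the
#' cross-validation protocol requires.
#'
#' @param x numeric matrix, rows = training data points.
#' @param n_components number of components to retain; must not exceed
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return An object of class `"feature_pca"`: list with `center`,
#'   `rotation` (columns = components), `sdev` and `n_components`.
#' @export
fit_feature_pca <- function(x, n_components) {
  x <- as.matrix(x)
  n_components <- as.integer(n_components)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components < 1 || n_components > max_rank)
    stop("n_components must be in [1, ", max_rank, "] for this training set")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(center = pr$center,
                 rotation = pr$rotation,
                 sdev = pr$sdev,
                 n_components = n_components),
            class = "feature_pca")
}

#' @export
print.feature_pca <- function(x, ...) {
  cat(sprintf("<feature_pca> %d components over %d features\n",
              x$n_components, length(x$center)))
  invisible(x)
}

#' Project data points into a fitted PCA space
#' @param object a `"feature_pca"` from [fit_feature_pca()].
#' @param newdata matrix (or vector, one point) of rows to transform.
#' @param ... unused.
#' @return Score matrix, one row per data point.
#' @export
predict.feature_pca <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
}

# Multinomial logistic regression on PCA scores. decay = 0.5 mirrors an L2
# penalty ||w||^2 / (2C) at C = 1; maxit raised so 15-dimensional fits
# converge.
.fit_multinom <- function(scores, labels, decay = 0.5, maxit = 500) {
  df <- data.frame(.y = labels, scores)
  nnet::multinom(.y ~ ., data = df, trace = FALSE,
                 decay = decay, maxit = maxit)
}

.predict_multinom <- function(fit, scores) {
  stats::predict(fit, newdata = data.frame(scores), type = "class")
}

#' Fit the biogenicity classifier
#'
#' The core model: centered PCA of the flattened feature images followed by
#' multinomial (multi-class) logistic regression on the component scores.
#' This fits on all supplied data; use [cross_validate()] for the held-out
#' evaluation protocol.
#'
#' @param ds a `"labeled_dataset"` from [featurize_dataset()], or a feature
#'   matrix (then `labels` must be given).
#' @param labels class factor, required when `ds` is a bare matrix.
#' @param n_components PCA dimensionality retained before the logistic
#'   regression (default 15).
#' @param decay L2 weight-decay of the logistic regression; the default 0.5
#'   corresponds to a standard unit-strength ridge penalty.
#' @param maxit optimiser iteration cap.
#' @return An object of class `"biogen_fit"`: list with the `pca`
#'   projection, the multinomial `model`, `n_components`, class `levels`
#'   and the training accuracy.
#' @seealso [predict.biogen_fit()], [cross_validate()], [reconstruct_image()]
#' @export
fit_biogenicity <- function(ds, labels = NULL, n_components = 15,
                            decay = 0.5, maxit = 500) {
  if (inherits(ds, "labeled_dataset")) {
    x <- ds$features
    labels <- ds$labels
  } else {
    x <- as.matrix(ds)
    if (is.null(labels)) stop("labels required with a bare feature matrix")
    labels <- factor(labels)
  }
  pca <- fit_feature_pca(x, n_components)
  scores <- predict(pca, x)
  model <- .fit_multinom(scores, labels, decay, maxit)
  train_pred <- .predict_multinom(model, scores)
  structure(list(pca = pca,
                 model = model,
                 n_components = n_components,
                 levels = levels(labels),
                 labels = labels,
                 train_accuracy = mean(train_pred == labels),
                 call = match.call()),
            class = "biogen_fit")
}

#' @export
print.biogen_fit <- function(x, ...) {
  cat("Biogenicity classifier (PCA + multinomial logistic regression)\n")
  cat(sprintf("  components: %d   classes: %s\n",
              x$n_components, paste(x$levels, collapse = ", ")))
  cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  invisible(x)
}

#' @export
summary.biogen_fit <- function(object, ...) {
  cat("Biogenicity classifier\n")
  print(object)
  cat("  class counts:\n")
  print(table(object$labels))
  cat("  variance explained by retained components: ",
      sprintf("%.1f%%", 100 * sum(object$pca$sdev[seq_len(object$n_components)]^2) /
                sum(object$pca$sdev^2)), "\n", sep = "")
  invisible(object)
}

#' @export
coef.biogen_fit <- function(object, ...) stats::coef(object$model)

#' Predict class labels for new feature vectors
#' @param object a `"biogen_fit"`.
#' @param newdata feature matrix (rows = data points) or a
#'   `"labeled_dataset"`.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.biogen_fit <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "labeled_dataset")) newdata$features else newdata
  .predict_multinom(object$model, predict(object$pca, x))
}

#' Stratified k-fold assignment
#'
#' Assigns data points to `k` folds so that class proportions are preserved
#' per fold (each class's members differ across folds by at most one, as do
#' overall fold sizes). Assignment is a seeded shuffle within each class
#' followed by round-robin distribution with a fold pointer persisting
#' across classes. With `groups`, whole groups (e.g. the even/odd parity
#' pair of one sample) are assigned together, so no group spans train and
#' test.
#'
#' @param labels class factor (or character) per data point.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the shuffle.
#' @param groups optional grouping vector; label must be constant within a
#'   group.
#' @return Integer vector of fold ids in `1:k`, one per data point.
#' @export
stratified_folds <- function(labels, k = 5, seed = 0, groups = NULL) {
  labels <- factor(labels)
  if (k < 2) stop("k must be >= 2")
  if (!is.null(groups)) {
    gl <- split(as.character(labels), groups)
    if (any(vapply(gl, function(v) length(unique(v)), 1L) > 1))
      stop("label not constant within group")
    g_ids <- names(gl)
    g_lab <- factor(vapply(gl, `[[`, "", 1L), levels = levels(labels))
    g_fold <- stratified_folds(g_lab, k, seed)
    return(g_fold[match(groups, g_ids)])
  }
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least k members; smallest has ", min(counts))
  fold <- integer(length(labels))
  set.seed(seed)
  ptr <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
    ptr <- (ptr + length(idx)) %% k
  }
  fold
}

# One fold of the protocol: PCA fit on train rows only, both sides
# transformed, logistic regression on train scores, accuracy on test.
.fold_accuracy <- function(x, labels, train, test, n_components,
                           decay, maxit) {
  pca <- fit_feature_pca(x[train, , drop = FALSE], n_components)
  tr_scores <- predict(pca, x[train, , drop = FALSE])
  te_scores <- predict(pca, x[test, , drop = FALSE])
  fit <- .fit_multinom(tr_scores, labels[train], decay, maxit)
  mean(.predict_multinom(fit, te_scores) == labels[test])
}

#' Stratified k-fold cross-validation of the classifier
#'
#' The evaluation protocol: data points are split into `k` stratified folds
#' (seeded shuffle); for each fold a PCA is fitted on the training portion
#' only, both portions are transformed, a multinomial logistic regression
#' is fitted on the training scores and scored on the held-out fold.
#' Accuracy is the micro-averaged fraction of correct test predictions.
#'
#' @param ds a `"labeled_dataset"`.
#' @param n_components PCA dimensionality.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold shuffle.
#' @param grouped if `TRUE`, the two parity points of one sample are kept in
#'   the same fold (no leakage of near-duplicate pairs). Default `FALSE`,
#'   plain stratification over data points.
#' @param decay,maxit logistic-regression settings (see
#'   [fit_biogenicity()]).
#' @return An object of class `"cv_result"`: list with `n_components`,
#'   `fold_accuracies`, `mean_accuracy`, `sd_accuracy`, `seed`, `k`,
#'   `grouped` and the fold assignment `folds`.
#' @export
cross_validate <- function(ds, n_components, k = 5, seed = 0,
                           grouped = FALSE, decay = 0.5, maxit = 500) {
  stopifnot(inherits(ds, "labeled_dataset"))
  folds <- stratified_folds(ds$labels, k, seed,
                            groups = if (grouped) ds$groups else NULL)
  acc <- vapply(seq_len(k), function(f) {
    .fold_accuracy(ds$features, ds$labels,
                   train = which(folds != f), test = which(folds == f),
                   n_components, decay, maxit)
  }, numeric(1))
  structure(list(n_components = as.integer(n_components),
                 fold_accuracies = acc,
                 mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 seed = seed, k = k, grouped = grouped, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV, %d PCA components (seed %s%s)\n",
              x$k, x$n_components, format(x$seed),
              if (x$grouped) ", grouped" else ""))
  cat(sprintf("  fold accuracies: %s\n",
              paste(sprintf("%.3f", x$fold_accuracies), collapse = " ")))
  cat(sprintf("  mean %.3f  sd %.3f\n", x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Accuracy versus number of PCA components
#'
#' Runs the cross-validation protocol over a grid of PCA dimensionalities
#' with identical fold assignments across the grid, so the curve varies
#' only with dimensionality. Per fold, one PCA is fitted at the largest
#' grid value and its nested leading columns reused for the smaller values
#' (principal components are nested, so this equals refitting).
#'
#' @inheritParams cross_validate
#' @param component_grid ascending integer vector of component counts.
#' @return An object of class `"cv_sweep"`: list of `"cv_result"` objects
#'   plus the grid; has `print` and `plot` methods.
#' @export
sweep_components <- function(ds, component_grid, k = 5, seed = 0,
                             grouped = FALSE, decay = 0.5, maxit = 500) {
  stopifnot(inherits(ds, "labeled_dataset"))
  grid <- as.integer(component_grid)
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stop("component_grid must be nonempty and strictly ascending")
  folds <- stratified_folds(ds$labels, k, seed,
                            groups = if (grouped) ds$groups else NULL)
  n_max <- max(grid)
  acc <- matrix(NA_real_, nrow = length(grid), ncol = k)
  for (f in seq_len(k)) {
    train <- which(folds != f); test <- which(folds == f)
    pca <- fit_feature_pca(ds$features[train, , drop = FALSE], n_max)
    tr <- predict(pca, ds$features[train, , drop = FALSE])
    te <- predict(pca, ds$features[test, , drop = FALSE])
    for (g in seq_along(grid)) {
      m <- grid[g]
      fit <- .fit_multinom(tr[, seq_len(m), drop = FALSE],
                           ds$labels[train], decay, maxit)
      acc[g, f] <- mean(.predict_multinom(
        fit, te[, seq_len(m), drop = FALSE]) == ds$labels[test])
    }
  }
  results <- lapply(seq_along(grid), function(g) {
    structure(list(n_components = grid[g],
                   fold_accuracies = acc[g, ],
                   mean_accuracy = mean(acc[g, ]),
                   sd_accuracy = stats::sd(acc[g, ]),
                   seed = seed, k = k, grouped = grouped, folds = folds),
              class = "cv_result")
  })
  structure(list(grid = grid, results = results, seed = seed, k = k),
            class = "cv_sweep")
}

#' @export
print.cv_sweep <- function(x, ...) {
  cat(sprintf("Component sweep, %d-fold CV (seed %s)\n", x$k, format(x$seed)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.cv_sweep <- function(x, ...) {
  data.frame(n_components = x$grid,
             mean_accuracy = vapply(x$results, `[[`, 0, "mean_accuracy"),
             sd_accuracy = vapply(x$results, `[[`, 0, "sd_accuracy"))
}

#' @export
plot.cv_sweep <- function(x, ...) {
  df <- as.data.frame(x)
  plot(df$n_components, df$mean_accuracy, type = "b", pch = 19,
       ylim = c(0, 1), xlab = "PCA components",
       ylab = "mean test accuracy", ...)
  nonzero <- df$sd_accuracy > 0
  if (any(nonzero))
    arrows(df$n_components[nonzero],
           df$mean_accuracy[nonzero] - df$sd_accuracy[nonzero],
           df$n_components[nonzero],
           df$mean_accuracy[nonzero] + df$sd_accuracy[nonzero],
           angle = 90, code = 3, length = 0.04)
  invisible(df)
}
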