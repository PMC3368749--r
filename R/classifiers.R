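# run code with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a classifier family and its hyperparameter grid
#'
#' Supported families and their tunable hyperparameters:
#' * `svm_rbf` — Gaussian RBF-kernel SVM; regularisation `C` and kernel
#'   width `sigma` (multi-class by one-vs-one vote).
#' * `svm_poly` — polynomial-kernel SVM; `C`, `scale`, `degree`.
#' * `knn` — k-nearest neighbours in the (scaled) descriptor space,
#'   Euclidean distance; `k`. Vote ties are broken by the nearest
#'   neighbour's class, so prediction is deterministic.
#' * `rf` — Random Forest; `mtry` (descriptors tried per split; `NA`
#'   entries are resolved at fit time from M, the number of
#'   descriptors, as floor(sqrt(M)/2), ceiling(sqrt(M)) and
#'   2*ceiling(sqrt(M))) and `n_trees`.
#'
#' Grids are fixed-step lists in the CARET style; every combination is
#' evaluated by inner cross-validated accuracy and the best is kept.
#'
#' @param family one of `"svm_rbf"`, `"svm_poly"`, `"knn"`, `"rf"`.
#' @param grid optional named list of hyperparameter value vectors
#'   overriding the defaults.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm_rbf", "svm_poly", "knn", "rf"),
                            grid = NULL) {
  family <- match.arg(family)
  default <- switch(family,
    svm_rbf = list(C = c(0.25, 1, 4, 16, 64, 256),
                   sigma = 4^(-3:1)),              # 2^-6 .. 2^2 by powers of 4
    svm_poly = list(C = c(0.25, 1, 4, 16, 64, 256),
                    scale = c(0.01, 0.1, 1), degree = c(2, 3)),
    knn = list(k = c(1, 3, 5, 7, 9, 11)),
    rf = list(mtry = NA_real_, n_trees = 500))
  if (!is.null(grid)) default[names(grid)] <- grid
  if (any(vapply(default, length, 1L) == 0L)) stop("empty hyperparameter grid")
  structure(list(family = family, grid = default), class = "classifier_spec")
}

# expand the grid into a data.frame of candidate settings; rf's NA mtry
# placeholder is resolved from the number of descriptors M
grid_points <- function(spec, M) {
  g <- spec$grid
  if (spec$family == "rf" && anyNA(g$mtry)) {
    r <- sqrt(M)
    derived <- unique(pmax(1, pmin(M, c(floor(r / 2), ceiling(r), 2 * ceiling(r)))))
    g$mtry <- sort(unique(c(g$mtry[!is.na(g$mtry)], derived)))
  }
  expand.grid(g, KEEP.OUT.ATTRS = FALSE)
}

# fit one model; X is the (already scaled) training matrix
fit_classifier <- function(spec, params, X, y, seed = 1L) {
  y <- factor(y, levels = sort(unique(y)))
  switch(spec$family,
    svm_rbf = with_seed(seed, e1071::svm(
      x = X, y = y, kernel = "radial", cost = params$C, gamma = params$sigma,
      scale = FALSE)),
    svm_poly = with_seed(seed, e1071::svm(
      x = X, y = y, kernel = "polynomial", cost = params$C,
      gamma = params$scale, coef0 = 1, degree = params$degree, scale = FALSE)),
    knn = structure(list(X = X, y = as.integer(as.character(y)), k = params$k),
                    class = "knn_model"),
    rf = with_seed(seed, randomForest::randomForest(
      x = X, y = y, mtry = params$mtry, ntree = params$n_trees)))
}

predict_classifier <- function(spec, model, Xnew) {
  if (spec$family == "knn") return(predict_knn(model, Xnew))
  as.integer(as.character(predict(model, Xnew)))
}

# deterministic kNN: Euclidean distance, majority vote, vote ties broken
# by the class of the nearest neighbour among the tied classes; distance
# ties broken by training order
predict_knn <- function(model, Xnew) {
  X <- model$X; y <- model$y; k <- min(model$k, nrow(X))
  x2 <- rowSums(X^2)
  out <- integer(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    d2 <- x2 - 2 * as.vector(X %*% Xnew[i, ]) + sum(Xnew[i, ]^2)
    ord <- order(d2)           # stable: ties keep training order
    nn <- ord[seq_len(k)]
    votes <- table(y[nn])
    top <- as.integer(names(votes)[votes == max(votes)])
    if (length(top) == 1L) out[i] <- top
    else out[i] <- y[nn][match(TRUE, y[nn] %in% top)]
  }
  out
}

#' Tune hyperparameters by inner cross-validated accuracy
#'
#' Evaluates every point of the specification's grid by `inner_folds`-
#' fold cross-validation on the training data only (the outer test fold
#' is never seen), and returns the setting with the highest accuracy;
#' ties are broken by grid order. A single-point grid is returned
#' directly without resampling.
#'
#' @param spec a [classifier_spec()].
#' @param X scaled training matrix.
#' @param y integer class labels (>= 2 classes).
#' @param inner_folds folds for the internal resampling (default 5).
#' @param seed RNG seed for the inner fold assignment and stochastic
#'   fits.
#' @return one-row data.frame of chosen hyperparameters, with attribute
#'   `"inner_accuracy"`.
#' @export
tune <- function(spec, X, y, inner_folds = 5L, seed = 1L) {
  if (length(unique(y)) < 2L) stop("cannot tune on single-class training data")
  grid <- grid_points(spec, ncol(X))
  if (nrow(grid) == 1L) return(grid)
  inner_folds <- min(inner_folds, nrow(X))
  assign_ <- make_folds(nrow(X), inner_folds, seed = seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      te <- which(assign_ == f)
      if (length(te) == 0L || length(unique(y[-te])) < 2L) next
      m <- fit_classifier(spec, grid[g, , drop = FALSE], X[-te, , drop = FALSE],
                          y[-te], seed = seed + f)
      correct <- correct + sum(predict_classifier(spec, m, X[te, , drop = FALSE]) == y[te])
    }
    acc[g] <- correct / nrow(X)
  }
  best <- which.max(acc)   # first index on ties = first grid order
  out <- grid[best, , drop = FALSE]
  attr(out, "inner_accuracy") <- acc[best]
  out
}
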