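#' Confusion matrix
#'
#' @param true_labels,predicted_labels equal-length integer vectors with
#'   values in `1..K`.
#' @param K number of classes (default 6, the EC top-level classes).
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, K = 6L) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  lab <- c(true_labels, predicted_labels)
  if (length(lab) && (any(is.na(lab)) || any(lab < 1L) || any(lab > K) ||
                      any(lab != round(lab))))
    stop(sprintf("labels must be integers in 1..%d", K))
  cm <- matrix(0L, K, K, dimnames = list(true = 1:K, predicted = 1:K))
  for (i in seq_along(true_labels))
    cm[true_labels[i], predicted_labels[i]] <- cm[true_labels[i], predicted_labels[i]] + 1L
  cm
}

#' Overall accuracy
#'
#' The proportion of predictions that are correct: trace over total.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Per-class accuracy (class recall)
#'
#' For each true class with at least one instance, the fraction of its
#' instances predicted correctly. Classes absent from the truth are
#' reported as `NA`, not 0.
#'
#' @param cm confusion matrix.
#' @return named numeric vector, one value (or `NA`) per class.
#' @export
per_class_accuracy <- function(cm) {
  rt <- rowSums(cm)
  out <- ifelse(rt > 0, diag(cm) / rt, NA_real_)
  names(out) <- rownames(cm)
  out
}

#' Gorodkin's K-category correlation coefficient
#'
#' The multi-class generalisation of the Matthews correlation
#' coefficient, a balanced measure of prediction success across
#' unbalanced classes. With `N` predictions, row sums `t_k`, column
#' sums `p_k` and trace `c`:
#' `R_K = (N c - sum t_k p_k) / sqrt((N^2 - sum p_k^2)(N^2 - sum t_k^2))`.
#' On a 2 x 2 table this equals the binary Matthews coefficient. When a
#' denominator factor is 0 (all truth or all predictions in one class)
#' the coefficient is defined as 0.
#'
#' @param cm confusion matrix.
#' @return value in `[-1, 1]`.
#' @export
gorodkin_rk <- function(cm) {
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  cm <- matrix(as.numeric(cm), nrow(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  num <- N * sum(diag(cm)) - sum(tk * pk)
  d1 <- N^2 - sum(pk^2); d2 <- N^2 - sum(tk^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  num / sqrt(d1 * d2)
}

#' Exhaustive fold-wise permutation test for a classifier pair
#'
#' Compares two classifiers evaluated on the same cross-validation
#' folds. With `NA_i`/`NB_i` the numbers of correct predictions on fold
#' i, the observed difference is `D_0 = sum_i (NA_i - NB_i)`. All `2^F`
#' sign assignments `D_p = sum_i +/-(NA_i - NB_i)` are enumerated
#' (F = 10 folds gives 1024 permutations). Under the default two-sided
#' criterion `n = #{|D_p| >= |D_0|}` and `p = n / 2^F`; `n` can never be
#' smaller than 2, because both `D_0` and `-D_0` occur among the
#' permuted values. The one-sided option counts `D_p >= D_0`.
#'
#' @param a,b per-fold correct-prediction counts for the two
#'   classifiers: equal-length numeric vectors, or `cv_result` objects
#'   from [cross_validate()] (their `fold_correct` is used, and the fold
#'   structures must match).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return object of class `permutation_result`: list with `D0`,
#'   `Dp` (all `2^F` permuted differences), `n`, `p`, `sidedness`.
#' @export
permutation_test <- function(a, b, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (inherits(a, "cv_result") && inherits(b, "cv_result")) {
    if (!identical(a$fold_sizes, b$fold_sizes))
      stop("classifiers were evaluated on different fold structures")
    a <- a$fold_correct; b <- b$fold_correct
  }
  if (length(a) != length(b)) stop("mismatched number of folds")
  F <- length(a)
  if (F < 1L || F > 20L) stop("need between 1 and 20 folds (exhaustive enumeration)")
  d <- as.numeric(a) - as.numeric(b)
  D0 <- sum(d)
  idx <- 0:(2^F - 1)
  Dp <- numeric(2^F)
  for (i in seq_len(F)) {
    sign_i <- ifelse(bitwAnd(idx, bitwShiftL(1L, i - 1L)) > 0L, 1, -1)
    Dp <- Dp + sign_i * d[i]
  }
  n <- if (sidedness == "two") sum(abs(Dp) >= abs(D0)) else sum(Dp >= D0)
  structure(list(D0 = D0, Dp = Dp, n = n, p = n / 2^F, sidedness = sidedness),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("fold-wise permutation test (%s-sided): D0 = %g, n = %d of %d, p = %.4g\n",
              x$sidedness, x$D0, x$n, length(x$Dp), x$p))
  invisible(x)
}
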