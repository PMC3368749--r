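#' Fit z-scaling parameters on a training matrix
#'
#' Per-feature mean and population standard deviation, so that the
#' fitted-then-applied training columns have mean 0 and standard
#' deviation 1. Test matrices are transformed with the training-set
#' parameters, never their own.
#'
#' @param mat numeric matrix (entries x features).
#' @return object of class `scaling_params`: list with `features`,
#'   `mean`, `sd` (population sd; 0 for constant columns).
#' @export
zscale_fit <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  n <- nrow(mat)
  mu <- colMeans(mat)
  sdev <- sqrt(colMeans(sweep(mat, 2L, mu)^2))
  structure(list(features = colnames(mat), mean = mu, sd = sdev),
            class = "scaling_params")
}

#' Apply z-scaling parameters
#'
#' Constant training columns (sd = 0) map to all zeros and are kept, so
#' matrix shapes stay stable across cross-validation folds.
#'
#' @param mat numeric matrix whose columns match `params$features`.
#' @param params a `scaling_params` object from [zscale_fit()].
#' @return the scaled matrix.
#' @export
zscale_apply <- function(mat, params) {
  stopifnot(inherits(params, "scaling_params"), is.matrix(mat))
  if (!identical(colnames(mat), params$features))
    stop("feature mismatch between matrix and scaling parameters")
  sd_safe <- ifelse(params$sd == 0, 1, params$sd)
  out <- sweep(sweep(mat, 2L, params$mean), 2L, sd_safe, `/`)
  out[, params$sd == 0] <- 0
  out
}
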