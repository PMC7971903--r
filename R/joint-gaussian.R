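#' Joint Gaussian description of a (past, future) pair
#'
#' Bundles the zero-mean second-order statistics of a jointly Gaussian pair
#' of random vectors: the marginal covariances of the past and future blocks,
#' their cross-covariance, and the conditional covariance of the past given
#' the future, \eqn{\Sigma_{X_t|X_{t+\Delta t}} = \Sigma_p - \Sigma_c
#' \Sigma_f^{-1} \Sigma_c^\top}. This object is the input to the Gaussian
#' information-bottleneck solver.
#'
#' @param sigma_past Covariance matrix of the past vector (symmetric positive
#'   definite).
#' @param sigma_future Covariance matrix of the future vector.
#' @param sigma_cross Cross-covariance `cov(past, future)`, with past indexing
#'   rows.
#' @return An object of class `pib_joint_gaussian` with elements `dim_past`,
#'   `dim_future`, `sigma_past`, `sigma_future`, `sigma_cross`,
#'   `sigma_past_given_future` and `mi_bits`, the total mutual information
#'   \eqn{I(X_t; X_{t+\Delta t})} in bits.
#' @examples
#' j <- joint_gaussian(diag(2), diag(2), 0.5 * diag(2))
#' j$mi_bits
#' @export
joint_gaussian <- function(sigma_past, sigma_future, sigma_cross) {
  sigma_past <- as.matrix(sigma_past)
  sigma_future <- as.matrix(sigma_future)
  sigma_cross <- as.matrix(sigma_cross)
  dp <- nrow(sigma_past)
  df <- nrow(sigma_future)
  if (!identical(dim(sigma_cross), c(dp, df))) {
    stop("sigma_cross must be dim_past x dim_future", call. = FALSE)
  }
  sigma_past <- symmetrize(sigma_past)
  sigma_future <- symmetrize(sigma_future)
  if (!is_pd(sigma_past)) {
    stop("invalid model: sigma_past is not positive definite", call. = FALSE)
  }
  if (!is_pd(sigma_future)) {
    stop("invalid model: sigma_future is not positive definite", call. = FALSE)
  }
  spf <- symmetrize(sigma_past - sigma_cross %*% solve(sigma_future, t(sigma_cross)))
  if (!is_psd(spf)) {
    stop("invalid model: conditional covariance sigma_past_given_future is not PSD",
         call. = FALSE)
  }
  ## numerical floor keeps downstream determinants finite
  spf <- psd_floor(spf)
  mi <- 0.5 * (log2_det(sigma_past) - log2_det(spf))
  structure(
    list(
      dim_past = dp, dim_future = df,
      sigma_past = sigma_past, sigma_future = sigma_future,
      sigma_cross = sigma_cross, sigma_past_given_future = spf,
      mi_bits = max(mi, 0)
    ),
    class = "pib_joint_gaussian"
  )
}

#' @export
print.pib_joint_gaussian <- function(x, ...) {
  cat("<pib_joint_gaussian> past dim", x$dim_past, "| future dim", x$dim_future,
      sprintf("| I(past;future) = %.4f bits\n", x$mi_bits))
  invisible(x)
}
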