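#' Steady-state Kalman-filter baseline for the oscillator
#'
#' Filters noisy observations of the oscillator state (both coordinates
#' observed with isotropic noise `r * I`) at a fixed cadence, iterates the
#' discrete Riccati recursion to its steady state, and places the filter's
#' posterior mean on the information plane using the same Gaussian
#' mutual-information formulas as the bottleneck solver. The posterior mean
#' is a linear-Gaussian function of the current state (conditionally
#' independent of the future given the present), so each filter point must
#' lie on or below the information-bottleneck curve: Kalman filtering is not
#' an efficient coder for a given channel capacity.
#'
#' @param params A [sddho_params()] object.
#' @param obs_noise_grid Positive observation-noise variances to sweep.
#' @param dt_obs Observation interval; defaults to the prediction lag.
#' @param tol Relative convergence tolerance of the Riccati iteration.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return A tibble with columns `obs_noise`, `i_past_bits`, `i_future_bits`.
#' @export
kalman_curve <- function(params, obs_noise_grid, dt_obs = params$dt_pred,
                         tol = 1e-12, max_iter = 100000L) {
  stopifnot(inherits(params, "pib_sddho_params"), all(obs_noise_grid > 0))
  S <- sddho_stationary_cov(params$zeta)
  M <- sddho_drift(params$zeta)
  F_obs <- mat_exp(M * dt_obs)
  Q <- symmetrize(S - F_obs %*% S %*% t(F_obs))
  F_pred <- mat_exp(M * params$dt_pred)
  rows <- lapply(obs_noise_grid, function(r) {
    P <- kalman_steady_posterior(F_obs, Q, r, S, tol, max_iter)
    C <- symmetrize(S - P)            # cov(state, estimate) = cov(estimate)
    ip <- gaussian_mi_bits(C, S, C)
    ifu <- gaussian_mi_bits(C, S, C %*% t(F_pred))
    tibble::tibble(obs_noise = r, i_past_bits = ip, i_future_bits = ifu)
  })
  dplyr::bind_rows(rows)
}

## Steady-state posterior covariance of the filter x' = F x + w, y = x + e.
kalman_steady_posterior <- function(F_obs, Q, r, S, tol, max_iter) {
  P <- S
  R <- r * diag(nrow(S))
  for (k in seq_len(max_iter)) {
    Pp <- F_obs %*% P %*% t(F_obs) + Q
    K <- t(solve(Pp + R, Pp))
    Pn <- symmetrize((diag(nrow(S)) - K) %*% Pp)
    if (max(abs(Pn - P)) <= tol * max(max(abs(P)), 1e-300)) return(Pn)
    P <- Pn
  }
  stop("Riccati iteration did not converge after ", max_iter, " iterations",
       call. = FALSE)
}

## MI in bits between Gaussian vectors u, w given cov(u) = Su, cov(w) = Sw,
## cross = cov(u, w). Guarded against singular posterior covariances.
gaussian_mi_bits <- function(Su, Sw, cross) {
  ev <- eigen(symmetrize(Su), symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 1e-300) return(0)
  cond <- symmetrize(Su - cross %*% solve(Sw, t(cross)))
  cond <- psd_floor(cond, rtol = 1e-14)
  mi <- 0.5 * (log2_det(psd_floor(Su, rtol = 1e-14)) - log2_det(cond))
  max(mi, 0)
}
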