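#' Parameters of the generalized Langevin model
#'
#' A harmonically bound particle with power-law friction kernel
#' \eqn{\gamma |t - t'|^{-\alpha}} and fluctuation-dissipation-consistent
#' noise. The bottleneck analysis uses windows of positions: the past window
#' spans `[t - t0, t]` and the future window `[t + dt_pred, t + dt_pred + t0]`,
#' both sampled every `dt_grid` (so a window holds
#' `round(t0/dt_grid) + 1` points). Velocities are excluded from the
#' windows; densely sampled positions carry the same information.
#'
#' @param alpha Power-law exponent, > 0 (position autocovariance tail
#'   `~ t^-alpha`).
#' @param omega0 Restoring frequency.
#' @param gamma Friction amplitude.
#' @param dt_sim Integration step of the simulator.
#' @param t0 History/future window length.
#' @param dt_pred Prediction lag.
#' @param dt_grid Sampling interval of the windows (defaults to `t0 / 4`).
#' @param kernel_horizon Truncation horizon of the memory kernel (defaults
#'   to `10 * t0`).
#' @param noise_scale Amplitude of the power-law noise covariance; the
#'   default `NULL` means fluctuation-dissipation balance (amplitude equal
#'   to `gamma`, unit temperature).
#' @return An object of class `pib_gle_params`.
#' @export
gle_params <- function(alpha = 0.5, omega0 = 0.5, gamma = 2, dt_sim = 0.02,
                       t0 = 1, dt_pred = 1, dt_grid = NULL,
                       kernel_horizon = NULL, noise_scale = NULL) {
  stopifnot(alpha > 0, omega0 >= 0, gamma >= 0, dt_sim > 0, t0 >= 0,
            dt_pred > 0)
  dt_grid <- dt_grid %||% max(t0 / 4, dt_sim)
  if (t0 > 0 && dt_sim >= t0) stop("dt_sim must be smaller than t0", call. = FALSE)
  structure(list(alpha = alpha, omega0 = omega0, gamma = gamma,
                 dt_sim = dt_sim, t0 = t0, dt_pred = dt_pred,
                 dt_grid = dt_grid,
                 window_points = as.integer(round(t0 / dt_grid)) + 1L,
                 kernel_horizon = kernel_horizon %||% (10 * max(t0, 1)),
                 noise_scale = noise_scale),
            class = "pib_gle_params")
}

#' @export
print.pib_gle_params <- function(x, ...) {
  cat(sprintf("<pib_gle_params> alpha = %g, omega0 = %g, gamma = %g | t0 = %g, dt = %g (%d window points)\n",
              x$alpha, x$omega0, x$gamma, x$t0, x$dt_pred, x$window_points))
  invisible(x)
}

#' Stationary position autocovariance of the generalized Langevin model
#'
#' Estimated from seeded trajectory replicates (the stationary law of the
#' power-law model has no simple closed form): each replicate contributes an
#' empirical autocovariance of position on the simulation grid; the mean and
#' the standard error across replicates are returned.
#'
#' @param params A [gle_params()] object.
#' @param n_traj Number of replicate trajectories.
#' @param traj_len Steps per trajectory (must comfortably exceed the lags
#'   needed: `2 * t0 + dt_pred`).
#' @param burn_in Steps dropped from the start of each replicate (at least a
#'   quarter of the trajectory).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param max_lag_time Largest lag (time units) to estimate; defaults to
#'   just beyond the window requirement `2 t0 + dt_pred`.
#' @return A tibble of class `pib_gle_acov` with columns `lag` (time),
#'   `acov`, `se`, and attribute `params`.
#' @export
gle_autocovariance <- function(params, n_traj = 8L, traj_len = 2000L,
                               burn_in = ceiling(traj_len / 4), seed = 1L,
                               max_lag_time = NULL) {
  stopifnot(inherits(params, "pib_gle_params"))
  need <- max_lag_time %||% (1.2 * (2 * params$t0 + params$dt_pred))
  if (traj_len * params$dt_sim <= 2.5 * need) {
    stop("traj_len too short for the requested windows", call. = FALSE)
  }
  max_lag <- min(ceiling(need / params$dt_sim) + 2L,
                 floor((traj_len - burn_in) / 2))
  acfs <- vapply(seq_len(n_traj), function(r) {
    tr <- simulate_gle(params, traj_len, seed = child_seed(seed, r))
    x <- tr$states[-seq_len(burn_in), "x"]
    x <- x - mean(x)
    n <- length(x)
    vapply(0:max_lag, function(l) sum(x[1:(n - l)] * x[(1 + l):n]) / (n - l), 0)
  }, numeric(max_lag + 1L))
  est <- rowMeans(acfs)
  se <- apply(acfs, 1, stats::sd) / sqrt(n_traj)
  out <- tibble::tibble(lag = (0:max_lag) * params$dt_sim, acov = est, se = se)
  attr(out, "params") <- params
  attr(out, "replicates") <- acfs
  class(out) <- c("pib_gle_acov", class(out))
  out
}

#' Jackknife replicates of an autocovariance estimate
#'
#' Leave-one-trajectory-out versions of a [gle_autocovariance()] estimate,
#' used to put Monte-Carlo error bands on derived information quantities.
#'
#' @param acov A [gle_autocovariance()] result.
#' @return A list of acov tibbles, one per left-out replicate.
#' @export
gle_acov_jackknife <- function(acov) {
  reps <- attr(acov, "replicates")
  if (is.null(reps)) stop("acov carries no replicate record", call. = FALSE)
  lags <- acov$lag
  ses <- acov$se
  lapply(seq_len(ncol(reps)), function(r) {
    out <- tibble::tibble(lag = lags,
                          acov = rowMeans(reps[, -r, drop = FALSE]),
                          se = ses)
    attr(out, "params") <- attr(acov, "params")
    class(out) <- c("pib_gle_acov", class(out))
    out
  })
}

## Look up c(|tau|) on the simulation grid by nearest index.
acov_at <- function(acov, tau) {
  dt <- acov$lag[2] - acov$lag[1]
  i <- round(abs(tau) / dt) + 1L
  if (any(i > nrow(acov))) {
    stop("autocovariance does not cover the requested lags; extend traj_len",
         call. = FALSE)
  }
  acov$acov[i]
}

#' Extended-history joint Gaussian of the generalized Langevin model
#'
#' Stacks the past window \eqn{X_{t-t_0:t}} and future window
#' \eqn{X_{t+\Delta t:t+\Delta t+t_0}} of positions into a jointly Gaussian
#' pair whose block-Toeplitz covariance is filled from the estimated
#' stationary autocovariance; the result is eigenvalue-floored to the
#' nearest PSD matrix before use.
#'
#' @param params A [gle_params()] object.
#' @param acov A [gle_autocovariance()] result covering lags up to
#'   `2 * t0 + dt_pred`.
#' @return A [joint_gaussian()] over `window_points`-dimensional past and
#'   future.
#' @export
gle_extended_joint <- function(params, acov) {
  w <- params$window_points
  tp <- -rev(seq(0, params$t0, length.out = w))          # past sample times
  tf <- params$dt_pred + seq(0, params$t0, length.out = w)
  tt <- c(tp, tf)
  ## The autocovariance is estimated, so the assembled matrix need not be
  ## PSD: floor the spectrum of the full stacked covariance (relative floor
  ## 1e-10 of the leading eigenvalue) before extracting blocks. Window
  ## spacings close to the simulation grid leave eigen-directions dominated
  ## by estimation noise and inflate the information; keep dt_grid a
  ## comfortable multiple of dt_sim (see the jackknife band helpers).
  S <- outer(tt, tt, function(a, b) acov_at(acov, a - b))
  e <- eigen(symmetrize(S), symmetric = TRUE)
  lam <- pmax(e$values, 1e-10 * max(e$values))
  S <- symmetrize(e$vectors %*% (lam * t(e$vectors)))
  ip <- seq_len(w)
  joint_gaussian(S[ip, ip], S[-ip, -ip], S[ip, -ip, drop = FALSE])
}

#' Saturation of predictive information with history length
#'
#' For each window length in `t0_list`, rebuilds the extended joint and
#' records the predictive information extracted by the optimal encoder at a
#' large tradeoff `beta_large` together with the window's total mutual
#' information. The window sampling interval `dt_grid` is held fixed across
#' the list, so successive windows are nested and the true curve is
#' nondecreasing with diminishing increments: using more history helps, with
#' rapidly saturating gains.
#'
#' @param params A [gle_params()] object (its `t0` is overridden per entry).
#' @param t0_list Ascending history lengths (0 means single-point windows).
#' @param beta_large Tradeoff used for the near-lossless encoder.
#' @param dt_grid Shared window sampling interval (default: spacing of the
#'   largest window in `params`-style, `max(t0)/4`).
#' @param acov Optional shared [gle_autocovariance()]; by default one is
#'   estimated with lags covering the largest window.
#' @param ... Passed to [gle_autocovariance()] when `acov` is missing.
#' @return A tibble with `t0`, `window_points`, `i_past_bits`,
#'   `i_future_bits`, `total_mi_bits`.
#' @export
saturation_curve <- function(params, t0_list, beta_large = 1e3,
                             dt_grid = NULL, acov = NULL, ...) {
  stopifnot(!is.unsorted(t0_list))
  dt_grid <- dt_grid %||% max(max(t0_list) / 4, params$dt_sim)
  pmax_ <- modify_gle(params, t0 = max(t0_list), dt_grid = dt_grid)
  acov <- acov %||% gle_autocovariance(pmax_, ...)
  rows <- lapply(t0_list, function(t0) {
    p <- modify_gle(params, t0 = t0, dt_grid = dt_grid)
    j <- gle_extended_joint(p, acov)
    pt <- evaluate_encoder(optimal_encoder(j, beta_large), j)
    tibble::tibble(t0 = t0, window_points = p$window_points,
                   i_past_bits = pt$i_past_bits,
                   i_future_bits = pt$i_future_bits,
                   total_mi_bits = j$mi_bits)
  })
  dplyr::bind_rows(rows)
}

## rebuild params with some fields changed, keeping the window spacing fixed
modify_gle <- function(params, t0 = params$t0, dt_grid = params$dt_grid) {
  gle_params(alpha = params$alpha, omega0 = params$omega0,
             gamma = params$gamma, dt_sim = params$dt_sim, t0 = t0,
             dt_pred = params$dt_pred,
             dt_grid = max(dt_grid, params$dt_sim),
             kernel_horizon = params$kernel_horizon,
             noise_scale = params$noise_scale)
}
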