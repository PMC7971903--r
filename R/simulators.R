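#' Simulate the rescaled oscillator exactly
#'
#' Draws a stationary trajectory of the (position, velocity) pair using the
#' exact discrete-time Gaussian transition: one step of length `dt_sim` maps
#' \eqn{X \to e^{M\,dt} X + \eta} with \eqn{\eta \sim N(0, \Sigma - e^{M dt}
#' \Sigma e^{M^\top dt})}. There is no Euler discretization bias, so the
#' sample moments converge to the analytic stationary covariance at the
#' Monte-Carlo rate.
#'
#' @param zeta Damping coefficient.
#' @param dt_sim Sampling interval.
#' @param n_steps Number of stored steps.
#' @param seed Integer seed (bit-for-bit reproducible).
#' @param noise Logical; `FALSE` gives the deterministic damped oscillator.
#' @param x0 Optional initial state (length 2); default is a stationary draw.
#' @return An object of class `pib_trajectory`: list with `times`, `states`
#'   (n x 2 matrix, columns x, v), `seed`, `params`.
#' @export
simulate_sddho <- function(zeta, dt_sim, n_steps, seed = 1L, noise = TRUE,
                           x0 = NULL) {
  stopifnot(zeta > 0, dt_sim > 0, n_steps >= 1)
  S <- sddho_stationary_cov(zeta)
  F1 <- mat_exp(sddho_drift(zeta) * dt_sim)
  Q <- symmetrize(S - F1 %*% S %*% t(F1))
  L <- t(chol(psd_floor(Q, rtol = 1e-14)))
  states <- matrix(0, n_steps, 2)
  withr::with_seed(seed, {
    x <- x0 %||% drop(t(chol(S)) %*% stats::rnorm(2))
    if (!noise) x <- x0 %||% c(1, 0)
    eps <- if (noise) matrix(stats::rnorm(2 * n_steps), 2) else matrix(0, 2, n_steps)
    for (k in seq_len(n_steps)) {
      x <- drop(F1 %*% x) + drop(L %*% eps[, k])
      states[k, ] <- x
    }
  })
  structure(list(times = dt_sim * seq_len(n_steps), states = states,
                 seed = seed, params = list(zeta = zeta, dt_sim = dt_sim)),
            class = "pib_trajectory")
}

#' Simulate the binomial Wright-Fisher chain
#'
#' The discrete population process: each generation the `N` offspring are
#' drawn binomially around the post-selection, post-mutation expected
#' frequency \eqn{f(X) = X + sX(1-X) + \mu(1-2X)} (clipped to `[0, 1]`).
#' Under neutral parameters the mean frequency is a martingale.
#'
#' @param params A [wf_params()] object.
#' @param n_gen Number of generations.
#' @param n_reps Number of independent replicate chains.
#' @param seed Integer seed.
#' @param x0 Initial frequency (scalar or length `n_reps`); default 0.5.
#' @return A `pib_trajectory` whose `states` is an `n_gen x n_reps` matrix
#'   of allele frequencies.
#' @export
simulate_wf <- function(params, n_gen, n_reps = 1L, seed = 1L, x0 = 0.5) {
  stopifnot(inherits(params, "pib_wf_params"))
  N <- params$N
  states <- matrix(0, n_gen, n_reps)
  withr::with_seed(seed, {
    x <- rep_len(x0, n_reps)
    for (g in seq_len(n_gen)) {
      f <- wf_update_mean(x, params)
      x <- stats::rbinom(n_reps, N, f) / N
      states[g, ] <- x
    }
  })
  structure(list(times = seq_len(n_gen), states = states, seed = seed,
                 params = params),
            class = "pib_trajectory")
}

#' Simulate generalized Langevin dynamics with power-law memory
#'
#' Integrates
#' \eqn{\dot v = -\gamma \int_0^t v(t')\,|t-t'|^{-\alpha}\,dt' - \omega_0^2 x
#' + \xi(t)} with fluctuation-dissipation-consistent noise
#' \eqn{\langle\xi(t)\xi(t')\rangle \propto |t-t'|^{-\alpha}}. The memory
#' integral uses the trapezoid rule over a kernel truncated at
#' `kernel_horizon`; the kernel's integrable singularity at equal times is
#' regularized by offsetting \eqn{|t - t'|} by `dt_sim`. The correlated
#' noise is drawn by factorizing (Cholesky) the power-law covariance over
#' the whole trajectory.
#'
#' @param params A [gle_params()] object.
#' @param n_steps Number of integration steps (capped so the noise
#'   factorization stays tractable).
#' @param seed Integer seed.
#' @return A `pib_trajectory` with `states` an `n_steps x 2` matrix (x, v).
#' @export
simulate_gle <- function(params, n_steps, seed = 1L) {
  stopifnot(inherits(params, "pib_gle_params"), n_steps >= 10)
  if (n_steps > 6000) {
    stop("n_steps too large for dense noise factorization; use replicates",
         call. = FALSE)
  }
  dt <- params$dt_sim
  horizon <- max(params$kernel_horizon, 10 * params$t0)
  nk <- min(n_steps, ceiling(horizon / dt))
  kern <- params$gamma / (dt * (0:(nk - 1)) + dt)^params$alpha
  ## FDT-consistent noise: covariance proportional to the friction kernel
  tau <- abs(outer(0:(n_steps - 1), 0:(n_steps - 1), "-")) * dt
  amp <- params$noise_scale %||% params$gamma
  Cn <- amp / (tau + dt)^params$alpha
  Ln <- t(chol(Cn + diag(1e-10 * Cn[1, 1], n_steps)))
  x <- numeric(n_steps + 1L)
  v <- numeric(n_steps + 1L)
  withr::with_seed(seed, {
    xi <- drop(Ln %*% stats::rnorm(n_steps))
    for (k in seq_len(n_steps)) {
      idx <- max(1L, k - nk + 1L):k
      w <- rep(dt, length(idx)); w[1] <- dt / 2; w[length(w)] <- dt / 2
      mem <- sum(kern[k - idx + 1L] * v[idx] * w)
      a <- -mem - params$omega0^2 * x[k] + xi[k]
      v[k + 1L] <- v[k] + dt * a
      x[k + 1L] <- x[k] + dt * v[k + 1L]
      if (abs(x[k + 1L]) > 1e6) {
        stop("GLE integration unstable (|x| > 1e6); reduce dt_sim",
             call. = FALSE)
      }
    }
  })
  structure(list(times = dt * seq_len(n_steps),
                 states = cbind(x = x[-1], v = v[-1]),
                 seed = seed, params = params),
            class = "pib_trajectory")
}

#' @export
print.pib_trajectory <- function(x, ...) {
  cat(sprintf("<pib_trajectory> %d steps x %d columns | seed %d\n",
              nrow(x$states), ncol(x$states), x$seed))
  invisible(x)
}

#' Empirical joint statistics of lagged pairs
#'
#' Builds the past/future joint from simulated trajectories: for Gaussian
#' kinds the sample covariance blocks of lagged state pairs, for the
#' discrete kind the bivariate histogram of lagged frequencies on the
#' Wright-Fisher grid. Pairs are pooled across columns/replicates after
#' removing `burn_in` initial rows.
#'
#' @param traj A `pib_trajectory` (states n x k).
#' @param dt_pred Prediction lag, in sampling steps (integer) for matrices
#'   of replicates, or in time units for two-column state trajectories.
#' @param kind `"gaussian"` or `"discrete"`.
#' @param burn_in Rows dropped from the start.
#' @param grid Frequency grid for the discrete kind.
#' @return A [joint_gaussian()] or [discrete_joint()]. A warning attribute
#'   `n_pairs` below 1e4 is recorded in the object's `meta`.
#' @export
empirical_joint <- function(traj, dt_pred, kind = c("gaussian", "discrete"),
                            burn_in = 0L, grid = NULL) {
  kind <- match.arg(kind)
  X <- traj$states
  if (burn_in > 0L) X <- X[-seq_len(burn_in), , drop = FALSE]
  if (kind == "gaussian") {
    dt_sim <- traj$params$dt_sim %||% diff(traj$times[1:2])
    lag <- as.integer(round(dt_pred / dt_sim))
    n <- nrow(X) - lag
    past <- X[seq_len(n), , drop = FALSE]
    fut <- X[seq_len(n) + lag, , drop = FALSE]
    jg <- joint_gaussian(stats::cov(past), stats::cov(fut),
                         stats::cov(past, fut))
    jg$meta <- list(n_pairs = n, low_sample = n < 1e4)
    return(jg)
  }
  ## discrete: columns are replicate chains, lag in generations
  lag <- as.integer(round(dt_pred))
  if (is.null(grid)) grid <- wf_grid(traj$params)
  n <- nrow(X) - lag
  i_past <- factor(round(X[seq_len(n), ] * (length(grid) - 1L)),
                   levels = 0:(length(grid) - 1L))
  i_fut <- factor(round(X[seq_len(n) + lag, ] * (length(grid) - 1L)),
                  levels = 0:(length(grid) - 1L))
  tab <- table(i_past, i_fut)
  dj <- discrete_joint(grid, unclass(tab) / sum(tab), params = traj$params)
  dj$meta <- list(n_pairs = n * ncol(X), low_sample = n * ncol(X) < 1e4)
  dj
}
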