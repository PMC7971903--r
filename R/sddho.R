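#' Parameters of the stochastically driven damped harmonic oscillator
#'
#' The oscillator is worked in rescaled coordinates (time in units of the
#' relaxation time, position in units of its stationary standard deviation),
#' so only two parameters remain: the dimensionless damping coefficient
#' `zeta` and the prediction lag `dt_pred`. The derived angular frequency
#' obeys \eqn{\omega^2 = 1/(4\zeta^2) - 1/4}; it is imaginary in the
#' overdamped regime, which the closed-form results handle by analytic
#' continuation.
#'
#' @param zeta Damping coefficient, > 0. `zeta < 1` underdamped, `zeta = 1`
#'   critically damped, `zeta > 1` overdamped.
#' @param dt_pred Prediction lag, > 0.
#' @return An object of class `pib_sddho_params`.
#' @export
sddho_params <- function(zeta, dt_pred) {
  stopifnot(zeta > 0, dt_pred > 0)
  omega2 <- 1 / (4 * zeta^2) - 1 / 4
  regime <- if (zeta < 1) "underdamped" else if (zeta == 1) "critical" else "overdamped"
  structure(list(zeta = zeta, dt_pred = dt_pred, omega2 = omega2, regime = regime),
            class = "pib_sddho_params")
}

#' @export
print.pib_sddho_params <- function(x, ...) {
  cat(sprintf("<pib_sddho_params> zeta = %g, dt = %g (%s)\n",
              x$zeta, x$dt_pred, x$regime))
  invisible(x)
}

sddho_drift <- function(zeta) matrix(c(0, -1 / (4 * zeta^2), 1, -1), 2, 2)

#' Stationary covariance of the rescaled oscillator
#'
#' Solves the Lyapunov equation for the drift
#' \eqn{M = [[0, 1], [-1/(4\zeta^2), -1]]} with white noise of variance
#' \eqn{1/(2\zeta^2)} on the velocity; the solution is
#' \eqn{\mathrm{diag}(1, 1/(4\zeta^2))}.
#'
#' @param zeta Damping coefficient.
#' @return A 2x2 covariance matrix.
#' @export
sddho_stationary_cov <- function(zeta) diag(c(1, 1 / (4 * zeta^2)))

#' Joint Gaussian of oscillator states one lag apart
#'
#' Builds the [joint_gaussian()] of \eqn{X_t = (x, v)} and
#' \eqn{X_{t+\Delta t}} for a stationary oscillator: the marginals are the
#' Lyapunov stationary covariance and the cross-covariance is
#' \eqn{\Sigma e^{M^\top \Delta t}}, with the matrix exponential computed by
#' scaling and squaring (one code path across damping regimes). For lags so
#' large that the cross block underflows the joint degrades gracefully to
#' independence.
#'
#' @param params A [sddho_params()] object.
#' @return A `pib_joint_gaussian`.
#' @export
sddho_joint <- function(params) {
  stopifnot(inherits(params, "pib_sddho_params"))
  S <- sddho_stationary_cov(params$zeta)
  E <- mat_exp(sddho_drift(params$zeta) * params$dt_pred)
  joint_gaussian(S, S, S %*% t(E))
}

## Shared closed-form machinery: theta = omega * dt as a complex number,
## valid in every damping regime. Returns the pieces used by the angle,
## slope and total-information formulas.
## The "s"-suffixed quantities carry no exp(-dt) factor, so angle ratios stay
## finite at lags where exp(-dt) underflows.
sddho_closed_parts <- function(zeta, dt) {
  if (abs(zeta - 1) < 1e-7) {
    ## critically damped limit of the expressions below
    t <- dt
    k1s <- 1 + t^2 / 2 + t * sqrt(1 + t^2 / 4)
    return(list(k1 = exp(-t) * k1s, k1s = k1s,
                K11s = 1 + t + t^2 / 2, K21s = t^2 / 4,
                trace_term = 1 + t^2 / 2, degenerate = FALSE))
  }
  th <- sqrt(as.complex(1 - zeta^2)) / (2 * zeta) * dt
  c2 <- cos(2 * th); s1 <- sin(th); s2 <- sin(2 * th)
  D <- Re((1 - zeta^2) * s2^2 + 4 * s1^4)     # real and >= 0 in both regimes
  sqD <- sqrt(max(D, 0))
  base <- Re(1 - zeta^2 * c2)
  k1s <- max((base + zeta * sqD) / (1 - zeta^2),
             (base - zeta * sqD) / (1 - zeta^2))
  r <- sqrt(as.complex(1 - zeta^2))
  K11s <- Re((zeta^2 * c2 - zeta * r * s2 - 1) / (zeta^2 - 1))
  K21s <- Re(s1^2 / (1 - zeta^2))
  list(k1 = exp(-dt) * k1s, k1s = k1s, K11s = K11s, K21s = K21s,
       trace_term = base / (1 - zeta^2),
       degenerate = abs(Re(s1)) < 1e-9 && abs(Im(s1)) < 1e-9)
}

#' Angle of the leading encoding vector from the position axis
#'
#' Closed-form angle of the leading left eigenvector of
#' \eqn{\Sigma_{X_t|X_{t+\Delta t}}\Sigma_{X_t}^{-1}} — the direction in the
#' (position, velocity) plane that the optimal high-compression encoder
#' represents. The underdamped expression continues analytically to the
#' overdamped regime (\eqn{\omega \to i|\omega|}). At the degenerate lags
#' \eqn{\omega \Delta t = n\pi}, where every direction is equally good, the
#' convention is position-only encoding (angle 0).
#'
#' @param params A [sddho_params()] object.
#' @return The angle in radians, in `[0, pi/2]`.
#' @export
leading_angle <- function(params) {
  stopifnot(inherits(params, "pib_sddho_params"))
  p <- sddho_closed_parts(params$zeta, params$dt_pred)
  if (p$degenerate || p$K21s <= 0) return(0)
  phi <- atan2(p$k1s - p$K11s, p$K21s)
  phi %% pi
}

#' Initial slope of the information-bottleneck curve
#'
#' The bottleneck curve leaves the origin with slope \eqn{1 - \lambda_1},
#' where \eqn{\lambda_1} is the smallest eigenvalue of
#' \eqn{\Sigma_{X_t|X_{t+\Delta t}}\Sigma_{X_t}^{-1}}. Evaluated here in
#' closed form (all damping regimes).
#'
#' @param params A [sddho_params()] object.
#' @return The dimensionless slope in `(0, 1)`.
#' @export
slope_at_origin <- function(params) {
  stopifnot(inherits(params, "pib_sddho_params"))
  sddho_closed_parts(params$zeta, params$dt_pred)$k1
}

#' Total predictive information of the oscillator
#'
#' \eqn{I(X_t;X_{t+\Delta t}) = \tfrac12\log_2|\Sigma_{X_t}| -
#' \tfrac12\log_2|\Sigma_{X_t|X_{t+\Delta t}}|}, evaluated in closed form:
#' the eigenvalue product \eqn{\lambda_1\lambda_2} equals
#' \eqn{1 - \mathrm{tr}K + \det K} with
#' \eqn{K = \Sigma e^{M^\top\Delta t}\Sigma^{-1}e^{M\Delta t}}. This is the
#' saturation level of the bottleneck curve (the \eqn{\beta\to\infty} limit).
#'
#' @param params A [sddho_params()] object.
#' @return Total predictive information in bits.
#' @export
total_predictive_info <- function(params) {
  stopifnot(inherits(params, "pib_sddho_params"))
  t <- params$dt_pred
  z <- params$zeta
  if (t < 0.01) {
    ## small-lag series: the closed form below cancels to O(t^4) and loses
    ## precision in double arithmetic
    lam_prod <- t^4 / (360 * z^4) *
      (30 * z^2 - 30 * z^2 * t + (17 * z^2 - 1) * t^2 + (1 - 7 * z^2) * t^3)
  } else {
    p <- sddho_closed_parts(z, t)
    lam_prod <- 1 + exp(-2 * t) - 2 * exp(-t) * p$trace_term
  }
  lam_prod <- min(max(lam_prod, .Machine$double.xmin), 1)
  -0.5 * log2(lam_prod)
}

#' Optimal encoders across the oscillator parameter plane at fixed capacity
#'
#' For every combination of damping and lag, finds the tradeoff beta whose
#' optimal encoder carries exactly `i_past` bits about the current state
#' (monotone root bracketing), and reports its information coordinates,
#' encoder weights, and the conditional covariance ellipses of the current
#' and future state given the representation.
#'
#' @param zeta_grid,dt_grid Parameter grids.
#' @param i_past Fixed information about the past, in bits.
#' @return A tibble with one row per (zeta, dt) cell: `beta`, `i_past_bits`,
#'   `i_future_bits`, first-row encoder weights `w_x`, `w_v`, and the
#'   flattened conditional covariances of past and future.
#' @export
fixed_info_sweep <- function(zeta_grid, dt_grid, i_past = 5) {
  grid <- tidyr::expand_grid(zeta = zeta_grid, dt = dt_grid)
  rows <- purrr::pmap(grid, function(zeta, dt) {
    prm <- sddho_params(zeta, dt)
    j <- sddho_joint(prm)
    enc <- tryCatch(encoder_at_ipast(j, i_past, source = prm),
                    error = function(e) {
                      stop("fixed_info_sweep failed at cell (zeta = ", zeta,
                           ", dt = ", dt, "): ", conditionMessage(e), call. = FALSE)
                    })
    pt <- evaluate_encoder(enc, j)
    cc <- conditional_covariances(enc, j)
    lead <- enc$A[which.max(rowSums(enc$A^2)), ]
    tibble::tibble(
      zeta = zeta, dt = dt, beta = enc$beta,
      i_past_bits = pt$i_past_bits, i_future_bits = pt$i_future_bits,
      w_x = lead[1], w_v = lead[2],
      past_xx = cc$past[1, 1], past_xv = cc$past[1, 2], past_vv = cc$past[2, 2],
      fut_xx = cc$future[1, 1], fut_xv = cc$future[1, 2], fut_vv = cc$future[2, 2]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pib_sweep", class(out))
  out
}

#' Transfer an optimal oscillator encoder to different dynamics
#'
#' Freezes the encoder optimized for `source` at compression level `i_past`
#' and evaluates it on the joint statistics of `target`. The transferred
#' past information generally differs from the source level.
#'
#' @param source,target [sddho_params()] objects.
#' @param i_past Compression level (bits) at which the source encoder is
#'   optimized.
#' @return A one-row tibble with transferred `i_past_bits`, `i_future_bits`.
#' @export
transfer_gaussian <- function(source, i_past, target) {
  enc <- encoder_at_ipast(sddho_joint(source), i_past, source = source)
  evaluate_encoder(enc, sddho_joint(target))
}

#' Transferability map and Q metric of an oscillator encoder
#'
#' Sweeps the frozen source encoder over a grid of target dynamics
#' \eqn{(\zeta', \Delta t')}, recording the transferred predictive
#' information, and summarizes the surface by
#' \eqn{Q = \int I^{transfer}_{future} / \int I^{optimal}_{future}}
#' over the region (trapezoid rule, linear measure on the log-spaced grid).
#'
#' @inheritParams transfer_gaussian
#' @param zeta_range,dt_range Ranges of the target grids.
#' @param n_zeta,n_dt Grid sizes (log-spaced).
#' @return A list of class `pib_transfer_map`: `surface` (tibble with
#'   `zeta_t`, `dt_t`, `i_past_bits`, `i_future_bits`, `i_future_optimal`),
#'   `q`, `source`, `i_past_level`.
#' @export
q_transfer <- function(source, i_past, zeta_range = c(1 / 3, 3),
                       dt_range = c(0.1, 10), n_zeta = 15, n_dt = 15) {
  zg <- exp(seq(log(zeta_range[1]), log(zeta_range[2]), length.out = n_zeta))
  tg <- exp(seq(log(dt_range[1]), log(dt_range[2]), length.out = n_dt))
  enc <- encoder_at_ipast(sddho_joint(source), i_past, source = source)
  grid <- tidyr::expand_grid(zeta_t = zg, dt_t = tg)
  rows <- purrr::pmap(grid, function(zeta_t, dt_t) {
    jt <- sddho_joint(sddho_params(zeta_t, dt_t))
    tr <- evaluate_encoder(enc, jt)
    opt <- evaluate_encoder(encoder_at_ipast(jt, i_past), jt)
    dplyr::mutate(tr, i_future_optimal = opt$i_future_bits)
  })
  surface <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  q <- trapz2(zg, tg, matrix(surface$i_future_bits, n_zeta, n_dt, byrow = TRUE)) /
    trapz2(zg, tg, matrix(surface$i_future_optimal, n_zeta, n_dt, byrow = TRUE))
  structure(list(surface = surface, q = q, source = source,
                 i_past_level = i_past),
            class = "pib_transfer_map")
}

## 2-D trapezoid integral of z over the (x, y) grid; singleton axes act as
## unit-weight point evaluations so degenerate ranges stay well defined.
trapz2 <- function(x, y, z) {
  w <- function(g) {
    if (length(g) == 1L) return(1)
    d <- diff(g)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  }
  sum(outer(w(x), w(y)) * z)
}

#' @export
print.pib_transfer_map <- function(x, ...) {
  cat(sprintf("<pib_transfer_map> source zeta = %g, dt = %g, i_past = %g bits | Q = %.4f\n",
              x$source$zeta, x$source$dt_pred, x$i_past_level, x$q))
  invisible(x)
}
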