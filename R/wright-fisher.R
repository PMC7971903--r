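#' Wright-Fisher model parameters
#'
#' A single biallelic locus in a haploid population of constant size `N`,
#' with scaled symmetric mutation rate `n_mu` (= N mu) and scaled selection
#' `n_s` (= N s). Time is measured in generations; `dt_pred` is the
#' prediction lag. The allele-frequency state space is the grid
#' `{0, 1/N, ..., 1}`.
#'
#' @param N Population size (integer >= 2).
#' @param n_mu Scaled mutation rate, >= 0.
#' @param n_s Scaled selection coefficient.
#' @param dt_pred Prediction lag in generations, > 0.
#' @return An object of class `pib_wf_params`.
#' @export
wf_params <- function(N = 100L, n_mu = 0.2, n_s = 0.001, dt_pred = 1) {
  stopifnot(N >= 2, n_mu >= 0, dt_pred > 0)
  structure(list(N = as.integer(N), n_mu = n_mu, n_s = n_s,
                 dt_pred = dt_pred, mu = n_mu / N, s = n_s / N),
            class = "pib_wf_params")
}

#' @export
print.pib_wf_params <- function(x, ...) {
  cat(sprintf("<pib_wf_params> N = %d, Nmu = %g, Ns = %g, dt = %g generations\n",
              x$N, x$n_mu, x$n_s, x$dt_pred))
  invisible(x)
}

wf_grid <- function(params) seq(0, 1, length.out = params$N + 1L)

## Expected offspring frequency after one generation of drift-free dynamics
wf_update_mean <- function(x, params) {
  pmin(pmax(x + params$s * x * (1 - x) + params$mu * (1 - 2 * x), 0), 1)
}

#' Finite-lag transition matrix of the Wright-Fisher process
#'
#' Two constructions are provided.
#'
#' `method = "generation"` (the default used in all analyses): the exact
#' one-generation kernel of the Wright-Fisher population process —
#' multinomial resampling of `N` individuals around the post-selection,
#' post-mutation expected frequency — composed over `dt_pred` whole
#' generations. This kernel is the Markov chain whose diffusion limit is the
#' allele-frequency stochastic differential equation, and it is what the
#' trajectory simulator draws from, so propagator and simulation agree row
#' by row.
#'
#' `method = "diffusion"`: Crank-Nicolson integration of the Fokker-Planck
#' operator with drift \eqn{s x(1-x) + \mu(1-2x)} and diffusion
#' \eqn{x(1-x)/N}, discretized in conservative (flux) form with
#' Scharfetter-Gummel exponential fitting and zero-flux boundaries; the
#' vanishing diffusion coefficient at the boundaries is regularized on the
#' half-cells. Available for arbitrary real lags and used for the
#' small-lag moment checks; at boundary states it cannot reproduce the
#' chain's single-generation jumps, which is why the analyses use the
#' generation kernel.
#'
#' @param params A [wf_params()] object.
#' @param method `"generation"` or `"diffusion"`.
#' @param n_substeps Substep count for the Crank-Nicolson integrator; the
#'   internal step `dt_pred / n_substeps` must be at most 0.01.
#' @return A row-stochastic `(N+1) x (N+1)` matrix of class `pib_wf_propagator`
#'   (rows: state at t; columns: state at t + dt).
#' @export
wf_propagator <- function(params, method = c("generation", "diffusion"),
                          n_substeps = NULL) {
  stopifnot(inherits(params, "pib_wf_params"))
  method <- match.arg(method)
  x <- wf_grid(params)
  if (method == "generation") {
    if (abs(params$dt_pred - round(params$dt_pred)) > 1e-9) {
      stop("generation kernel requires an integer lag in generations",
           call. = FALSE)
    }
    f <- wf_update_mean(x, params)
    T1 <- t(vapply(f, function(p) stats::dbinom(0:params$N, params$N, p),
                   numeric(params$N + 1L)))
    T1 <- T1 / rowSums(T1)
    Tm <- mat_pow(T1, as.integer(round(params$dt_pred)))
  } else {
    n_substeps <- n_substeps %||% max(100L, ceiling(params$dt_pred / 0.01))
    h_t <- params$dt_pred / n_substeps
    if (h_t > 0.01 + 1e-12) {
      stop("n_substeps too small: internal step must be <= 0.01", call. = FALSE)
    }
    G <- wf_generator(params)
    n <- nrow(G)
    ## Crank-Nicolson substep acting on row vectors: p' = p %*% Tstep
    Tstep <- t(solve(diag(n) - h_t / 2 * t(G), diag(n) + h_t / 2 * t(G)))
    Tm <- mat_pow(Tstep, n_substeps)
    neg <- min(Tm)
    if (neg < -1e-10) {
      stop("discretization error: propagator has negative entries (",
           signif(neg, 3), "); increase n_substeps", call. = FALSE)
    }
    Tm[Tm < 0] <- 0
    Tm <- Tm / rowSums(Tm)
  }
  structure(Tm, class = c("pib_wf_propagator", "matrix"),
            params = params, method = method)
}

mat_pow <- function(A, k) {
  out <- diag(nrow(A))
  P <- A
  while (k > 0) {
    if (k %% 2L == 1L) out <- out %*% P
    k <- k %/% 2L
    if (k > 0) P <- P %*% P
  }
  out
}

## Transition-rate generator of the Fokker-Planck operator in flux form.
## States hold cell masses (half-cells at the boundaries); nearest-neighbour
## rates use Scharfetter-Gummel (Bernoulli-function) exponential fitting so
## all rates are nonnegative and the discrete stationary law matches the
## continuum zero-flux solution.
wf_generator <- function(params) {
  N <- params$N
  n <- N + 1L
  h <- 1 / N
  x <- wf_grid(params)
  xe <- (x[-1] + x[-n]) / 2
  b_node <- x * (1 - x) / N
  ## regularize the vanishing diffusion coefficient on the boundary half-cells
  b_node[1] <- (h / 4) * (1 - h / 4) / N
  b_node[n] <- b_node[1]
  b_edge <- xe * (1 - xe) / N
  a_edge <- params$s * xe * (1 - xe) + params$mu * (1 - 2 * xe)
  v <- 2 * a_edge * h / b_edge
  dx <- rep(h, n); dx[c(1, n)] <- h / 2
  up <- bernoulli_fn(-v) * b_node[-n] / (2 * h * dx[-n])
  dn <- bernoulli_fn(v) * b_node[-1] / (2 * h * dx[-1])
  G <- matrix(0, n, n)
  i <- seq_len(n - 1L)
  G[cbind(i, i + 1L)] <- up
  G[cbind(i + 1L, i)] <- dn
  diag(G) <- -rowSums(G)
  G
}

## x / (exp(x) - 1), numerically stable near 0
bernoulli_fn <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 - x / 2, x / expm1(x))
  as.numeric(out)
}

#' Stationary allele-frequency distribution
#'
#' Returns the stationary law of the finite-lag propagator (its leading left
#' eigenvector) together with the analytic diffusion steady state evaluated
#' as cell-integrated masses on the same grid,
#' \eqn{P_s(X) \propto [X(1-X)]^{c\,N\mu - 1} e^{c\,N s X}}. The exponent
#' scale `c = 2` is the one consistent with per-generation drift
#' \eqn{sx(1-x) + \mu(1-2x)} and variance \eqn{x(1-x)/N} (and with the
#' binomial-chain simulator); `c = 1` reproduces the weak-mutation form
#' often quoted with the factor absorbed into the rates.
#'
#' @param params A [wf_params()] object.
#' @param propagator Optional precomputed [wf_propagator()].
#' @param exponent_scale Scale `c` of the analytic exponents (default 2; see
#'   Details).
#' @return A tibble with columns `x`, `p_chain` (eigenvector route) and
#'   `p_analytic` (cell-integrated closed form). If `n_mu = 0` the analytic
#'   column is an error to request (absorbing boundaries dominate); only the
#'   eigenvector route is returned then.
#' @export
wf_steady_state <- function(params, propagator = NULL, exponent_scale = 2) {
  stopifnot(inherits(params, "pib_wf_params"))
  Tm <- propagator %||% wf_propagator(params)
  p_chain <- stationary_left_eigvec(unclass(Tm))
  x <- wf_grid(params)
  if (params$n_mu > 0) {
    p_an <- wf_analytic_pmf(params, exponent_scale)
    tibble::tibble(x = x, p_chain = p_chain, p_analytic = p_an)
  } else {
    tibble::tibble(x = x, p_chain = p_chain)
  }
}

stationary_left_eigvec <- function(Tm) {
  e <- eigen(t(Tm))
  i <- which.max(Re(e$values))
  p <- abs(Re(e$vectors[, i]))
  p / sum(p)
}

## Cell-integrated masses of [x(1-x)]^(a-1) e^(g x) on the grid, a = c*Nmu,
## g = c*Ns. Boundary half-cells handled by the substitution u = x^a, which
## removes the integrable endpoint singularity when a < 1.
wf_analytic_pmf <- function(params, exponent_scale = 2) {
  if (params$n_mu <= 0) {
    stop("analytic steady state requires n_mu > 0; use the propagator ",
         "eigenvector route instead", call. = FALSE)
  }
  a <- exponent_scale * params$n_mu
  g <- exponent_scale * params$n_s
  N <- params$N
  h <- 1 / N
  dens <- function(x) (x * (1 - x))^(a - 1) * exp(g * x)
  m <- numeric(N + 1L)
  ## boundary cells [0, h/2] and [1 - h/2, 1]
  m[1] <- stats::integrate(function(u) {
    xx <- u^(1 / a); (1 - xx)^(a - 1) * exp(g * xx) / a
  }, 0, (h / 2)^a, rel.tol = 1e-10)$value
  m[N + 1L] <- stats::integrate(function(u) {
    xx <- 1 - u^(1 / a); xx^(a - 1) * exp(g * xx) / a
  }, 0, (h / 2)^a, rel.tol = 1e-10)$value
  for (i in 2:N) {
    lo <- (i - 1) / N - h / 2
    hi <- (i - 1) / N + h / 2
    m[i] <- stats::integrate(dens, lo, hi, rel.tol = 1e-10)$value
  }
  m / sum(m)
}

#' Joint distribution of allele frequencies one lag apart
#'
#' Builds the stationary discrete joint
#' \eqn{P(X_t, X_{t+\Delta t}) = P_s(X_t) T[X_t \to X_{t+\Delta t}]} on the
#' frequency grid, where \eqn{P_s} is the propagator's stationary law, and
#' exposes the mutual information between the two times in bits.
#'
#' @param params A [wf_params()] object.
#' @param method Propagator construction, see [wf_propagator()].
#' @return An object of class `pib_discrete_joint`: list with `grid`,
#'   `p_joint`, `p_past` (= stationary law), `p_future`, `mi_bits` and the
#'   conditional table `p_future_given_past`.
#' @export
wf_joint <- function(params, method = c("generation", "diffusion")) {
  method <- match.arg(method)
  Tm <- wf_propagator(params, method = method)
  ps <- stationary_left_eigvec(unclass(Tm))
  discrete_joint(wf_grid(params), ps * unclass(Tm), params = params)
}

#' Construct a discrete joint distribution on a frequency grid
#'
#' @param grid State values (length n).
#' @param p_joint n x n joint probability table, rows indexing the past.
#' @param params Optional parameter record for provenance.
#' @return An object of class `pib_discrete_joint`.
#' @export
discrete_joint <- function(grid, p_joint, params = NULL) {
  p_joint <- as.matrix(p_joint)
  stopifnot(length(grid) == nrow(p_joint), nrow(p_joint) == ncol(p_joint))
  if (min(p_joint) < -1e-12) {
    stop("joint table has negative entries", call. = FALSE)
  }
  p_joint[p_joint < 0] <- 0
  tot <- sum(p_joint)
  if (abs(tot - 1) > 1e-8) p_joint <- p_joint / tot
  p_past <- rowSums(p_joint)
  p_future <- colSums(p_joint)
  cond <- p_joint / pmax(p_past, 1e-300)
  structure(
    list(grid = grid, p_joint = p_joint, p_past = p_past, p_future = p_future,
         p_future_given_past = cond, mi_bits = mi_bits_table(p_joint),
         params = params),
    class = "pib_discrete_joint"
  )
}

#' @export
print.pib_discrete_joint <- function(x, ...) {
  cat(sprintf("<pib_discrete_joint> %d states | I(past;future) = %.4f bits\n",
              length(x$grid), x$mi_bits))
  invisible(x)
}
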