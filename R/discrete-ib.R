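#' Blahut-Arimoto solver for the discrete information bottleneck
#'
#' Iterates the self-consistent bottleneck equations for a discrete
#' representation variable with `m` values:
#' \deqn{q(\tilde x|x) \propto q(\tilde x)\,
#'   e^{-\beta\, KL[P(y|x)\,\|\,P(y|\tilde x)]},}
#' recomputing the cluster marginal \eqn{q(\tilde x)} and the decoders
#' \eqn{P(y|\tilde x)} after every sweep. The bottleneck Lagrangian
#' \eqn{I(X;\tilde X) - \beta I(\tilde X;Y)} (natural units internally) is
#' nonincreasing along the iteration; convergence is declared when its
#' change falls below `tol`.
#'
#' @param joint A [discrete_joint()] (e.g. from [wf_joint()]).
#' @param m Cardinality of the representation variable (>= 1).
#' @param beta Tradeoff parameter (>= 0).
#' @param init Either `"perturbed-uniform"` (deterministic, lightly broken
#'   symmetry), `"random"`, or a numeric `n x m` matrix of initial
#'   conditionals.
#' @param tol Convergence tolerance on the Lagrangian (nats).
#' @param max_iter Iteration cap; the best iterate is returned flagged
#'   `converged = FALSE` if reached.
#' @param seed Seed used for random initialization.
#' @param check_monotone If `TRUE`, error if the Lagrangian ever increases
#'   by more than numerical roundoff.
#' @return An object of class `pib_discrete_encoder`: list with the `n x m`
#'   conditional table `q`, `m`, `beta`, `i_past_bits`, `i_future_bits`,
#'   `lagrangian_nats`, `n_iter`, `converged`.
#' @export
ba_solve <- function(joint, m, beta, init = "perturbed-uniform",
                     tol = 1e-10, max_iter = 50000L, seed = 1L,
                     check_monotone = FALSE) {
  stopifnot(inherits(joint, "pib_discrete_joint"), m >= 1, beta >= 0)
  n <- length(joint$grid)
  px <- joint$p_past
  pyx <- joint$p_future_given_past
  lpyx <- log(pmax(pyx, 1e-300))
  neg_hyx <- rowSums(pyx * lpyx)      # -H(Y|X = x), nats
  q <- ba_init(init, n, m, seed)
  L_old <- Inf
  L_best <- Inf
  q_best <- q
  converged <- FALSE
  it <- 0L
  ## the Lagrangian is evaluated every sweep when its monotonicity is being
  ## asserted, and every few sweeps otherwise (it is the costly part)
  cadence <- if (check_monotone) 1L else 10L
  while (it < max_iter) {
    it <- it + 1L
    qt <- drop(px %*% q)                              # q(xtilde)
    dec <- crossprod(px * q, pyx) / pmax(qt, 1e-300)  # m x n decoders
    dec <- pmax(dec, 1e-300)
    kl <- neg_hyx - pyx %*% t(log(dec))               # n x m KL in nats
    lq <- rep(log(pmax(qt, 1e-300)), each = n) - beta * kl
    lq <- lq - lq[cbind(seq_len(n), max.col(lq, ties.method = "first"))]
    q <- exp(lq)
    q <- q / rowSums(q)
    if (it %% cadence == 0L || it == max_iter) {
      L <- ba_lagrangian(q, px, pyx, beta)
      if (check_monotone && L > L_old + 1e-9) {
        stop("Blahut-Arimoto Lagrangian increased: ", L_old, " -> ", L,
             call. = FALSE)
      }
      if (L < L_best) { L_best <- L; q_best <- q }
      if (is.finite(L_old) && abs(L_old - L) < tol) { converged <- TRUE; break }
      L_old <- L
    }
  }
  inf <- discrete_info_q(q_best, px, pyx)
  structure(
    list(q = q_best, m = as.integer(m), beta = beta,
         i_past_bits = inf[1], i_future_bits = inf[2],
         lagrangian_nats = L_best, n_iter = it, converged = converged,
         grid = joint$grid),
    class = "pib_discrete_encoder"
  )
}

ba_init <- function(init, n, m, seed) {
  if (is.matrix(init)) {
    stopifnot(nrow(init) == n, ncol(init) == m)
    return(init / rowSums(init))
  }
  if (identical(init, "perturbed-uniform")) {
    ## deterministic gentle symmetry breaking along the grid
    q <- matrix(1, n, m) +
      0.1 * sin(outer(seq_len(n) / n, seq_len(m)) * pi)
    return(q / rowSums(q))
  }
  if (identical(init, "random")) {
    q <- withr::with_seed(seed, matrix(stats::runif(n * m, 0.05, 1), n, m))
    return(q / rowSums(q))
  }
  stop("unknown init: ", init, call. = FALSE)
}

## Lagrangian I(X;Xt) - beta I(Xt;Y) in nats
ba_lagrangian <- function(q, px, pyx, beta) {
  inf <- discrete_info_q(q, px, pyx)
  (inf[1] - beta * inf[2]) / LOG2E
}

## (i_past, i_future) in bits for encoder table q against p(x), p(y|x)
discrete_info_q <- function(q, px, pyx) {
  Pxt <- px * q                        # p(x, xtilde)
  qt <- colSums(Pxt)
  ip <- mi_bits_table(Pxt)
  Pty <- crossprod(Pxt, pyx)           # p(xtilde, y)
  ifu <- mi_bits_table(Pty)
  c(ip, ifu)
}

#' @export
print.pib_discrete_encoder <- function(x, ...) {
  cat(sprintf(
    "<pib_discrete_encoder> m = %d, beta = %.4g | i_past = %.4f, i_future = %.4f bits | %s\n",
    x$m, x$beta, x$i_past_bits, x$i_future_bits,
    if (x$converged) paste0("converged in ", x$n_iter, " iter") else "NOT converged"))
  invisible(x)
}

#' Information coordinates of a discrete encoder under a joint
#'
#' Evaluates \eqn{I(X_t;\tilde X)} and \eqn{I(\tilde X;X_{t+\Delta t})} for
#' an arbitrary conditional table `q` against a discrete joint — the
#' evaluation used for optimal, suboptimal and transferred encoders alike.
#'
#' @param encoder A `pib_discrete_encoder` (or a plain conditional matrix).
#' @param joint A [discrete_joint()] on the same grid.
#' @return A one-row tibble with `i_past_bits` and `i_future_bits`.
#' @export
discrete_info <- function(encoder, joint) {
  q <- if (inherits(encoder, "pib_discrete_encoder")) encoder$q else as.matrix(encoder)
  stopifnot(inherits(joint, "pib_discrete_joint"))
  if (nrow(q) != length(joint$grid)) {
    stop("grid mismatch: encoder has ", nrow(q), " states, joint has ",
         length(joint$grid), call. = FALSE)
  }
  inf <- discrete_info_q(q, joint$p_past, joint$p_future_given_past)
  tibble::tibble(i_past_bits = inf[1], i_future_bits = inf[2])
}

#' Discrete information-bottleneck curve
#'
#' Sweeps beta upward with warm starts from the previous solution
#' (annealing along the physical branch through its bifurcations) plus
#' independent seeded restarts at every beta; per beta the iterate with the
#' lowest Lagrangian \eqn{I_{past} - \beta I_{future}} is kept.
#'
#' @param joint A [discrete_joint()].
#' @param m Representation cardinality.
#' @param beta_grid Ascending tradeoff values.
#' @param n_restarts Restarts per beta (restart 0 is the deterministic
#'   perturbed-uniform initialization; the rest are random with seeds
#'   derived from `seed`).
#' @param seed Master seed.
#' @param tol,max_iter Passed to [ba_solve()].
#' @return A tibble of class `pib_info_curve` with columns `beta`,
#'   `i_past_bits`, `i_future_bits`, `converged`.
#' @export
discrete_curve <- function(joint, m, beta_grid, n_restarts = 10L, seed = 1L,
                           tol = 1e-10, max_iter = 50000L) {
  stopifnot(n_restarts >= 1L, !is.unsorted(beta_grid))
  warm <- NULL
  out <- vector("list", length(beta_grid))
  for (k in seq_along(beta_grid)) {
    b <- beta_grid[k]
    best <- ba_best(joint, m, b, n_restarts, seed, tol, max_iter, warm = warm)
    warm <- best$q
    out[[k]] <- tibble::tibble(beta = b, i_past_bits = best$i_past_bits,
                               i_future_bits = best$i_future_bits,
                               converged = best$converged)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("pib_info_curve", class(res))
  res
}

#' Best-of-restarts Blahut-Arimoto solve
#'
#' Runs [ba_solve()] from the deterministic perturbed-uniform start, from
#' `n_restarts - 1` random starts (seeds derived from `seed`), and from an
#' optional warm start, returning the solution with the lowest Lagrangian.
#'
#' @inheritParams discrete_curve
#' @param beta Tradeoff value.
#' @param warm Optional encoder table used as an extra initialization.
#' @return A `pib_discrete_encoder`.
#' @export
ba_best <- function(joint, m, beta, n_restarts = 10L, seed = 1L,
                    tol = 1e-10, max_iter = 50000L, warm = NULL) {
  cands <- list(ba_solve(joint, m, beta, init = "perturbed-uniform",
                         tol = tol, max_iter = max_iter))
  if (n_restarts > 1L) {
    for (r in seq_len(n_restarts - 1L)) {
      cands[[length(cands) + 1L]] <-
        ba_solve(joint, m, beta, init = "random",
                 seed = child_seed(seed, r), tol = tol, max_iter = max_iter)
    }
  }
  if (!is.null(warm)) {
    cands[[length(cands) + 1L]] <-
      ba_solve(joint, m, beta, init = warm, tol = tol, max_iter = max_iter)
  }
  Ls <- vapply(cands, function(e) e$lagrangian_nats, 0)
  cands[[which.min(Ls)]]
}

#' Effective cardinality of a discrete encoder
#'
#' Counts the representation values actually in use: clusters with marginal
#' mass below `mass_tol` are dropped, then clusters whose future decoders
#' differ by less than `divergence_tol` (Jensen-Shannon divergence, bits)
#' are merged; merging repeats until no pair is below the threshold, so the
#' operation is idempotent.
#'
#' @param encoder A `pib_discrete_encoder`.
#' @param joint The [discrete_joint()] it was trained on.
#' @param mass_tol Minimum cluster mass.
#' @param divergence_tol JSD merge threshold in bits.
#' @return Integer count of distinct clusters (>= 1 when any mass remains).
#' @export
effective_cardinality <- function(encoder, joint, mass_tol = 1e-3,
                                  divergence_tol = 0.01) {
  q <- encoder$q
  px <- joint$p_past
  pyx <- joint$p_future_given_past
  qt <- drop(px %*% q)
  keep <- which(qt >= mass_tol)
  if (length(keep) == 0L) return(0L)
  dec <- crossprod(px * q[, keep, drop = FALSE], pyx) / qt[keep]
  w <- qt[keep]
  repeat {
    k <- nrow(dec)
    if (k <= 1L) break
    merged <- FALSE
    for (i in seq_len(k - 1L)) {
      js <- vapply((i + 1L):k, function(j) jsd_bits(dec[i, ], dec[j, ]), 0)
      j <- which(js < divergence_tol)
      if (length(j) > 0L) {
        j <- j[1] + i
        dec[i, ] <- (w[i] * dec[i, ] + w[j] * dec[j, ]) / (w[i] + w[j])
        w[i] <- w[i] + w[j]
        dec <- dec[-j, , drop = FALSE]
        w <- w[-j]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  nrow(dec)
}

jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(pmax(b[i], 1e-300))))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Decoders of a discrete encoder
#'
#' The inferred historical and predicted future allele-frequency
#' distributions for each representation value:
#' \eqn{P(X_t|\tilde x)} and \eqn{P(X_{t+\Delta t}|\tilde x)}, with cluster
#' weights and conditional means/standard deviations. The weighted mixture
#' of the decoders recovers the marginals exactly.
#'
#' @inheritParams effective_cardinality
#' @return A list with `weights` (length m), matrices `past` and `future`
#'   (m x n, rows are decoder distributions), and a tibble `moments` with
#'   per-cluster conditional means and standard deviations of both times.
#' @export
decoders <- function(encoder, joint) {
  q <- encoder$q
  px <- joint$p_past
  pyx <- joint$p_future_given_past
  g <- joint$grid
  qt <- drop(px %*% q)
  past <- t(px * q) / pmax(qt, 1e-300)          # m x n : P(x | xtilde)
  future <- crossprod(px * q, pyx) / pmax(qt, 1e-300)
  mom <- tibble::tibble(
    xtilde = seq_along(qt),
    weight = qt,
    mean_past = drop(past %*% g),
    sd_past = sqrt(pmax(drop(past %*% g^2) - drop(past %*% g)^2, 0)),
    mean_future = drop(future %*% g),
    sd_future = sqrt(pmax(drop(future %*% g^2) - drop(future %*% g)^2, 0))
  )
  list(weights = qt, past = past, future = future, moments = mom)
}

#' Transfer a discrete encoder to a different joint
#'
#' Freezes the trained conditional table \eqn{q(\tilde x|x)} and evaluates
#' its information coordinates under a target joint on the same frequency
#' grid.
#'
#' @param encoder A `pib_discrete_encoder`.
#' @param target_joint A [discrete_joint()] with an identical grid.
#' @return A one-row tibble with transferred `i_past_bits`, `i_future_bits`.
#' @export
transfer_discrete <- function(encoder, target_joint) {
  if (!isTRUE(all.equal(encoder$grid, target_joint$grid))) {
    stop("grid mismatch between encoder and target joint", call. = FALSE)
  }
  discrete_info(encoder, target_joint)
}
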