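#' Information-bottleneck spectrum of a joint Gaussian
#'
#' Solves the generalized symmetric eigenproblem
#' \eqn{\Sigma_{X|Y} w = \lambda \Sigma_X w}, whose solutions are the left
#' eigenvectors of \eqn{\Sigma_{X|Y}\Sigma_X^{-1}}. Each eigenvalue
#' \eqn{\lambda_i \in (0, 1]} carries a critical tradeoff
#' \eqn{\beta_i^c = 1/(1-\lambda_i)} at which the optimal encoder gains a new
#' active dimension, and a scale factor \eqn{r_i = w_i^\top \Sigma_X w_i}.
#'
#' @param joint A [joint_gaussian()] object.
#' @return An object of class `pib_ib_spectrum`: a list with `lambda`
#'   (ascending), `W` (rows are unit-norm left eigenvectors, first nonzero
#'   component positive), `beta_c`, and `r`.
#' @export
ib_spectrum <- function(joint) {
  stopifnot(inherits(joint, "pib_joint_gaussian"))
  Sp <- joint$sigma_past
  Spf <- joint$sigma_past_given_future
  U <- chol(Sp)                       # Sp = t(U) %*% U
  Uinv <- backsolve(U, diag(nrow(U)))
  B <- symmetrize(t(Uinv) %*% Spf %*% Uinv)
  e <- eigen(B, symmetric = TRUE)
  ord <- order(e$values)
  lambda <- pmin(pmax(e$values[ord], .Machine$double.xmin), 1)
  W <- t(Uinv %*% e$vectors[, ord, drop = FALSE])
  ## canonical orientation and unit Euclidean norm
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    w <- w / sqrt(sum(w^2))
    j <- which(abs(w) > 1e-12)[1]
    if (!is.na(j) && w[j] < 0) w <- -w
    W[i, ] <- w
  }
  r <- vapply(seq_len(nrow(W)), function(i) drop(W[i, ] %*% Sp %*% W[i, ]), 0)
  beta_c <- ifelse(lambda >= 1 - 1e-14, Inf, 1 / (1 - lambda))
  structure(list(lambda = lambda, W = W, beta_c = beta_c, r = r),
            class = "pib_ib_spectrum")
}

#' @export
print.pib_ib_spectrum <- function(x, ...) {
  cat("<pib_ib_spectrum>\n")
  print(tibble::tibble(lambda = x$lambda, beta_c = x$beta_c, r = x$r))
  invisible(x)
}

#' Optimal Gaussian information-bottleneck encoder
#'
#' Constructs the optimal noisy linear encoder \eqn{\tilde X = A X + \xi}
#' (unit-variance Gaussian noise) at tradeoff `beta`. Row `i` of `A` is
#' \eqn{c_i w_i^\top} with
#' \eqn{c_i^2 = (\beta(1-\lambda_i) - 1)/(\lambda_i r_i)} whenever
#' \eqn{\beta > \beta_i^c}, and zero otherwise, so representation
#' dimensionality steps up exactly at the critical tradeoffs.
#'
#' @param joint A [joint_gaussian()] object.
#' @param beta Positive tradeoff parameter.
#' @param source Optional record (list) of the dynamics parameters the
#'   encoder was optimized for; stored for provenance.
#' @return A `pib_gaussian_encoder`: list with `A`, `beta`, `source`.
#' @export
optimal_encoder <- function(joint, beta, source = NULL) {
  stopifnot(inherits(joint, "pib_joint_gaussian"), beta > 0)
  sp <- ib_spectrum(joint)
  d <- joint$dim_past
  A <- matrix(0, d, d)
  for (i in seq_len(d)) {
    if (is.finite(sp$beta_c[i]) && beta > sp$beta_c[i]) {
      c2 <- (beta * (1 - sp$lambda[i]) - 1) / (sp$lambda[i] * sp$r[i])
      A[i, ] <- sqrt(max(c2, 0)) * sp$W[i, ]
    }
  }
  new_gaussian_encoder(A, beta, source)
}

new_gaussian_encoder <- function(A, beta = NA_real_, source = NULL) {
  structure(list(A = A, beta = beta, source = source),
            class = "pib_gaussian_encoder")
}

#' @export
print.pib_gaussian_encoder <- function(x, ...) {
  act <- sum(rowSums(abs(x$A)) > 0)
  cat(sprintf("<pib_gaussian_encoder> beta = %.4g | active rows = %d\n",
              x$beta, act))
  invisible(x)
}

#' Evaluate a linear Gaussian encoder on a joint Gaussian
#'
#' Computes the information-plane coordinates of an arbitrary noisy linear
#' encoder \eqn{\tilde X = A X + \xi}:
#' \eqn{I_{past} = \tfrac12 \log_2 \det(A \Sigma_X A^\top + I)} and
#' \eqn{I_{future} = I_{past} - \tfrac12 \log_2 \det(A \Sigma_{X|Y} A^\top + I)}.
#' Works for suboptimal and transferred encoders alike.
#'
#' @param encoder A `pib_gaussian_encoder` (or a plain matrix `A`).
#' @param joint A [joint_gaussian()] object with `dim_past` matching the
#'   encoder's column dimension.
#' @return A one-row tibble with `i_past_bits` and `i_future_bits`.
#' @export
evaluate_encoder <- function(encoder, joint) {
  A <- if (inherits(encoder, "pib_gaussian_encoder")) encoder$A else as.matrix(encoder)
  stopifnot(inherits(joint, "pib_joint_gaussian"))
  if (ncol(A) != joint$dim_past) {
    stop("dimension mismatch: encoder has ", ncol(A),
         " columns but joint$dim_past is ", joint$dim_past, call. = FALSE)
  }
  ip <- 0.5 * log2_det_I_plus(A %*% joint$sigma_past %*% t(A))
  ifu <- ip - 0.5 * log2_det_I_plus(A %*% joint$sigma_past_given_future %*% t(A))
  tibble::tibble(i_past_bits = max(ip, 0), i_future_bits = max(ifu, 0))
}

#' Gaussian information-bottleneck curve
#'
#' Sweeps the tradeoff parameter over `beta_grid`, building the optimal
#' encoder at each value and evaluating it, to trace the bottleneck curve
#' \eqn{I_{future}(I_{past})}.
#'
#' @param joint A [joint_gaussian()] object.
#' @param beta_grid Ascending positive tradeoff values. Defaults to 200
#'   log-spaced points on `[1.001, 1e4]`, which resolves both the critical
#'   region and the saturation plateau.
#' @return A tibble of class `pib_info_curve` with columns `beta`,
#'   `i_past_bits`, `i_future_bits`.
#' @export
info_curve <- function(joint, beta_grid = default_beta_grid()) {
  stopifnot(!is.unsorted(beta_grid), all(beta_grid > 0))
  pts <- lapply(beta_grid, function(b) evaluate_encoder(optimal_encoder(joint, b), joint))
  out <- dplyr::bind_cols(tibble::tibble(beta = beta_grid), dplyr::bind_rows(pts))
  class(out) <- c("pib_info_curve", class(out))
  out
}

#' @rdname info_curve
#' @export
default_beta_grid <- function() exp(seq(log(1.001), log(1e4), length.out = 200))

#' Closed-form Gaussian information-bottleneck curve
#'
#' Piecewise-analytic information coordinates of the optimal encoder as a
#' function of beta, derived from the bottleneck spectrum:
#' with active set \eqn{\{i : \beta > \beta_i^c\}},
#' \eqn{I_{past} = \tfrac12\sum_i \log_2[(\beta-1)(1-\lambda_i)/\lambda_i]}
#' and \eqn{I_{future} = I_{past} - \tfrac12\sum_i \log_2[\beta(1-\lambda_i)]}.
#' Used as an independent check on [info_curve()].
#'
#' @inheritParams info_curve
#' @return A tibble with columns `beta`, `i_past_bits`, `i_future_bits`.
#' @export
ib_curve_analytic <- function(joint, beta_grid = default_beta_grid()) {
  sp <- ib_spectrum(joint)
  rows <- lapply(beta_grid, function(b) {
    act <- is.finite(sp$beta_c) & (b > sp$beta_c)
    lam <- sp$lambda[act]
    ip <- 0.5 * sum(log2((b - 1) * (1 - lam) / lam))
    ifu <- ip - 0.5 * sum(log2(b * (1 - lam)))
    tibble::tibble(beta = b, i_past_bits = ip, i_future_bits = ifu)
  })
  dplyr::bind_rows(rows)
}

#' Find the tradeoff beta that achieves a target past information
#'
#' Inverts the monotone map \eqn{\beta \mapsto I_{past}(\beta)} of the
#' optimal Gaussian encoder by root bracketing.
#'
#' @param joint A [joint_gaussian()] object.
#' @param i_past Target past information in bits (> 0).
#' @return The tradeoff value `beta`.
#' @export
beta_for_ipast <- function(joint, i_past) {
  stopifnot(i_past > 0)
  sp <- ib_spectrum(joint)
  b1 <- min(sp$beta_c)
  if (!is.finite(b1)) {
    stop("independent past/future: no finite beta achieves positive i_past",
         call. = FALSE)
  }
  f <- function(logb) {
    b <- exp(logb)
    act <- is.finite(sp$beta_c) & (b > sp$beta_c)
    lam <- sp$lambda[act]
    0.5 * sum(log2((b - 1) * (1 - lam) / lam)) - i_past
  }
  lo <- log(b1) + 1e-12
  hi <- log(b1 + 1)
  for (k in 1:200) {
    if (f(hi) > 0) break
    hi <- hi + log(4)
  }
  if (f(hi) <= 0) {
    stop("root not bracketed when inverting i_past(beta); target i_past = ",
         i_past, call. = FALSE)
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-13)$root)
}

#' Optimal encoder at a fixed level of past information
#'
#' @inheritParams beta_for_ipast
#' @param source Optional provenance record stored on the encoder.
#' @return A `pib_gaussian_encoder` whose `i_past` equals the target.
#' @export
encoder_at_ipast <- function(joint, i_past, source = NULL) {
  optimal_encoder(joint, beta_for_ipast(joint, i_past), source = source)
}

#' Conditional covariances given a representation
#'
#' Gaussian conditioning of the past and future on the representation
#' \eqn{\tilde X = A X + \xi}: returns
#' \eqn{\Sigma_{X_t|\tilde X}} and \eqn{\Sigma_{X_{t+\Delta t}|\tilde X}},
#' both preceding their priors in the PSD order. These are the uncertainty
#' ellipses drawn in the information-plane figures.
#'
#' @inheritParams evaluate_encoder
#' @return A list with elements `past` and `future`.
#' @export
conditional_covariances <- function(encoder, joint) {
  A <- if (inherits(encoder, "pib_gaussian_encoder")) encoder$A else as.matrix(encoder)
  if (ncol(A) != joint$dim_past) {
    stop("dimension mismatch between encoder and joint", call. = FALSE)
  }
  Sp <- joint$sigma_past
  Sf <- joint$sigma_future
  Sc <- joint$sigma_cross
  G <- A %*% Sp %*% t(A) + diag(nrow(A))
  CxT <- Sp %*% t(A)                  # cov(past, xtilde)
  CfT <- t(Sc) %*% t(A)               # cov(future, xtilde)
  past <- symmetrize(Sp - CxT %*% solve(G, t(CxT)))
  future <- symmetrize(Sf - CfT %*% solve(G, t(CfT)))
  list(past = past, future = future)
}

#' Rotate a two-dimensional encoder in the (position, velocity) plane
#'
#' Builds a deliberately suboptimal representation by rotating each row of
#' the encoding matrix by `theta` and rescaling (a common scalar on all
#' rows) so the rotated encoder carries the same past information as the
#' original, to within 1e-6 bits.
#'
#' @inheritParams evaluate_encoder
#' @param theta Rotation angle in radians.
#' @return A `pib_gaussian_encoder`.
#' @export
rotate_encoder <- function(encoder, theta, joint) {
  stopifnot(inherits(encoder, "pib_gaussian_encoder"))
  if (joint$dim_past != 2L) {
    stop("unsupported dimension: rotation is defined for 2-D joints only",
         call. = FALSE)
  }
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  A0 <- encoder$A %*% t(R)
  target <- evaluate_encoder(encoder, joint)$i_past_bits
  if (target <= 0 || all(abs(A0) < 1e-300)) {
    return(new_gaussian_encoder(A0 * 0, encoder$beta, encoder$source))
  }
  f <- function(logs) {
    evaluate_encoder(exp(logs) * A0, joint)$i_past_bits - target
  }
  lo <- -40; hi <- 40
  s <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-14)$root)
  new_gaussian_encoder(s * A0, encoder$beta, encoder$source)
}
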