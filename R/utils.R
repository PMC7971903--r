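## Internal numerical helpers shared across modules.

LOG2E <- log2(exp(1))

nat_to_bits <- function(x) x * LOG2E

#' @keywords internal
symmetrize <- function(S) (S + t(S)) / 2

## Relative PSD tolerance used everywhere (eigenvalues may dip this far below
## zero, relative to the largest eigenvalue, before we call a matrix non-PSD).
PSD_RTOL <- 1e-10

is_psd <- function(S, rtol = PSD_RTOL) {
  ev <- eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -rtol * max(abs(ev), 1e-300)
}

is_pd <- function(S, rtol = PSD_RTOL) {
  ev <- eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > rtol * max(abs(ev))
}

## log2 det of (I + S) for symmetric PSD S, via eigenvalues for stability.
log2_det_I_plus <- function(S) {
  if (length(S) == 0L) return(0)
  ev <- eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  sum(log2(pmax(1 + ev, .Machine$double.xmin)))
}

log2_det <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  as.numeric(d$modulus) / log(2)
}

## Floor the spectrum of a symmetric matrix at rtol * max eigenvalue.
psd_floor <- function(S, rtol = PSD_RTOL) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  lam <- pmax(e$values, rtol * max(e$values))
  symmetrize(e$vectors %*% (lam * t(e$vectors)))
}

## Matrix exponential by scaling and squaring with a Pade(6) approximant.
## Small dense matrices only (the package never exceeds a few hundred rows).
mat_exp <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin) / 0.5)))
  As <- A / 2^s
  ## Pade(6,6)
  cfs <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n)
  P <- I
  U <- cfs[1] * I
  V <- cfs[1] * I
  sgn <- -1
  for (k in seq_len(6)) {
    P <- P %*% As
    U <- U + cfs[k + 1] * P
    V <- V + sgn * cfs[k + 1] * P
    sgn <- -sgn
  }
  E <- solve(V, U)
  for (k in seq_len(s)) E <- E %*% E
  E
}

## Discrete entropy / MI in bits for probability tables.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_bits_table <- function(P) {
  px <- rowSums(P)
  py <- colSums(P)
  nz <- P > 0
  sum(P[nz] * (log2(P[nz]) - log2(outer(px, py)[nz])))
}

## Deterministic child seeds below 2^31 derived from a master seed.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
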