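## Shared fixtures built in code.

## scalar joint with correlation rho (unit variances)
scalar_joint <- function(rho, var = 1) {
  joint_gaussian(matrix(var), matrix(var), matrix(rho * var))
}

## independent 2-D past/future
independent_joint <- function() {
  joint_gaussian(diag(2), diag(2), matrix(0, 2, 2))
}

## seeded random (zeta, dt) draws spanning all damping regimes
random_sddho_draws <- function(n = 20, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      zeta = exp(stats::runif(n, log(0.2), log(5))),
      dt = exp(stats::runif(n, log(0.05), log(5)))
    )
  })
}

## tiny discrete joint (n states) with everywhere-positive entries
toy_discrete_joint <- function(n = 5, seed = 7) {
  P <- withr::with_seed(seed, matrix(stats::runif(n * n, 0.2, 1), n))
  ## mix with a diagonal to give it real past/future dependence
  P <- P / sum(P) * 0.5 + diag(n) / n * 0.5
  discrete_joint(seq(0, 1, length.out = n), P / sum(P))
}

## brute-force MI by explicit double sum (independent oracle)
mi_brute <- function(P) {
  px <- rowSums(P); py <- colSums(P)
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) s <- s + P[i, j] * log2(P[i, j] / (px[i] * py[j]))
  }
  s
}

## small WF joint used across tests (the standard study conditions)
wf_joint_low <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- wf_joint(wf_params(100, 0.2, 0.001, 1))
    val
  }
})

wf_joint_high <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- wf_joint(wf_params(100, 20, 0.001, 1))
    val
  }
})
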