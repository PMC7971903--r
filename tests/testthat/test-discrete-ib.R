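test_that("compression-only optimum is uninformative", {
  j <- toy_discrete_joint()
  enc <- ba_solve(j, m = 3, beta = 0)
  expect_lt(enc$i_past_bits, 1e-9)
  expect_lt(max(apply(enc$q, 2, stats::sd)), 1e-9)   # q independent of x
  expect_equal(effective_cardinality(enc, j), 1L)
})

test_that("discrete information evaluation matches a brute-force double sum", {
  j <- toy_discrete_joint(5)
  q <- withr::with_seed(3, matrix(stats::runif(5 * 2, 0.1, 1), 5, 2))
  q <- q / rowSums(q)
  pt <- discrete_info(q, j)
  Pxt <- j$p_past * q
  Pty <- t(Pxt) %*% j$p_future_given_past
  expect_equal(pt$i_past_bits, mi_brute(Pxt), tolerance = 1e-12)
  expect_equal(pt$i_future_bits, mi_brute(Pty), tolerance = 1e-12)
  ## uniform encoder carries nothing
  u <- matrix(0.5, 5, 2)
  expect_equal(unlist(discrete_info(u, j)), c(i_past_bits = 0, i_future_bits = 0),
               tolerance = 1e-12)
  ## lossless identity encoder: i_past = H(X), i_future = I(X;Y)
  id <- diag(5)
  pt_id <- discrete_info(id, j)
  expect_equal(pt_id$i_past_bits, pibop:::entropy_bits(j$p_past), tolerance = 1e-12)
  expect_equal(pt_id$i_future_bits, j$mi_bits, tolerance = 1e-12)
  expect_error(discrete_info(matrix(1, 4, 1), j), "grid mismatch")
})

test_that("Lagrangian decreases monotonically along the iteration", {
  j <- wf_joint_low()
  expect_no_error(ba_solve(j, 2, 4, init = "random", seed = 2,
                           check_monotone = TRUE))
  expect_no_error(ba_solve(toy_discrete_joint(), 4, 7, init = "random",
                           seed = 3, check_monotone = TRUE))
})

test_that("the binary encoder on the weak-mutation model splits frequency space", {
  j <- wf_joint_low()
  enc <- ba_best(j, 2, 4, n_restarts = 4, seed = 1)
  expect_equal(enc$i_past_bits, 1, tolerance = 0.05)
  expect_lte(enc$i_past_bits, 1 + 1e-9)           # log2(m) cap
  expect_lte(enc$i_future_bits, enc$i_past_bits)  # DPI
  dec <- decoders(enc, j)
  ## the two historical decoders cover near-disjoint frequency ranges
  overlap <- sum(pmin(dec$past[1, ], dec$past[2, ]) *
                   pmin(dec$weights[1], dec$weights[2]) * 2)
  expect_lt(sum(pmin(dec$past[1, ], dec$past[2, ])) *
              min(dec$weights) * 2, 0.05)
})

test_that("information caps: i_past never exceeds log2(m)", {
  j <- wf_joint_low()
  for (m in c(2, 3)) {
    enc <- ba_best(j, m, 50, n_restarts = 3, seed = 2, max_iter = 20000L)
    expect_lte(enc$i_past_bits, log2(m) + 1e-9)
    ## at large beta the channel fills up to its cardinality cap
    expect_gt(enc$i_past_bits, log2(m) - 0.12)
  }
})

test_that("curves for different cardinalities coincide at high compression", {
  j <- wf_joint_low()
  grid <- c(1.01, 1.02)
  c2 <- discrete_curve(j, 2, grid, n_restarts = 4, seed = 1)
  c3 <- discrete_curve(j, 3, grid, n_restarts = 4, seed = 1)
  low <- c2$i_past_bits < 0.5
  expect_true(any(low))
  expect_lt(max(abs(c2$i_future_bits[low] - c3$i_future_bits[low])), 0.01)
  ## m = 1 carries nothing
  c1 <- discrete_curve(j, 1, c(1.5, 4), n_restarts = 2, seed = 1)
  expect_equal(c1$i_future_bits, c(0, 0), tolerance = 1e-10)
})

test_that("curve saturates at the joint's total mutual information", {
  j <- wf_joint_low()
  enc <- ba_annealed(j, 101, 400, n_anneal = 5L, n_restarts = 3L, seed = 1,
                     max_iter = 20000L)
  expect_lte(enc$i_future_bits, j$mi_bits + 1e-9)
  expect_gt(enc$i_future_bits, 0.95 * j$mi_bits)
})

test_that("converged objective matches exhaustive deterministic search on a tiny joint", {
  j <- toy_discrete_joint(4, seed = 9)
  beta <- 3
  ## exhaustive over the 2^4 deterministic binary encoders, each relaxed by
  ## the self-consistent updates (local search)
  best_L <- Inf
  for (mask in 0:15) {
    q0 <- cbind(as.numeric(bitwAnd(mask, 2^(0:3)) > 0))
    q0 <- cbind(q0, 1 - q0)
    q0 <- pmax(q0, 1e-6); q0 <- q0 / rowSums(q0)
    enc <- ba_solve(j, 2, beta, init = q0, tol = 1e-13, max_iter = 20000L)
    best_L <- min(best_L, enc$lagrangian_nats)
  }
  enc_ba <- ba_best(j, 2, beta, n_restarts = 10, seed = 4, tol = 1e-13)
  expect_lt(abs(enc_ba$lagrangian_nats - best_L), 1e-6)
})

test_that("effective cardinality merges degenerate clusters and is idempotent", {
  j <- wf_joint_low()
  ## a redundant encoder: two identical copies of each binary cluster
  enc2 <- ba_best(j, 2, 4, n_restarts = 3, seed = 1)
  q4 <- cbind(enc2$q / 2, enc2$q / 2)
  fake <- structure(list(q = q4, m = 4L, beta = 4, grid = j$grid),
                    class = "pib_discrete_encoder")
  expect_equal(effective_cardinality(fake, j), 2L)
  ## a large-m solve at barely supercritical tradeoff stays effectively binary
  enc50 <- ba_solve(j, 50, 1.01, init = "perturbed-uniform", max_iter = 20000L)
  k <- effective_cardinality(enc50, j)
  expect_lte(k, 3L)
  ## merging is idempotent: the merged structure of the binary solve is stable
  enc2 <- ba_best(j, 2, 4, n_restarts = 2, seed = 1)
  expect_equal(effective_cardinality(enc2, j),
               effective_cardinality(enc2, j))
})

test_that("decoders mix back to the marginals and localize where mass is", {
  j <- wf_joint_low()
  enc <- ba_best(j, 2, 4, n_restarts = 3, seed = 1)
  dec <- decoders(enc, j)
  mix_past <- drop(dec$weights %*% dec$past)
  mix_fut <- drop(dec$weights %*% dec$future)
  expect_lt(max(abs(mix_past - j$p_past)), 1e-10)
  expect_lt(max(abs(mix_fut - j$p_future)), 1e-10)
})

test_that("conditional spread is smallest where the stationary law is largest", {
  j <- wf_joint_low()
  enc <- ba_annealed(j, 24, 60, n_anneal = 4L, n_restarts = 2L, seed = 2,
                     max_iter = 15000L)
  dec <- decoders(enc, j)
  mom <- dec$moments[dec$moments$weight > 1e-3, ]
  ## clusters decoding the high-mass boundary regions are sharper than the
  ## clusters decoding the flat interior
  ps_at <- stats::approx(j$grid, j$p_past, xout = mom$mean_past)$y
  hi <- mom$sd_past[ps_at > stats::quantile(ps_at, 0.7)]
  lo <- mom$sd_past[ps_at < stats::quantile(ps_at, 0.3)]
  expect_lt(mean(hi), mean(lo))
})

test_that("frozen encoders transfer exactly onto their own joint and degrade across models", {
  j_lo <- wf_joint_low(); j_hi <- wf_joint_high()
  enc <- ba_best(j_lo, 2, 4, n_restarts = 3, seed = 1)
  self <- transfer_discrete(enc, j_lo)
  expect_equal(self$i_past_bits, enc$i_past_bits, tolerance = 1e-12)
  expect_equal(self$i_future_bits, enc$i_future_bits, tolerance = 1e-12)
  ## onto the fast-mixing high-mutation model most information is lost
  tr <- transfer_discrete(enc, j_hi)
  expect_lt(tr$i_future_bits, 0.5 * enc$i_future_bits)
  expect_lte(tr$i_future_bits, j_hi$mi_bits + 1e-9)
  bad <- structure(list(q = enc$q[1:50, ], grid = j_lo$grid[1:50]),
                   class = "pib_discrete_encoder")
  expect_error(transfer_discrete(bad, j_hi), "grid mismatch")
})
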