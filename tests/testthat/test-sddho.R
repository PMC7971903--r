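test_that("stationary covariance solves the Lyapunov equation analytically", {
  for (z in c(0.3, 1, 2.5)) {
    S <- sddho_stationary_cov(z)
    expect_equal(S, diag(c(1, 1 / (4 * z^2))), tolerance = 1e-14)
    ## residual of M S + S M' + Q = 0 with the velocity noise 1/(2 zeta^2)
    M <- matrix(c(0, -1 / (4 * z^2), 1, -1), 2, 2)
    Q <- diag(c(0, 1 / (2 * z^2)))
    expect_lt(max(abs(M %*% S + S %*% t(M) + Q)), 1e-14)
  }
})

test_that("joint is stationary and degrades gracefully at extreme lags", {
  j <- sddho_joint(sddho_params(0.7, 0.8))
  expect_equal(j$sigma_past, j$sigma_future, tolerance = 1e-14)
  ## dt -> 0: conditional covariance -> 0, information diverges
  j0 <- sddho_joint(sddho_params(0.7, 1e-5))
  expect_gt(j0$mi_bits, 20)
  ## huge lag: cross block underflows, joint approaches independence
  jinf <- sddho_joint(sddho_params(0.7, 200))
  expect_lt(jinf$mi_bits, 1e-8)
})

test_that("closed forms match the numeric eigen route over randomized draws", {
  draws <- random_sddho_draws(20)
  for (k in seq_len(nrow(draws))) {
    p <- sddho_params(draws$zeta[k], draws$dt[k])
    j <- sddho_joint(p)
    sp <- ib_spectrum(j)
    ## angle of the leading eigenvector (1e-6 rad)
    w <- sp$W[1, ]
    expect_equal(leading_angle(p), atan2(abs(w[2]), abs(w[1])),
                 tolerance = 1e-6)
    ## slope 1 - lambda_1 (1e-8)
    expect_equal(slope_at_origin(p), 1 - sp$lambda[1], tolerance = 1e-8)
    ## total information vs the determinant route (1e-9 bits)
    det_route <- 0.5 * (log2(det(j$sigma_past)) -
                          log2(det(j$sigma_past_given_future)))
    expect_equal(total_predictive_info(p), det_route, tolerance = 1e-9)
  }
})

test_that("angle limits: overdamped late-time convergence and degenerate lags", {
  ## strongly overdamped, large lag: position and velocity weighted equally;
  ## the late-time angle sits at pi/4 + O(1/zeta^2)
  expect_equal(leading_angle(sddho_params(10, 50)), pi / 4, tolerance = 2e-3)
  expect_equal(leading_angle(sddho_params(40, 300)), pi / 4, tolerance = 1e-4)
  gap10 <- abs(leading_angle(sddho_params(10, 300)) - pi / 4)
  gap40 <- abs(leading_angle(sddho_params(40, 300)) - pi / 4)
  expect_equal(gap10 / gap40, 16, tolerance = 0.1)
  ## degenerate lag omega * dt = pi: every direction tied, convention 0
  z <- 0.1
  omega <- sqrt(1 / (4 * z^2) - 1 / 4)
  expect_equal(leading_angle(sddho_params(z, pi / omega)), 0)
  ## small-lag behaviour: angle grows as dt/2 from the position axis
  expect_equal(leading_angle(sddho_params(0.5, 1e-4)), 5e-5, tolerance = 1e-3)
  expect_equal(leading_angle(sddho_params(0.3, 1e-4)), 5e-5, tolerance = 1e-3)
})

test_that("slope limits: near-one at small lags, exponential decay at large lags", {
  for (z in c(0.5, 2)) {
    for (dt in c(0.05, 0.02, 0.01)) {
      s <- slope_at_origin(sddho_params(z, dt))
      expect_gte(s, 1 - dt^2)       # deviation from 1 is higher order
      expect_lt(s, 1)
    }
  }
  ## underdamped large-lag decay rate ~ 1 per unit lag (log scale)
  s1 <- slope_at_origin(sddho_params(0.5, 12))
  s2 <- slope_at_origin(sddho_params(0.5, 12 + 2 * pi * 2 * 0.5 / sqrt(3)))
  ## compare one full oscillation period apart to dodge the oscillatory factor
  period <- 2 * pi / sqrt(1 / (4 * 0.25) - 0.25)
  s2 <- slope_at_origin(sddho_params(0.5, 12 + period))
  expect_equal(log(s1 / s2), period, tolerance = 0.02)
})

test_that("critical damping closed forms agree with the numeric route", {
  p <- sddho_params(1, 1.3)
  j <- sddho_joint(p)
  sp <- ib_spectrum(j)
  expect_equal(slope_at_origin(p), 1 - sp$lambda[1], tolerance = 1e-8)
  w <- sp$W[1, ]
  expect_equal(leading_angle(p), atan2(abs(w[2]), abs(w[1])), tolerance = 1e-6)
})

test_that("total predictive information decays monotonically and vanishes", {
  dts <- c(0.1, 0.5, 1, 2, 5, 10, 30)
  for (z in c(0.5, 1.7)) {
    I <- vapply(dts, function(dt) total_predictive_info(sddho_params(z, dt)), 0)
    expect_false(is.unsorted(rev(I)))
  }
  ## decorrelation: underdamped modes decay at rate 1, overdamped ones at
  ## the slow-eigenvalue rate, so the lag for "vanished" differs by regime
  expect_lt(total_predictive_info(sddho_params(0.5, 30)), 1e-8)
  expect_lt(total_predictive_info(sddho_params(1.7, 150)), 1e-8)
})

test_that("small-lag growth of total information follows the log law", {
  ## the 2-D (position, velocity) state decorrelates with det ~ dt^4, so
  ## information grows as -2 log2(e) ln(dt) + const
  dts <- exp(seq(log(1e-4), log(1e-2), length.out = 12))
  I <- vapply(dts, function(dt) total_predictive_info(sddho_params(0.5, dt)), 0)
  slope <- stats::coef(stats::lm(I ~ log(dts)))[2]
  expect_equal(unname(slope), -2 * log2(exp(1)), tolerance = 0.05 * 2 * log2(exp(1)))
})

test_that("fixed-information sweep hits the target and orders lags correctly", {
  sw <- fixed_info_sweep(c(4, 0.4), c(0.3, 1, 3), i_past = 5)
  expect_true(all(abs(sw$i_past_bits - 5) < 1e-6))
  ## overdamped short-lag cell: mostly position information
  cell <- dplyr::filter(sw, zeta == 4, dt == 0.3)
  expect_lt(abs(cell$w_v) / abs(cell$w_x), 1)
  ## predictive information decreases with the lag at fixed damping
  for (z in c(4, 0.4)) {
    ii <- dplyr::filter(sw, zeta == z) |> dplyr::arrange(dt)
    expect_false(is.unsorted(rev(ii$i_future_bits)))
  }
})

test_that("transfer recovers the source optimum on identity and respects optimality", {
  src <- sddho_params(1, 1)
  self <- transfer_gaussian(src, 1, src)
  opt <- evaluate_encoder(encoder_at_ipast(sddho_joint(src), 1), sddho_joint(src))
  expect_equal(as.data.frame(self), as.data.frame(opt), tolerance = 1e-9)
  ## transferred future information never beats the target-optimal encoder
  ## at the transferred past level
  for (tgt in list(sddho_params(0.4, 0.5), sddho_params(2.5, 2))) {
    tr <- transfer_gaussian(src, 1, tgt)
    jt <- sddho_joint(tgt)
    opt_t <- evaluate_encoder(encoder_at_ipast(jt, tr$i_past_bits), jt)
    expect_lte(tr$i_future_bits, opt_t$i_future_bits + 1e-8)
  }
})

test_that("transferability surface and Q metric behave as expected", {
  ## single-point grid at the source itself: Q = 1
  src <- sddho_params(1, 1)
  tm1 <- q_transfer(src, 1, zeta_range = c(1, 1), dt_range = c(1, 1),
                    n_zeta = 1, n_dt = 1)
  expect_equal(tm1$q, 1, tolerance = 1e-6)
  ## surface value at the source equals the source optimum
  self_row <- dplyr::filter(tm1$surface,
                            abs(zeta_t - 1) < 1e-12, abs(dt_t - 1) < 1e-12)
  opt <- evaluate_encoder(encoder_at_ipast(sddho_joint(src), 1), sddho_joint(src))
  expect_equal(self_row$i_future_bits[1], opt$i_future_bits, tolerance = 1e-9)

  ## a source in the middle of the target region transfers broadly, while a
  ## source near an oscillation node (velocity-only encoder) does not
  q_center <- q_transfer(sddho_params(1, 1), 1, n_zeta = 7, n_dt = 7)$q
  q_node <- q_transfer(sddho_params(1 / 2, 3.2), 1, n_zeta = 7, n_dt = 7)$q
  expect_gt(q_center, 0.9)
  expect_lt(q_node, 0.5)
  expect_gt(q_node, 0)

  ## integration converges: doubling the grid moves Q by < 2 percent
  q1 <- q_transfer(sddho_params(1, 1), 1, n_zeta = 8, n_dt = 8)$q
  q2 <- q_transfer(sddho_params(1, 1), 1, n_zeta = 16, n_dt = 16)$q
  expect_lt(abs(q2 - q1) / q2, 0.02)
})

test_that("near an oscillation node the optimal encoder is velocity-dominated", {
  ## brute-force search over encoder orientations at fixed i_past confirms
  ## the closed-form angle just below omega * dt = pi
  p <- sddho_params(0.5, 3.2)
  j <- sddho_joint(p)
  best <- c(angle = NA, ifu = -Inf)
  for (phi in seq(0, pi - 1e-9, length.out = 721)) {
    w <- matrix(c(cos(phi), sin(phi)), 1)
    wsw <- drop(w %*% j$sigma_past %*% t(w))
    A <- sqrt((2^(2 * 1) - 1) / wsw) * w        # i_past = 1 bit
    ifu <- evaluate_encoder(A, j)$i_future_bits
    if (ifu > best["ifu"]) best <- c(angle = phi, ifu = ifu)
  }
  expect_equal(unname(best["angle"]), leading_angle(p), tolerance = 0.01)
  expect_gt(best["angle"], 1)   # velocity-dominated
})
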