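test_that("spectrum: independent pair gives unit eigenvalues and infinite critical tradeoffs", {
  sp <- ib_spectrum(independent_joint())
  expect_equal(sp$lambda, c(1, 1), tolerance = 1e-12)
  expect_true(all(is.infinite(sp$beta_c)))
})

test_that("spectrum: scalar joint gives lambda = 1 - rho^2, beta_c = 1/rho^2", {
  for (rho in c(0.3, 0.6, 0.9)) {
    sp <- ib_spectrum(scalar_joint(rho))
    expect_equal(sp$lambda, 1 - rho^2, tolerance = 1e-12)
    expect_equal(sp$beta_c, 1 / rho^2, tolerance = 1e-10)
  }
})

test_that("spectrum eigenvectors are genuine left eigenvectors, sorted and normalized", {
  j <- sddho_joint(sddho_params(0.5, 1))
  sp <- ib_spectrum(j)
  M <- j$sigma_past_given_future %*% solve(j$sigma_past)
  for (i in seq_along(sp$lambda)) {
    resid <- drop(sp$W[i, ] %*% M) - sp$lambda[i] * sp$W[i, ]
    expect_lt(max(abs(resid)), 1e-10)
    expect_equal(sum(sp$W[i, ]^2), 1, tolerance = 1e-12)
    first_nz <- sp$W[i, which(abs(sp$W[i, ]) > 1e-12)[1]]
    expect_gt(first_nz, 0)
  }
  expect_false(is.unsorted(sp$lambda))
  expect_false(is.unsorted(sp$beta_c))
  expect_true(all(sp$lambda > 0 & sp$lambda <= 1))
  expect_true(all(sp$beta_c >= 1))
})

test_that("spectrum matches the oscillator's closed-form leading angle", {
  p <- sddho_params(0.5, 1)
  sp <- ib_spectrum(sddho_joint(p))
  w <- sp$W[1, ]
  expect_equal(atan2(abs(w[2]), abs(w[1])), leading_angle(p), tolerance = 1e-6)
})

test_that("optimal encoder activates rows exactly at the critical tradeoffs", {
  j <- sddho_joint(sddho_params(0.5, 1))
  sp <- ib_spectrum(j)
  enc0 <- optimal_encoder(j, sp$beta_c[1] * 0.999)
  expect_equal(enc0$A, matrix(0, 2, 2))
  expect_equal(as.data.frame(evaluate_encoder(enc0, j)),
               data.frame(i_past_bits = 0, i_future_bits = 0))
  enc1 <- optimal_encoder(j, mean(sp$beta_c))
  expect_equal(qr(enc1$A)$rank, 1L)
  enc2 <- optimal_encoder(j, sp$beta_c[2] * 1.01)
  expect_equal(qr(enc2$A)$rank, 2L)
  ## representation dimensionality steps up exactly at beta_c
  betas <- c(sp$beta_c[1] * c(0.99, 1.01), sp$beta_c[2] * c(0.99, 1.01))
  ranks <- vapply(betas, function(b) sum(rowSums(abs(optimal_encoder(j, b)$A)) > 0), 0L)
  expect_equal(ranks, c(0L, 1L, 1L, 2L))
})

test_that("large beta approaches the total predictive information", {
  p <- sddho_params(0.5, 1)
  j <- sddho_joint(p)
  pt <- evaluate_encoder(optimal_encoder(j, 1e6), j)
  expect_equal(pt$i_future_bits, total_predictive_info(p), tolerance = 1e-3)
})

test_that("evaluate_encoder reproduces the scalar closed form and checks dimensions", {
  rho <- 0.7; a <- 1.3; v <- 2
  j <- scalar_joint(rho, var = v)
  pt <- evaluate_encoder(new_gaussian_encoder(matrix(a)), j)
  ip <- 0.5 * log2(1 + a^2 * v)
  expect_equal(pt$i_past_bits, ip, tolerance = 1e-12)
  expect_equal(pt$i_future_bits, ip - 0.5 * log2(1 + a^2 * v * (1 - rho^2)),
               tolerance = 1e-12)
  expect_error(evaluate_encoder(matrix(1, 1, 3), j), "dimension mismatch")
})

test_that("no random encoder beats the optimal one at matched past information", {
  j <- sddho_joint(sddho_params(0.5, 1))
  target <- 2
  opt <- evaluate_encoder(encoder_at_ipast(j, target), j)
  worst_gap <- Inf
  withr::with_seed(11, {
    for (k in 1:200) {
      A <- matrix(stats::rnorm(4), 2)
      ## rescale to the target i_past
      f <- function(logs) {
        evaluate_encoder(exp(logs) * A, j)$i_past_bits - target
      }
      s <- exp(stats::uniroot(f, c(-30, 30), tol = 1e-13)$root)
      pt <- evaluate_encoder(s * A, j)
      expect_equal(pt$i_past_bits, target, tolerance = 1e-6)
      expect_lte(pt$i_future_bits, opt$i_future_bits + 1e-6)
      worst_gap <- min(worst_gap, opt$i_future_bits - pt$i_future_bits)
    }
  })
  expect_gte(worst_gap, -1e-6)
})

test_that("info curve matches the piecewise-analytic solution and is concave", {
  j <- sddho_joint(sddho_params(0.5, 1))
  grid <- exp(seq(log(1.001), log(500), length.out = 80))
  cv <- info_curve(j, grid)
  an <- ib_curve_analytic(j, grid)
  expect_lt(max(abs(cv$i_past_bits - an$i_past_bits)), 1e-6)
  expect_lt(max(abs(cv$i_future_bits - an$i_future_bits)), 1e-6)
  ## monotone in beta, DPI everywhere
  expect_false(is.unsorted(cv$i_past_bits))
  expect_false(is.unsorted(cv$i_future_bits))
  expect_true(all(cv$i_future_bits <= cv$i_past_bits + 1e-12))
  expect_true(all(cv$i_future_bits <= j$mi_bits + 1e-9))
  ## concavity of i_future(i_past): discrete second differences <= tol
  act <- cv$i_past_bits > 1e-9
  x <- cv$i_past_bits[act]; y <- cv$i_future_bits[act]
  slopes <- diff(y) / diff(x)
  expect_true(all(diff(slopes) <= 1e-8))
})

test_that("independent past/future gives an identically zero curve", {
  cv <- info_curve(independent_joint(), c(1.5, 10, 100))
  expect_equal(cv$i_future_bits, rep(0, 3))
})

test_that("initial slope of the oscillator curve matches the closed form", {
  p <- sddho_params(0.5, 1)
  j <- sddho_joint(p)
  b1 <- min(ib_spectrum(j)$beta_c)
  cv <- info_curve(j, b1 * c(1.0005, 1.001))
  slope <- diff(cv$i_future_bits) / diff(cv$i_past_bits)
  expect_equal(slope, slope_at_origin(p), tolerance = 1e-3)
})

test_that("conditional covariances behave at the limits and satisfy the MI identity", {
  j <- sddho_joint(sddho_params(0.5, 1))
  cc0 <- conditional_covariances(new_gaussian_encoder(matrix(0, 2, 2)), j)
  expect_equal(cc0$past, j$sigma_past, tolerance = 1e-12)
  expect_equal(cc0$future, j$sigma_future, tolerance = 1e-12)

  enc <- optimal_encoder(j, 1e7)
  cc <- conditional_covariances(enc, j)
  sfp <- j$sigma_future -
    t(j$sigma_cross) %*% solve(j$sigma_past, j$sigma_cross)
  expect_equal(cc$future, sfp, tolerance = 1e-4)
  ## PSD ordering against the priors
  expect_gte(min(eigen(j$sigma_past - cc$past, symmetric = TRUE)$values), -1e-10)
  expect_gte(min(eigen(j$sigma_future - cc$future, symmetric = TRUE)$values), -1e-10)

  enc2 <- optimal_encoder(j, 20)
  cc2 <- conditional_covariances(enc2, j)
  ip <- evaluate_encoder(enc2, j)$i_past_bits
  expect_equal(0.5 * (log2(det(j$sigma_past)) - log2(det(cc2$past))), ip,
               tolerance = 1e-9)
})

test_that("rotating an encoder preserves past information and loses future information", {
  j <- sddho_joint(sddho_params(0.5, 1))
  enc <- encoder_at_ipast(j, 3)
  base <- evaluate_encoder(enc, j)

  r0 <- rotate_encoder(enc, 0, j)
  expect_equal(as.data.frame(evaluate_encoder(r0, j)), as.data.frame(base),
               tolerance = 1e-9)

  r90 <- rotate_encoder(enc, pi / 2, j)
  pt90 <- evaluate_encoder(r90, j)
  expect_equal(pt90$i_past_bits, base$i_past_bits, tolerance = 1e-6)
  expect_lt(pt90$i_future_bits, base$i_future_bits - 0.05)

  for (th in c(0.3, 1.1, 2.0)) {
    pt <- evaluate_encoder(rotate_encoder(enc, th, j), j)
    expect_equal(pt$i_past_bits, base$i_past_bits, tolerance = 1e-6)
    expect_lte(pt$i_future_bits, base$i_future_bits + 1e-9)
  }

  expect_error(rotate_encoder(encoder_at_ipast(scalar_joint(0.5), 1), 0.5,
                              scalar_joint(0.5)),
               "unsupported dimension")
})
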