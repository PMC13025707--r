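test_that("mutual information follows the Gaussian closed form", {
  expect_identical(mutual_information(0), 0)
  expect_identical(mutual_information(-0.5), mutual_information(0.5))
  expect_equal(mutual_information(0.3), 0.0471553, tolerance = 1e-6)
  expect_equal(mutual_information(0.3), -0.5 * log(0.91), tolerance = 1e-15)
  expect_true(all(mutual_information(seq(-0.95, 0.95, by = 0.05)) >= 0))
  expect_error(mutual_information(1), "rho")
  expect_error(mutual_information(-1.2), "rho")
})

test_that("exact dependence ratio matches the bivariate-normal density ratio", {
  expect_equal(dependence_ratio(0.7, -1.3, 0), 1)
  expect_equal(dependence_ratio(0, 0, 0.5), 1 / sqrt(0.75), tolerance = 1e-12)
  # independent oracle: explicit joint/marginal Gaussian densities
  dens_ratio <- function(zx, zy, rho) {
    joint <- exp(-(zx^2 - 2 * rho * zx * zy + zy^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
    joint / (dnorm(zx) * dnorm(zy))
  }
  set.seed(11)
  for (i in 1:50) {
    zx <- runif(1, -3, 3); zy <- runif(1, -3, 3); rho <- runif(1, -0.9, 0.9)
    expect_equal(dependence_ratio(zx, zy, rho), dens_ratio(zx, zy, rho),
                 tolerance = 1e-12)
  }
  expect_gt(dependence_ratio(1, 1, 0.1), 0)
  expect_error(dependence_ratio(0, 0, 1), "rho")
})

test_that("Mehler truncation has cubic-order error against the exact ratio", {
  expect_identical(mehler_truncation(1.7, -0.4, 0), 0)
  expect_equal(mehler_truncation(0, 0, 0.2), 0.02, tolerance = 1e-15)
  z <- seq(-2, 2, by = 0.05)
  g <- expand.grid(zx = z, zy = z)
  sup_err <- function(rho)
    max(abs(mehler_truncation(g$zx, g$zy, rho) -
              (dependence_ratio(g$zx, g$zy, rho) - 1)))
  errs <- vapply(c(0.01, 0.02, 0.04), sup_err, numeric(1))
  ratios <- errs[-1] / errs[-3]
  # O(rho^3) remainder: each doubling multiplies the error by ~8
  expect_true(all(ratios > 8 / 1.5 & ratios < 8 * 1.5))
})

test_that("weak-coupling polynomial matches the closed-form coefficients", {
  s0 <- sensing_params(rho = 0, zbar_Y = 0.7, S_X = 2, sigma_X = 0.5)
  q0 <- case1_polynomial(s0)
  expect_equal(c(q0$c0, q0$c1, q0$c2), c(0, 0, 0))
  expect_identical(q0$case_tag, "case_I")

  q <- case1_polynomial(sensing_params(rho = 0.1, zbar_Y = 0, S_X = 1, sigma_X = 1))
  expect_equal(q$c0, -0.01, tolerance = 1e-15)
  expect_equal(q$c1, 0.01, tolerance = 1e-15)
  expect_equal(q$c2, -0.005, tolerance = 1e-15)

  # (zbar_Y^2 - 1) factor kills the quadratic term at unit bias
  for (rho in c(-0.4, 0.2, 0.8)) {
    q1 <- case1_polynomial(sensing_params(rho, zbar_Y = 1, S_X = 3, sigma_X = 2))
    expect_identical(q1$c2, 0)
  }
})

test_that("the expansion-consistent weak-coupling variant differs only in the constant", {
  set.seed(21)
  for (i in 1:20) {
    s <- sensing_params(runif(1, -0.3, 0.3), runif(1, -2, 2),
                        runif(1, 0, 3), runif(1, 0.2, 2))
    qp <- case1_polynomial(s, variant = "printed")
    qe <- case1_polynomial(s, variant = "expansion")
    expect_identical(qp$c1, qe$c1)
    expect_identical(qp$c2, qe$c2)
    # oracle: substitute z_x = x/sigma - S into the truncated expansion and
    # read off the constant term
    c0_direct <- mehler_truncation(-s$S_X, s$zbar_Y, s$rho)
    expect_equal(qe$c0, c0_direct, tolerance = 1e-12)
  }
})

test_that("homeostatic-limit base constants obey their closed forms and limits", {
  b0 <- case2_base_constants(sensing_params(0, zbar_Y = 1.3))
  expect_equal(c(b0$A, b0$B, b0$r0, b0$r_tilde), c(0, 0, 1, 0))

  b <- case2_base_constants(sensing_params(0.5, zbar_Y = 0))
  expect_equal(b$A, 0)
  expect_equal(b$B, -0.125, tolerance = 1e-15)
  expect_equal(b$r0, 1 / sqrt(0.75), tolerance = 1e-12)

  # r0 is the exact dependence ratio at z_x = 0
  set.seed(31)
  for (i in 1:25) {
    rho <- runif(1, -0.95, 0.95); zy <- runif(1, -3, 3)
    bb <- case2_base_constants(sensing_params(rho, zbar_Y = zy))
    expect_equal(bb$r0, dependence_ratio(0, zy, rho), tolerance = 1e-12)
    expect_gte(bb$r0, 0)
  }
})

test_that("homeostatic-limit polynomial reproduces the perfect-sensing signs", {
  s <- sensing_params(0.5, zbar_Y = 0, S_X = 1, sigma_X = 1)
  q <- case2_polynomial(s)
  r0 <- 1 / sqrt(0.75)
  expect_equal(q$c2, -0.125 * r0, tolerance = 1e-12)       # C-tilde
  expect_equal(q$c2, -0.1443376, tolerance = 1e-6)
  # A-tilde part of the constant: c0 - r_tilde
  expect_equal(q$c0 - (r0 - 1), -0.125 * r0, tolerance = 1e-12)
  expect_identical(q$case_tag, "case_II")

  q0 <- case2_polynomial(sensing_params(0, zbar_Y = 0.4, S_X = 2))
  expect_equal(c(q0$c0, q0$c1, q0$c2), c(0, 0, 0))

  # sign of the quadratic term follows the sign of B
  set.seed(41)
  for (i in 1:30) {
    rho <- runif(1, 0.05, 0.95); zy <- runif(1, 0, 3)
    qq <- case2_polynomial(sensing_params(rho, zy, S_X = 1.5, sigma_X = 0.7))
    if (zy^2 < (1 - rho^2)^2) expect_lt(qq$c2, 0) else if (zy^2 > (1 - rho^2)^2)
      expect_gt(qq$c2, 0)
  }
})

test_that("effective coefficients combine adaptation and proliferation correctly", {
  q <- structure(list(c0 = 0.3, c1 = -0.2, c2 = 0.1, case_tag = "case_II"),
                 class = "quadratic_fitness")
  co <- effective_coefficients(q, proliferation_params(), tau = 1)
  expect_equal(unname(c(co$alpha, co$beta, co$gamma)), c(-0.2, 0.3, 0.1))

  z <- structure(list(c0 = 0, c1 = 0, c2 = 0, case_tag = "case_I"),
                 class = "quadratic_fitness")
  co2 <- effective_coefficients(z, proliferation_params(mu_prime = 1, X_bar = 2),
                                tau = 1)
  expect_equal(c(co2$alpha, co2$beta, co2$gamma), c(1, -2, 0))
  expect_error(effective_coefficients(q, proliferation_params(), tau = 0), "tau")
})

test_that("linear proliferation tilts but never changes the saturation term", {
  s <- sensing_params(0.4, 0.8, 1.5, 0.9, tau = 2)
  q <- case2_polynomial(s)
  base <- adaptation_only_coefficients(s, "II")
  set.seed(51)
  for (i in 1:20) {
    mp <- runif(1, -2, 2); xb <- runif(1, -2, 2)
    co <- effective_coefficients(q, proliferation_params(mu_prime = mp, X_bar = xb),
                                 tau = s$tau)
    expect_identical(co$gamma, base$gamma)
    expect_equal(co$beta, base$beta - mp * xb, tolerance = 1e-12)
    expect_equal(co$alpha, base$alpha + mp, tolerance = 1e-12)
  }
  # curvature shifts gamma by exactly mu''/2
  for (mpp in c(-0.6, 0.4)) {
    co <- effective_coefficients(q, proliferation_params(mu_double_prime = mpp),
                                 tau = s$tau)
    expect_equal(co$gamma - base$gamma, mpp / 2, tolerance = 1e-12)
  }
})

test_that("adaptation-only coefficients are the zero-proliferation composition", {
  s <- sensing_params(0.5, zbar_Y = 0.5, S_X = 0.25, sigma_X = 0.35, tau = 1)
  co <- adaptation_only_coefficients(s, "II")
  ref <- effective_coefficients(case2_polynomial(s), proliferation_params(), 1)
  expect_equal(co$alpha, ref$alpha)
  expect_equal(co$beta, ref$beta)
  expect_equal(co$gamma, ref$gamma)
  expect_equal(co$delta, 9 * co$alpha^2 - 48 * co$gamma * co$beta)

  z <- adaptation_only_coefficients(sensing_params(0, 1, 1, 1), "I")
  expect_equal(c(z$alpha, z$beta, z$gamma), c(0, 0, 0))
})

test_that("parameter containers validate their domains", {
  expect_error(sensing_params(1.0), "rho")
  expect_error(sensing_params(0.5, sigma_X = 0), "sigma_X")
  expect_error(sensing_params(0.5, S_X = -1), "S_X")
  expect_error(sensing_params(0.5, tau = -2), "tau")
  s <- sensing_params(0.2, S_X = 3, sigma_X = 0.5)
  expect_identical(s$mu_X, 1.5)
  expect_error(proliferation_params(mu_prime = Inf))
  co <- cubic_coefficients(2, -1, 0.5)
  expect_equal(co$delta, 9 * 4 - 48 * 0.5 * (-1))
})
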