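test_that("cubic force and bare potential are gradient-consistent", {
  sw <- cubic_coefficients(-1, 2, -1)
  expect_identical(cubic_force(0, sw), 0)
  expect_equal(cubic_force(1, sw), 7 / 6, tolerance = 1e-15)
  expect_identical(bare_potential(0, sw), 0)
  expect_equal(bare_potential(1.81174, sw), -1.3938, tolerance = 1e-3)

  set.seed(61)
  h <- 1e-5
  for (i in 1:30) {
    co <- cubic_coefficients(runif(1, -3, 3), runif(1, -3, 3), runif(1, -3, 3))
    x <- runif(5, -3, 3)
    num_grad <- (bare_potential(x + h, co) - bare_potential(x - h, co)) / (2 * h)
    expect_equal(cubic_force(x, co), -num_grad, tolerance = 1e-6)
  }
  # quartic confinement for gamma < 0
  expect_gt(bare_potential(50, cubic_coefficients(0.3, 5, -0.2)), 1e4)
  expect_gt(bare_potential(-50, cubic_coefficients(0.3, 5, -0.2)), 1e4)
})

test_that("fixed points match the closed-form roots and their stabilities", {
  fp <- fixed_points(cubic_coefficients(-1, 2, -1))
  expect_equal(fp$location, c(-3.311738, 0, 1.811738), tolerance = 1e-6)
  expect_identical(fp$stable, c(TRUE, FALSE, TRUE))

  fp2 <- fixed_points(cubic_coefficients(0.5, 2, 0.5))
  expect_identical(nrow(fp2), 1L)
  expect_identical(fp2$location, 0)
  expect_false(fp2$stable)

  fp3 <- fixed_points(cubic_coefficients(1.5, 2, 0))
  expect_equal(fp3$location, c(-8 / 3, 0), tolerance = 1e-12)
  expect_identical(fp3$stable, c(TRUE, FALSE))

  fp0 <- fixed_points(cubic_coefficients(0, 0, 0))
  expect_identical(nrow(fp0), 1L)
  expect_true(fp0$marginal)
})

test_that("fixed points agree with a brute-force sign-change scan", {
  set.seed(71)
  n_checked <- 0L
  for (i in 1:300) {
    co <- cubic_coefficients(runif(1, -3, 3), runif(1, -3, 3), runif(1, -3, 3))
    fp <- fixed_points(co)
    # residual bound on every reported root
    expect_true(all(abs(cubic_force(fp$location, co)) <=
                      1e-9 * pmax(1, abs(co$gamma) * abs(fp$location)^3)))
    scan <- scan_fixed_points(co, lim = 50, step = 1e-3)
    # a sign scan cannot see tangential roots, roots outside its window
    # (one root escapes to infinity as gamma -> 0), or pairs closer than its
    # step; skip those near-degenerate draws
    if (min(abs(fp$slope)) < 1e-2 || max(abs(fp$location)) > 49 ||
        (nrow(fp) > 1 && min(diff(fp$location)) < 1e-2)) next
    n_checked <- n_checked + 1L
    expect_identical(nrow(fp), length(scan))
    expect_true(all(abs(fp$location - scan) < 2e-3))
  }
  expect_gt(n_checked, 250L)
})

test_that("regime classification recovers the canonical labels", {
  for (nm in names(canonical_triples)) {
    tr <- canonical_triples[[nm]]
    expect_identical(classify_regime(cubic_coefficients(tr[1], tr[2], tr[3]))$name,
                     nm)
  }
  # sign pattern outside the canonical table rows: resolved topologically
  lbl <- classify_regime(cubic_coefficients(1, -2, -1))
  expect_identical(lbl$name, "phenotypic_fixation")
  expect_identical(lbl$matched_by, "topology_fallback")
  expect_identical(classify_regime(cubic_coefficients(0, 0, 0))$name,
                   "critical_switch")
})

test_that("regime labels are invariant under positive rescaling", {
  set.seed(81)
  for (i in 1:50) {
    co <- cubic_coefficients(runif(1, -3, 3), runif(1, -3, 3), runif(1, -3, 3))
    k <- runif(1, 0.01, 100)
    sc <- cubic_coefficients(k * co$alpha, k * co$beta, k * co$gamma)
    expect_identical(classify_regime(sc)$name, classify_regime(co)$name)
  }
})

test_that("barrier depth equals the potential difference between outer extrema", {
  sw <- cubic_coefficients(-1, 2, -1)
  expect_equal(barrier_depth(sw), 105^1.5 / 192, tolerance = 1e-12)
  expect_equal(barrier_depth(sw), 5.60381, tolerance = 1e-5)
  # alpha enters only through Delta = 9 alpha^2 - 48 gamma beta
  expect_identical(barrier_depth(cubic_coefficients(1, -2, 1)),
                   barrier_depth(cubic_coefficients(-1, -2, 1)))
  expect_error(barrier_depth(cubic_coefficients(0.5, 2, 0.5)), "undefined")
  expect_error(barrier_depth(cubic_coefficients(1.5, 2, 0)), "undefined")

  set.seed(91)
  n_ok <- 0L
  while (n_ok < 200L) {
    co <- cubic_coefficients(runif(1, -3, 3), runif(1, -3, 3), runif(1, -3, 3))
    if (!(co$delta > 0 && co$gamma != 0)) next
    n_ok <- n_ok + 1L
    xpm <- (-3 * co$alpha + c(-1, 1) * sqrt(co$delta)) / (4 * co$gamma)
    num <- abs(diff(bare_potential(xpm, co)))
    expect_equal(barrier_depth(co), num, tolerance = 1e-8)
  }
})

test_that("barrier depth decreases as the saturation strength grows", {
  delta <- 105
  depths <- vapply(c(0.5, 1, 2, 4), function(g) {
    beta <- (9 * 1 - delta) / (48 * -g)   # alpha = 1, gamma = -g keeps Delta fixed
    barrier_depth(cubic_coefficients(1, beta, -g))
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
})

test_that("stationary density recovers the Ornstein-Uhlenbeck law", {
  ou <- stationary_density(cubic_coefficients(0, -1, 0), D = 1)
  mass <- trapz_num(ou$grid, ou$density)
  expect_equal(mass, 1, tolerance = 1e-6)
  m1 <- trapz_num(ou$grid, ou$grid * ou$density)
  m2 <- trapz_num(ou$grid, ou$grid^2 * ou$density)
  expect_equal(m1, 0, tolerance = 1e-6)
  expect_equal(m2, 1, tolerance = 1e-4)
  # against the Gaussian closed form pointwise
  expect_equal(ou$density, dnorm(ou$grid), tolerance = 1e-6)

  ou2 <- stationary_density(cubic_coefficients(0, -2, 0), D = 0.5)
  v <- trapz_num(ou2$grid, ou2$grid^2 * ou2$density)
  expect_equal(v, 0.25, tolerance = 1e-4)   # D/|beta|
})

test_that("stationary density is defined exactly on confining landscapes", {
  fx <- stationary_density(cubic_coefficients(-1, -2, -1), D = 1)
  expect_equal(trapz_num(fx$grid, fx$density), 1, tolerance = 1e-6)
  expect_equal(fx$grid[which.max(fx$density)], 0, tolerance = 1e-2)
  # tails negligible at the truncation ends
  expect_lt(max(fx$density[c(1, length(fx$grid))]) / max(fx$density), 1e-11)
  expect_error(stationary_density(cubic_coefficients(0.5, 2, 0.5)),
               "non-normalizable")
  expect_error(stationary_density(cubic_coefficients(0, 1, 0)),
               "non-normalizable")
})

test_that("the landscape report bundles analysis consistently", {
  m <- phenoscape(fixture("regimes/switch"))
  expect_identical(m$regime$name, "phenotypic_switch")
  expect_identical(sum(m$fixed_points$stable), 2L)
  expect_equal(m$barrier_depth, 5.60381, tolerance = 1e-5)
  expect_true(m$barrier_is_well_asymmetry)  # both outer extrema are wells
  expect_true(m$normalizable)
  expect_equal(unname(coef(m)), c(-1, 2, -1))

  ex <- phenoscape(fixture("regimes/explosion"))
  expect_identical(ex$regime$name, "phenotypic_explosion")
  expect_identical(sum(ex$fixed_points$stable), 0L)
  expect_true(is.na(ex$barrier_depth))
  expect_false(ex$normalizable)

  z <- phenoscape(cubic_coefficients(0, 0, 0))
  expect_identical(z$regime$name, "critical_switch")
  expect_identical(nrow(z$fixed_points), 1L)
  expect_true(z$fixed_points$marginal)

  expect_error(phenoscape(), "exactly one")
  expect_error(phenoscape(fixture("regimes/switch"), D = 0), "D")
})

test_that("sensing-derived landscapes expose provenance and methods work", {
  s <- sensing_params(0.5, zbar_Y = 0.5, S_X = 0.25, sigma_X = 0.35, tau = 1)
  m <- phenoscape(sensing = s, case = "II")
  ref <- adaptation_only_coefficients(s, "II")
  expect_equal(coef(m), c(alpha = ref$alpha, beta = ref$beta, gamma = ref$gamma))
  expect_equal(m$mutual_information, mutual_information(0.5))
  expect_output(print(m), "phenotypic")
  expect_output(print(summary(m)), "Fixed points")

  e <- simulate(m, nsim = 3, seed = 5, t_end = 0.5)
  expect_s3_class(e, "trajectory_ensemble")
  expect_identical(e$n_traj, 3L)

  grDevices::pdf(nullfile())
  on.exit(grDevices::dev.off())
  expect_silent(plot(m))
  if (m$normalizable) expect_silent(plot(m, which = "density"))
})
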