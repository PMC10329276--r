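test_that("double-well potential and its diffusion ratio match closed forms", {
  expect_identical(dw_potential(0), 0)
  expect_identical(dw_potential(1), 0)
  expect_equal(dw_potential(2), 0.5)
  expect_equal(dw_potential(0.5), 1 / (2 * pi^2), tolerance = 1e-12)
  expect_error(dw_potential(-0.1), "nonnegative")

  expect_equal(dw_potential_ratio(1), 0)
  expect_equal(dw_potential_ratio(2), 0.5)
  expect_equal(dw_potential_ratio(1e-12), 1)
  # limit approached smoothly: sin(2 pi a) / (2 pi a)
  a <- c(1e-6, 1e-4, 0.01)
  expect_equal(dw_potential_ratio(a), sin(2 * pi * a) / (2 * pi * a),
               tolerance = 1e-12)
})

test_that("smoothed Dirac and Heaviside form a consistent mollifier pair", {
  eps <- 1.5
  expect_equal(dirac_smooth(c(-eps, eps), eps), c(0, 0))
  expect_equal(dirac_smooth(0, eps), 2 / (2 * eps))
  expect_error(dirac_smooth(0, -1), "positive")

  # midpoint-rule quadrature of the Dirac integrates to 1
  n <- 1e4
  s <- seq(-eps + eps / n, eps - eps / n, length.out = n)
  expect_equal(sum(dirac_smooth(s, eps)) * (2 * eps / n), 1, tolerance = 1e-6)

  expect_equal(heaviside_smooth(0, eps), 0.5)
  expect_equal(heaviside_smooth(c(-2 * eps, 2 * eps), eps), c(0, 1))
  # H' = dirac (central finite difference)
  h <- 1e-6
  fd <- (heaviside_smooth(0.3 + h, eps) - heaviside_smooth(0.3 - h, eps)) /
    (2 * h)
  expect_equal(fd, dirac_smooth(0.3, eps), tolerance = 1e-6)
})

test_that("edge indicator is 1 on flat images and matches the ramp oracle", {
  expect_true(all(edge_indicator(matrix(7, 16, 16)) == 1))
  # ramp I = 2x is invariant under symmetric smoothing away from borders,
  # so the interior gradient is 2 and beta = 1/(1+4)
  ramp <- matrix(rep(2 * (0:31), each = 32), 32, 32)
  beta <- edge_indicator(ramp, sigma = 1.5)
  expect_equal(beta[10:22, 10:22], matrix(0.2, 13, 13), tolerance = 1e-10)
  # bounded in (0, 1] on an arbitrary image
  img <- make_phantom(disk_spec(h = 64L, r = 15))$image
  b <- edge_indicator(img, 1.5)
  expect_true(all(b > 0 & b <= 1))
  expect_error(edge_indicator(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("energy terms match hand-computed and geometric oracles", {
  # phi = 2x on a 5x5 unit grid: |grad phi| = 2 everywhere -> 25 * A(2)
  phi <- matrix(rep(2 * (0:4), each = 5), 5, 5)
  expect_equal(regularization_energy(phi), 12.5)
  expect_equal(regularization_energy(matrix(3, 8, 8)), 0)
  # plane with unit slope sits in the |grad|=1 well
  plane <- matrix(rep(0:7, each = 8), 8, 8)
  expect_equal(regularization_energy(plane), 0)

  # circle signed distance: co-area length and interior area
  phi <- circle_sdf(128, 20)
  one <- matrix(1, 128, 128)
  expect_lt(abs(weighted_length(phi, one, 1.5) - 2 * pi * 20) / (2 * pi * 20),
            0.03)
  expect_lt(abs(weighted_area(phi, one, 1.5) - pi * 400) / (pi * 400), 0.03)
  # no zero crossing in the Dirac band -> zero length; constant signs -> area
  expect_equal(weighted_length(matrix(2, 16, 16), one[1:16, 1:16], 1.5), 0)
  expect_equal(weighted_area(matrix(2, 16, 16), one[1:16, 1:16], 1.5), 0)
  expect_equal(weighted_area(matrix(-2, 16, 16), one[1:16, 1:16], 1.5), 256)
  # linearity in beta
  beta <- edge_indicator(make_phantom(disk_spec())$image, 1.5)
  expect_equal(weighted_length(phi, beta / 2, 1.5),
               weighted_length(phi, beta, 1.5) / 2, tolerance = 1e-12)

  # total energy is the weighted sum of its three terms
  pars <- drlse_params(nu = 0.2, gamma = 5, mu = 1.5)
  expect_equal(total_energy(phi, beta, pars),
               0.2 * regularization_energy(phi) +
                 5 * weighted_length(phi, beta, 1.5) +
                 1.5 * weighted_area(phi, beta, 1.5), tolerance = 1e-10)
  zero <- drlse_params(nu = 1e-9, gamma = 0, mu = 0)
  expect_equal(total_energy(phi, beta, zero), 1e-9 * regularization_energy(phi))
})

test_that("parameter validation enforces the stability precondition", {
  expect_error(drlse_params(nu = 0.3, dt = 1), "1/4")
  expect_error(drlse_params(nu = -1), "nu")
  expect_silent(drlse_params(nu = 0.2, dt = 1))
})

test_that("a unit-slope plane is stationary under pure regularization", {
  phi <- matrix(rep(0:63, each = 64), 64, 64) - 30
  beta <- matrix(1, 64, 64)
  pars <- drlse_params(gamma = 0, mu = 0)
  expect_lte(max(abs(evolve_step(phi, beta, pars) - phi)), 1e-8)
})

test_that("a negative balloon force expands the interior", {
  phi <- circle_sdf(64, 8)
  beta <- matrix(1, 64, 64)
  pars <- drlse_params(nu = 0.04, gamma = 0, mu = -1.5)
  lattice <- numeric(10)
  smooth <- numeric(10)
  a0 <- sum(phi < 0)
  for (k in 1:10) {
    phi <- evolve_step(phi, beta, pars)
    lattice[k] <- sum(phi < 0)
    smooth[k] <- weighted_area(phi, beta, 1.5)
  }
  expect_true(all(diff(c(a0, lattice)) >= 0))
  expect_gt(lattice[10], a0)
  expect_true(all(diff(smooth) > 0))
})

test_that("the explicit update converges at second order in the step size", {
  h <- 64
  Y <- matrix(0:(h - 1), h, h)
  X <- t(Y)
  phi <- sqrt((Y - 31.5)^2 + (X - 31.5)^2) / 3 - 5 + 0.3 * sin(Y / 5)
  beta <- 1 / (1 + ((X - 31.5) / 20)^2)
  err <- vapply(c(0.5, 0.25), function(dt) {
    p1 <- drlse_params(nu = 0.04, gamma = 2, mu = 1, dt = dt)
    p2 <- drlse_params(nu = 0.04, gamma = 2, mu = 1, dt = 2 * dt)
    two <- evolve_step(evolve_step(phi, beta, p1), beta, p1)
    max(abs(two - evolve_step(phi, beta, p2)))
  }, numeric(1))
  # halving dt shrinks the two-step/one-step mismatch ~4x
  expect_lt(err[2] / err[1], 0.35)
})

test_that("binary initialization places the front on the seed boundary", {
  full <- initialize_binary(c(8, 8), matrix(TRUE, 8, 8), 2)
  expect_true(all(full == -2))
  empty <- initialize_binary(c(8, 8), matrix(FALSE, 8, 8), 2)
  expect_true(all(empty == 2))

  seed <- box_mask(c(64, 64), 20, 20, 43, 43)
  phi <- initialize_binary(c(64, 64), seed, 2)
  img <- matrix(100, 64, 64)
  phi1 <- evolve_step(phi, edge_indicator(img, 1.5), drlse_params())
  inside <- which(phi1[32, ] < 0)
  expect_equal(range(inside), c(21, 44))
})

test_that("segmentation recovers a disk and respects budget semantics", {
  ph <- make_phantom(disk_spec(r = 14, h = 96L))
  pars <- drlse_params(max_iter = 900, tol = 1e-4)
  seed <- box_mask(c(96, 96), 20, 20, 75, 75)
  res <- segment(ph$image, pars, seed)
  expect_gte(dice(res$mask, ph$mask), 0.95)
  expect_length(res$energy, res$iterations)
  # the distance-regularized profile holds next to the front
  expect_lte(band_gradient_deviation(res$phi, 1), 0.15)
  # energy decreases over the run as a whole
  expect_lt(res$energy[res$iterations], res$energy[1])

  # infinite tolerance: exactly one iteration, flagged as converged
  one <- segment(ph$image, drlse_params(tol = Inf), seed)
  expect_identical(one$iterations, 1L)
  # exhausted budget returns a flagged status, not an error
  short <- segment(ph$image, drlse_params(max_iter = 5, tol = 0), seed)
  expect_false(short$converged)
  expect_identical(short$iterations, 5L)
})

test_that("without edges or balloon the flat front sections stay put", {
  img <- matrix(100, 96, 96)
  pars <- drlse_params(mu = 0, max_iter = 50, tol = 0)
  res <- segment(img, pars, box_mask(c(96, 96), 30, 30, 65, 65))
  # zero-crossing scan along the central row and column (flat boundary
  # segments; corners round under curvature flow by design)
  for (line in list(res$phi[48, ], res$phi[, 48])) {
    expect_lte(abs(min(which(line < 0)) - 31), 2)
    expect_lte(abs(max(which(line < 0)) - 66), 2)
  }
})
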