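# SSD similarity, regularization energy and B-spline registration.

test_that("SSD matches its definition and a brute-force loop oracle", {
  set.seed(2)
  I <- matrix(runif(64), 8, 8)
  expect_identical(ssd_similarity(I, I), 0)
  expect_equal(ssd_similarity(I + 3, I), 9)
  J <- matrix(runif(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (I[i, j] - J[i, j])^2
  expect_equal(ssd_similarity(I, J), acc / 64, tolerance = 1e-15)
  expect_error(ssd_similarity(I, matrix(0, 4, 4)), "mismatch")
})

test_that("regularization energy is zero iff the field is spatially constant", {
  tr <- bspline_transform(c(32, 32), 5)
  expect_identical(regularization_energy(tr), 0)
  co <- tr$coef; co[, , 1] <- 4; co[, , 2] <- -2
  expect_equal(regularization_energy(bspline_transform(c(32, 32), 5, co)), 0)
})

test_that("regularization of a linear ramp matches a finite-difference quadrature oracle", {
  dims <- c(32L, 32L)
  tr <- bspline_transform(dims, 4)
  a <- 0.15
  K <- tr$n_spans
  co <- tr$coef
  co[, , 1] <- matrix(a * ((0:(K[1] + 2)) - 1) * 4, K[1] + 3, K[2] + 3)
  tr2 <- bspline_transform(dims, 4, co)
  # independent oracle: finite-difference gradient of the evaluated field,
  # averaged over the grid
  u <- bspline_map(tr2, grid_coords(dims)) - grid_coords(dims)
  ux <- matrix(u[, 1], dims[1], dims[2])
  uy <- matrix(u[, 2], dims[1], dims[2])
  oracle <- 0.5 * (sum(diff(ux)^2) + sum(t(diff(t(ux)))^2) +
                     sum(diff(uy)^2) + sum(t(diff(t(uy)))^2)) / prod(dims)
  E <- regularization_energy(tr2)
  expect_equal(E, oracle, tolerance = 1e-12)
  # analytic value for u_x = a*x per unit area: a^2/2
  expect_equal(E, 0.5 * a^2 * (dims[1] - 1) / dims[1], tolerance = 0.01)
})

test_that("objective decomposition E_obj = E_sim + lambda*E_reg holds exactly", {
  wp <- fixture_warped_pair()
  tr <- wp$true_transform
  for (lam in c(0, 0.1, 3)) {
    o <- registration_objective(wp$fixed, wp$moving, tr, lam)
    expect_identical(o$eobj, o$esim + lam * o$ereg)
    expect_equal(o$esim, ssd_similarity(wp$fixed, warp_image(wp$moving, tr)),
                 tolerance = 1e-12)
    expect_equal(o$ereg, regularization_energy(tr), tolerance = 1e-12)
  }
})

test_that("registering an image with itself returns (near) identity", {
  wp <- fixture_warped_pair()
  tr <- register_pair(wp$moving, wp$moving,
                      registration_config(n_levels = 2, max_iters = 50))
  pts <- grid_coords(dim(wp$moving))
  expect_lt(mean(row_norms(bspline_displacement(tr, pts))), 1e-3)
})

test_that("a known smooth warp (max 4 px) is recovered below half a pixel", {
  wp <- fixture_warped_pair()
  tr <- register_pair(wp$fixed, wp$moving, registration_config())
  # optimizer contract: warping reduces the SSD
  expect_lt(ssd_similarity(wp$fixed, warp_image(wp$moving, tr)),
            ssd_similarity(wp$fixed, wp$moving))
  fg <- which(wp$fixed > 0.2)
  pts <- grid_coords(dim(wp$fixed))[fg, ]
  epe <- row_norms(bspline_displacement(wp$true_transform, pts) -
                     bspline_displacement(tr, pts))
  expect_lt(mean(epe), 0.5)
})

test_that("overwhelming regularization shrinks the recovered displacement", {
  wp <- fixture_warped_pair()
  cfg_small <- registration_config(lambda = 0.1, n_levels = 2, max_iters = 60)
  cfg_huge <- registration_config(lambda = 1e6, n_levels = 2, max_iters = 60)
  tr_small <- register_pair(wp$fixed, wp$moving, cfg_small)
  tr_huge <- register_pair(wp$fixed, wp$moving, cfg_huge)
  expect_lt(mean(abs(tr_huge$coef)), 0.01 * mean(abs(tr_small$coef)))
})

test_that("SSD is intensity-scale covariant: k^2 on E_sim, argmin preserved with lambda*k^2", {
  wp <- fixture_warped_pair()
  k <- 3
  tr <- wp$true_transform
  o1 <- registration_objective(wp$fixed, wp$moving, tr, 0.1)
  o2 <- registration_objective(k * wp$fixed, k * wp$moving, tr, 0.1)
  expect_equal(o2$esim, k^2 * o1$esim, tolerance = 1e-12)
  cfg <- registration_config(lambda = 0.1, n_levels = 2, max_iters = 40)
  cfg_k <- registration_config(lambda = 0.1 * k^2, n_levels = 2, max_iters = 40)
  tr_a <- register_pair(wp$fixed, wp$moving, cfg)
  tr_b <- register_pair(k * wp$fixed, k * wp$moving, cfg_k)
  expect_equal(tr_a$coef, tr_b$coef, tolerance = 1e-6)
})

test_that("multiresolution beats a single level under the same iteration budget", {
  wp <- fixture_warped_pair()
  budget <- 120L
  multi <- register_pair(wp$fixed, wp$moving,
                         registration_config(n_levels = 4, max_iters = budget %/% 4L))
  single <- register_pair(wp$fixed, wp$moving,
                          registration_config(n_levels = 1, max_iters = budget))
  e_multi <- registration_objective(wp$fixed, wp$moving, multi, 0.1)$eobj
  e_single <- registration_objective(wp$fixed, wp$moving, single, 0.1)$eobj
  expect_lte(e_multi, e_single * (1 + 1e-8))
})
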