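# Cubic B-spline free-form deformation transform.

test_that("1-D basis weights at local parameter t = 0 are (1/6, 4/6, 1/6, 0)", {
  # recover the weights through a point evaluation: place a unit
  # coefficient on one control point at a time and evaluate at a knot
  # isolate the x-axis weights by setting a whole column of control points:
  # the partition of unity along y leaves exactly the x basis weight
  tr <- bspline_transform(c(41, 41), 5)
  w <- numeric(4)
  for (b in 1:4) {
    co <- tr$coef
    co[3 + b, , 1] <- 1   # x span of the knot at x = 15 uses storage 4..7
    w[b] <- bspline_displacement(bspline_transform(c(41, 41), 5, co),
                                 rbind(c(15, 10)))[1]
  }
  expect_equal(w, c(1 / 6, 4 / 6, 1 / 6, 0), tolerance = 1e-12)
})

test_that("zero coefficients give the identity map everywhere", {
  tr <- bspline_transform(c(30, 20, 16), 5)
  pts <- rbind(c(0, 0, 0), c(12.3, 7.7, 9.1), c(29, 19, 15))
  expect_equal(bspline_displacement(tr, pts), matrix(0, 3, 3))
  expect_equal(bspline_map(tr, pts), pts)
})

test_that("uniform coefficients translate interior points exactly (partition of unity)", {
  tr <- bspline_transform(c(40, 32), 5)
  co <- tr$coef
  co[, , 1] <- 1.75
  co[, , 2] <- -0.6
  tr2 <- bspline_transform(c(40, 32), 5, co)
  pts <- cbind(runif(20, 0, 39), runif(20, 0, 31))
  u <- bspline_displacement(tr2, pts)
  expect_equal(u[, 1], rep(1.75, 20), tolerance = 1e-12)
  expect_equal(u[, 2], rep(-0.6, 20), tolerance = 1e-12)
})

test_that("a linear displacement field is reproduced exactly", {
  tr <- bspline_transform(c(32, 32), 4)
  a <- 0.07
  K <- tr$n_spans
  pos <- ((0:(K[1] + 2)) - 1) * 4
  co <- tr$coef
  co[, , 1] <- matrix(a * pos, K[1] + 3, K[2] + 3)
  tr2 <- bspline_transform(c(32, 32), 4, co)
  pts <- cbind(c(3, 15.5, 28.2), c(4, 16, 30))
  expect_equal(bspline_displacement(tr2, pts)[, 1], a * pts[, 1],
               tolerance = 1e-12)
})

test_that("points outside the lattice support are clamped with a warning", {
  tr <- bspline_transform(c(20, 20), 5)
  co <- tr$coef; co[, , 1] <- 2
  tr2 <- bspline_transform(c(20, 20), 5, co)
  expect_warning(u <- bspline_displacement(tr2, rbind(c(-3, 10), c(25, 10))),
                 "clamped")
  expect_equal(u[, 1], c(2, 2))  # partition of unity still holds
})

test_that("dyadic lattice refinement reproduces the displacement field", {
  set.seed(31)
  tr <- bspline_transform(c(33, 33), 4)
  co <- tr$coef
  co[] <- rnorm(length(co))
  fine <- hemoflow:::crop_refined(hemoflow:::refine_lattice(co), c(33L, 33L), 2)
  trf <- bspline_transform(c(33, 33), 2, fine)
  # away from the border (end replication), subdivision is exact
  pts <- cbind(runif(30, 6, 26), runif(30, 6, 26))
  u_coarse <- bspline_displacement(bspline_transform(c(33, 33), 4, co), pts)
  u_fine <- bspline_displacement(trf, pts)
  expect_equal(u_coarse, u_fine, tolerance = 1e-10)
})

test_that("warp with the identity leaves the image unchanged; integer shifts match", {
  set.seed(8)
  J <- matrix(runif(32 * 32), 32, 32)
  tr <- bspline_transform(c(32, 32), 5)
  expect_equal(warp_image(J, tr), J)
  co <- tr$coef; co[, , 1] <- 2  # sample J at x + 2
  W <- warp_image(J, bspline_transform(c(32, 32), 5, co))
  expect_equal(W[1:30, ], J[3:32, ], tolerance = 1e-12)
})
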