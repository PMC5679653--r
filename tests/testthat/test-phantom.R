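# Synthetic phantom generator and manufactured flow cases.

test_that("beating-sphere ground truth carries the analytic ejection fraction", {
  spec <- phantom_spec("sphere", pulsation_amplitude = 0.2, n_frames = 8,
                       grid_dims = c(32, 32, 28), noise_sigma = 0, seed = 1)
  ph <- generate_beating_phantom(spec)
  # radius ratio (0.8/1.2)^3 of the extreme phases
  expect_equal(ph$truth$EF, 100 * (1 - (0.8 / 1.2)^3), tolerance = 1e-12)
  expect_equal(ph$truth$SV, ph$truth$EDV - ph$truth$ESV)
  # volume curve is periodic and strictly positive
  expect_equal(ph$truth$volume(0), ph$truth$volume(spec$period_s))
  expect_true(all(ph$truth$volumes > 0))
})

test_that("zero pulsation gives bit-identical frames, same seed gives identical output", {
  spec <- phantom_spec("disc", pulsation_amplitude = 0, n_frames = 5,
                       grid_dims = c(48, 48), noise_sigma = 0, seed = 7)
  ph <- generate_beating_phantom(spec)
  for (k in 2:5) expect_identical(ph$seq$frames[[k]], ph$seq$frames[[1]])

  spec2 <- phantom_spec("disc", noise_sigma = 0.05, n_frames = 4,
                        grid_dims = c(48, 48), seed = 42)
  a <- generate_beating_phantom(spec2)
  b <- generate_beating_phantom(spec2)
  expect_identical(a$seq$frames, b$seq$frames)
})

test_that("voxelized cavity volume tracks the analytic curve within 2%", {
  ph <- fixture_disc_phantom()
  vox <- prod(ph$truth$spec$spacing_um * 1e-4)
  for (k in c(1, 6, 11, 16)) {
    vol <- sum(ph$truth$cavity_mask(k)) * vox
    expect_lt(abs(vol - ph$truth$volumes[k]) / ph$truth$volumes[k], 0.02)
  }
})

test_that("ground-truth displacement field is periodic and zero at the template", {
  spec <- phantom_spec("ventricle2d", n_frames = 8, grid_dims = c(48, 48),
                       noise_sigma = 0, seed = 2)
  ph <- generate_beating_phantom(spec)
  pts <- rbind(c(30, 24), c(24, 40), c(10, 20))
  expect_equal(ph$truth$displacement(pts, 1), pts * 0)
  # frame 1 and a full period later coincide
  lam <- hemoflow:::phantom_lambda(spec, c(0, spec$period_s))
  expect_equal(lam[1], lam[2])
})

test_that("under-resolved wall is rejected", {
  expect_error(phantom_spec("disc", wall_thickness_vox = 1.5), "2 voxels")
})

test_that("manufactured Poiseuille flow has wall shear 4*mu*U/H", {
  ps <- generate_manufactured_flow("poiseuille2d",
                                   list(H = 2, U = 3, mu = 0.05))
  expect_equal(ps$wall_shear, 4 * 0.05 * 3 / 2)
  # differentiate the parabolic profile at the wall numerically
  eps <- 1e-6
  dudy <- (ps$velocity(rbind(c(0, eps)))[1] - ps$velocity(rbind(c(0, 0)))[1]) / eps
  expect_equal(0.05 * dudy, ps$wall_shear, tolerance = 1e-5)
  # centreline speed equals the peak velocity
  expect_equal(ps$velocity(rbind(c(0.5, 1)))[1], 3)
})

test_that("Taylor-Green fields satisfy the Navier-Stokes momentum balance", {
  nu <- 0.07; rho <- 1.3
  tg <- generate_manufactured_flow("taylor_green2d", list(nu = nu, rho = rho))
  # residual rho*(dv/dt + v.grad v) + grad p - mu lap v at sample points,
  # all derivatives by central differences
  pts <- rbind(c(0.7, 1.1), c(2.1, 0.4), c(1.3, 2.6))
  h <- 1e-5
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, ]; t <- 0.13
    dvdt <- (tg$velocity(rbind(x), t + h) - tg$velocity(rbind(x), t - h)) / (2 * h)
    dvdx <- (tg$velocity(rbind(x + c(h, 0)), t) - tg$velocity(rbind(x - c(h, 0)), t)) / (2 * h)
    dvdy <- (tg$velocity(rbind(x + c(0, h)), t) - tg$velocity(rbind(x - c(0, h)), t)) / (2 * h)
    v <- tg$velocity(rbind(x), t)
    conv <- v[1] * dvdx + v[2] * dvdy
    gradp <- c((tg$pressure(rbind(x + c(h, 0)), t) - tg$pressure(rbind(x - c(h, 0)), t)),
               (tg$pressure(rbind(x + c(0, h)), t) - tg$pressure(rbind(x - c(0, h)), t))) / (2 * h)
    lap <- (tg$velocity(rbind(x + c(h, 0)), t) + tg$velocity(rbind(x - c(h, 0)), t) +
              tg$velocity(rbind(x + c(0, h)), t) + tg$velocity(rbind(x - c(0, h)), t) -
              4 * tg$velocity(rbind(x), t)) / h^2
    resid <- rho * (dvdt + conv) + rbind(gradp) - rho * nu * lap
    expect_lt(max(abs(resid)), 1e-4)
  }
})

test_that("uniform stream has zero shear and dissipation; unknown cases fail", {
  us <- generate_manufactured_flow("uniform_stream", list(U = c(2, 0)))
  expect_equal(us$wall_shear, 0)
  expect_equal(us$dissipation, 0)
  expect_error(generate_manufactured_flow("couette9d"), "unknown")
})

test_that("image sequences round-trip through TIFF + JSON sidecar", {
  spec <- phantom_spec("disc", n_frames = 4, grid_dims = c(32, 32),
                       noise_sigma = 0.01, seed = 9)
  ph <- generate_beating_phantom(spec)
  dir <- withr::local_tempdir()
  write_image_sequence(ph$seq, dir)
  rt <- read_image_sequence(dir)
  expect_equal(rt$dims, ph$seq$dims)
  expect_equal(rt$spacing_um, ph$seq$spacing_um)
  expect_equal(rt$frame_times_s, ph$seq$frame_times_s)
  expect_equal(rt$orifice_markers, ph$seq$orifice_markers,
               ignore_attr = TRUE, tolerance = 1e-6)
  # float TIFF storage clamps to [0,1]; compare against the clamped frame
  expect_equal(rt$frames[[2]], pmin(pmax(ph$seq$frames[[2]], 0), 1),
               tolerance = 1e-6)
})
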