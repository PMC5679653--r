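# Template segmentation: threshold + enclosed-cavity extraction +
# morphological active-contour refinement.

test_that("a noise-free binary phantom segments to the exact cavity mask", {
  spec <- phantom_spec("disc", pulsation_amplitude = 0, n_frames = 4,
                       grid_dims = c(64, 64), noise_sigma = 0, seed = 1)
  ph <- generate_beating_phantom(spec)
  truth <- ph$truth$cavity_mask(1)
  # binary wall image built directly from the analytic geometry
  wall <- ph$truth$cavity_mask(1) * 0
  r0 <- spec$base_radius
  xy <- grid_coords(c(64L, 64L))
  rr <- row_norms(sweep(sweep(xy, 2, (c(64, 64) - 1) / 2, "-"), 2,
                        spec$spacing_um * 1e-4, "*"))
  img <- array(as.numeric(rr >= r0 & rr <= r0 + 3 * 0.65e-4), c(64, 64))
  mask <- segment_template(img, levelset_iters = 0)
  expect_identical(mask, array(rr < r0, c(64, 64)))
})

test_that("sphere phantom cavity volume is recovered within 2%", {
  spec <- phantom_spec("sphere", pulsation_amplitude = 0, n_frames = 4,
                       grid_dims = c(48, 48, 40), spacing_um = c(0.65, 0.65, 0.8),
                       base_radius = 1.3e-3, noise_sigma = 0, seed = 2)
  ph <- generate_beating_phantom(spec)
  mask <- segment_template(ph$seq$frames[[1]], levelset_iters = 10)
  vol <- sum(mask) * prod(spec$spacing_um * 1e-4)
  expect_lt(abs(vol - ph$truth$volumes[1]) / ph$truth$volumes[1], 0.02)
})

test_that("noisy phantom (sigma = 10% of range) still overlaps truth with Dice >= 0.95", {
  spec <- phantom_spec("ventricle2d", pulsation_amplitude = 0, n_frames = 4,
                       noise_sigma = 0.1, seed = 11)
  ph <- generate_beating_phantom(spec)
  mask <- segment_template(ph$seq$frames[[1]])
  expect_gte(dice_coefficient(mask, ph$truth$cavity_mask(1)), 0.95)
})

test_that("segmentation fails explicitly on empty foreground", {
  expect_error(segment_template(array(0, c(16, 16)) , threshold = 0.5),
               "empty foreground")
  # wall present but nothing enclosed
  img <- array(0, c(16, 16)); img[4:6, ] <- 1
  expect_error(segment_template(img, threshold = 0.5), "empty foreground")
})

test_that("template selection picks the mid-volume frame", {
  ph <- fixture_disc_phantom()
  tmpl <- select_template_frame(ph$seq)
  v <- cavity_volume_curve(ph$seq)$volume
  target <- (max(v) + min(v)) / 2
  expect_equal(abs(v[tmpl] - target), min(abs(v - target)))
})
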