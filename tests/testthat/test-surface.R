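# Watertight labeled surfaces: extraction, capping, orientation, volume.

test_that("unit-cube mask extracts to area 6 and volume 1 (scaled), watertight", {
  mask <- array(FALSE, c(24, 24, 24))
  mask[5:20, 5:20, 5:20] <- TRUE      # 16 voxels a side
  s <- extract_surface(mask, c(1, 1, 1), smooth_iters = 0)
  L <- 16 * 1e-4                       # 16 voxels at 1 um, in cm
  g <- hemoflow:::facet_geometry(s)
  expect_equal(sum(g$areas), 6 * L^2, tolerance = 0.02)
  expect_equal(volume_from_surface(s), L^3, tolerance = 0.02)
  expect_true(is_watertight(s))
})

test_that("a voxelized sphere surface has Euler characteristic 2 before capping", {
  spec <- phantom_spec("sphere", grid_dims = c(40, 40, 36),
                       spacing_um = c(0.7, 0.7, 0.8), base_radius = 1.1e-3,
                       n_frames = 4, noise_sigma = 0, seed = 3)
  ph <- generate_beating_phantom(spec)
  s <- extract_surface(ph$truth$cavity_mask(1), spec$spacing_um, smooth_iters = 2)
  expect_equal(euler_characteristic(s), 2)
  expect_true(is_watertight(s))
})

test_that("capped phantom surfaces are watertight with a disjoint label partition", {
  fx <- fixture_tracked_disc()
  s <- fx$surf_cap
  expect_true(is_watertight(s))
  want <- c("wall", "inlet_cap", "outlet_cap", "inlet_extrusion", "outlet_extrusion")
  expect_setequal(unique(s$labels), want)
  expect_identical(length(s$labels), nrow(s$facets))  # partition covers all
  # 3-D capped case: every edge shared by exactly two facets
  spec <- phantom_spec("sphere", grid_dims = c(48, 48, 40),
                       spacing_um = c(0.65, 0.65, 0.8), base_radius = 1.15e-3,
                       n_frames = 4, noise_sigma = 0, seed = 2)
  ph <- generate_beating_phantom(spec)
  s3 <- extract_surface(ph$truth$cavity_mask(1), spec$spacing_um,
                        ph$seq$orifice_markers, target_edge = 3 * 0.65e-4)
  expect_true(is_watertight(s3))
  expect_setequal(unique(s3$labels), want)
})

test_that("inward-flipped surfaces are rejected; markers off the surface fail", {
  sq <- surface_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                     rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  expect_equal(volume_from_surface(sq), 1)
  flipped <- surface_mesh(sq$vertices, sq$facets[, 2:1])
  expect_error(volume_from_surface(flipped), "inward-flipped")
  expect_equal(volume_from_surface(flipped, signed = TRUE), -1)

  mask <- array(FALSE, c(24, 24)); mask[8:16, 8:16] <- TRUE
  far <- rbind(inlet = c(1, 1), outlet = c(23, 23))
  expect_error(extract_surface(mask, c(1, 1), far), "does not lie on the surface")
})

test_that("surface divergence-theorem volume matches the volume-mesh sum within 1%", {
  s <- icosphere(3, radius = 1.2e-3)
  mesh <- mesh_interior(s)
  expect_equal(sum(element_volumes(mesh)), volume_from_surface(s),
               tolerance = 1e-12)
  # and both approximate the analytic ball volume
  expect_equal(volume_from_surface(s), 4 / 3 * pi * (1.2e-3)^3, tolerance = 0.01)
})
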