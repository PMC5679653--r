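# Simplex volume meshes, element Jacobians/quality, remeshing + transfer.

test_that("structured box mesh tessellates the unit cube exactly", {
  mesh <- mesh_box(5, 4, 3, L = c(1, 1, 1))
  expect_equal(sum(element_volumes(mesh)), 1, tolerance = 1e-12)
  expect_true(all(element_jacobian(mesh) > 0))
  expect_setequal(unique(mesh$boundary$labels),
                  c("left", "right", "bottom", "top", "back", "front"))
})

test_that("star-shaped mesher conforms to a sphere within 1% and inherits labels", {
  spec <- phantom_spec("sphere", grid_dims = c(48, 48, 40),
                       spacing_um = c(0.65, 0.65, 0.8), base_radius = 1.15e-3,
                       n_frames = 4, noise_sigma = 0, seed = 2)
  ph <- generate_beating_phantom(spec)
  s <- extract_surface(ph$truth$cavity_mask(1), spec$spacing_um,
                       ph$seq$orifice_markers, target_edge = 3.5 * 0.65e-4)
  mesh <- mesh_interior(s)
  expect_equal(sum(element_volumes(mesh)), volume_from_surface(s),
               tolerance = 1e-10)
  # boundary facets mirror the surface facets and labels exactly
  expect_identical(mesh$boundary$faces, s$facets)
  expect_identical(mesh$boundary$labels, s$labels)
  expect_true(all(element_jacobian(mesh) > 0))
})

test_that("element Jacobian is positive, sign-flips on vertex swap, zero when degenerate", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_gt(element_jacobian(rbind(c(1, 2, 3, 4)), nodes = nodes), 0)
  expect_lt(element_jacobian(rbind(c(1, 3, 2, 4)), nodes = nodes), 0)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.4, 0))
  expect_equal(element_jacobian(rbind(c(1, 2, 3, 4)), nodes = flat), 0)
  # equal magnitude under the swap
  expect_equal(abs(element_jacobian(rbind(c(1, 3, 2, 4)), nodes = nodes)),
               element_jacobian(rbind(c(1, 2, 3, 4)), nodes = nodes))
})

test_that("remesh transfer reproduces linear and constant fields and preserves volume", {
  fx <- fixture_tracked_disc()
  mesh <- mesh_interior(fx$surf_cap, target_edge = fx$h)
  # deform: nonuniform radial stretch of the whole mesh
  ctr <- colMeans(mesh$nodes[seq_len(mesh$surf_nv), ])
  off <- sweep(mesh$nodes, 2, ctr, "-")
  mesh$nodes <- sweep(off * (1 + 0.08 * off[, 1] / max(abs(off[, 1]))), 2, ctr, "+")
  lin <- 2 * mesh$nodes[, 1] - 3 * mesh$nodes[, 2] + 0.5e-3
  const <- rep(4.2, nrow(mesh$nodes))
  vel <- cbind(lin, -lin)
  V_before <- sum(element_volumes(mesh))
  rt <- remesh_and_transfer(mesh, fields = list(lin = lin, const = const, v = vel))
  new_lin <- 2 * rt$mesh$nodes[, 1] - 3 * rt$mesh$nodes[, 2] + 0.5e-3
  expect_equal(rt$fields$lin, new_lin, tolerance = 1e-9)
  expect_equal(rt$fields$const, rep(4.2, nrow(rt$mesh$nodes)))
  expect_equal(rt$fields$v[, 1], new_lin, tolerance = 1e-9)
  V_after <- sum(element_volumes(rt$mesh))
  expect_lt(abs(V_after - V_before) / V_before, 0.01)
  # boundary labels preserved
  expect_identical(rt$mesh$boundary$labels, mesh$boundary$labels)
})

test_that("field interpolation falls back to nearest-element projection outside the mesh", {
  mesh <- mesh_rectangle(4, 4, 1, 1)
  fld <- list(f = mesh$nodes[, 1])
  out <- interpolate_fields(mesh, rbind(c(0.5, 0.5), c(2, 0.5)), fld)
  expect_equal(out$n_outside, 1L)
  expect_equal(out$fields$f[1], 0.5, tolerance = 1e-12)
  expect_equal(out$fields$f[2], 1, tolerance = 1e-9)  # clamped to the right edge
})
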