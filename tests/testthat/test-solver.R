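# Generalized-alpha ALE stepping, linear solvers, mesh motion, phase
# switching and the cycle driver.

test_that("Jacobi-GMRES reproduces the direct solution of an assembled system", {
  res <- run_taylor_green(8, 2, Tend = 0.02)
  mesh <- res$mesh
  n <- nrow(mesh$nodes)
  cfg <- solver_config(rho = 1, mu = 0.05, dt = 0.01)
  asm <- assemble_vms(mesh, res$state$v, res$state$vdot, res$state$p,
                      config = cfg, cm = 1, cv = 1)
  set.seed(3)
  b <- rnorm(n * 3)
  xg <- gmres_solve(asm$tangent, b, tol = 1e-10, restart = 200)
  xd <- as.vector(Matrix::solve(asm$tangent, b))
  expect_true(xg$converged)
  expect_equal(xg$x, xd, tolerance = 1e-6)
})

test_that("steady Poiseuille flow is a fixed point and reproduces 4*mu*U/H wall shear", {
  ps <- generate_manufactured_flow("poiseuille2d",
                                   list(H = 1, L = 1, U = 1, mu = 0.05, rho = 1))
  mesh <- mesh_rectangle(12, 48, 1, 1)
  cfg <- solver_config(rho = 1, mu = 0.05, dt = 0.05, linear_solver = "direct",
                       newton_tol = 1e-12, newton_max = 20)
  bcs <- boundary_spec(
    dirichlet = list(left = function(x, t) ps$velocity(x, t),
                     bottom = 0, top = 0),
    neumann = list(right = 0), beta = 0.3)
  st <- flow_state_rest(mesh)
  st$v <- ps$velocity(mesh$nodes, 0)
  res <- simulate_flow(mesh, bcs, cfg, n_steps = 60, init = st)
  nxt <- advance_generalized_alpha(res$state, res$mesh, bcs, cfg)
  chg <- sqrt(sum((nxt$state$v - res$state$v)^2)) / sqrt(sum(res$state$v^2))
  expect_lt(chg, 1e-8)
  # wall shear away from the traction-free outlet (entrance-length free)
  w <- wall_shear_stress(res$state$v, res$mesh, 0.05)
  g <- hemoflow:::facet_geometry(surface_mesh(res$mesh$nodes,
                                              res$mesh$boundary$faces,
                                              res$mesh$boundary$labels))
  sel <- w$labels %in% c("bottom", "top") & g$centroids[, 1] < 0.6
  tw <- row_norms(w$vectors[sel, , drop = FALSE])
  expect_lt(abs(mean(tw) - ps$wall_shear) / ps$wall_shear, 0.03)
})

test_that("temporal accuracy is second order (Richardson sweep in dt)", {
  v1 <- run_taylor_green(24, 2, newton_tol = 1e-8)$state$v
  v2 <- run_taylor_green(24, 4, newton_tol = 1e-8)$state$v
  v3 <- run_taylor_green(24, 8, newton_tol = 1e-8)$state$v
  d1 <- sqrt(sum((v1 - v2)^2))
  d2 <- sqrt(sum((v2 - v3)^2))
  expect_gte(log2(d1 / d2), 1.8)
})

test_that("discrete kinetic energy is non-increasing for unforced Stokes flow", {
  tg <- generate_manufactured_flow("taylor_green2d", list(nu = 0.05, rho = 1))
  mesh <- mesh_rectangle(12, 12, pi, pi)
  cfg <- solver_config(rho = 1, mu = 0.2, dt = 0.02, linear_solver = "direct")
  bcs <- boundary_spec(dirichlet = list(left = 0, right = 0, bottom = 0, top = 0),
                       pin_pressure = 1L)
  st <- flow_state_rest(mesh)
  st$v <- tg$velocity(mesh$nodes, 0)
  st$v[unique(as.vector(mesh$boundary$faces)), ] <- 0
  ke <- numeric(25)
  for (s in 1:25) {
    st <- advance_generalized_alpha(st, mesh, bcs, cfg)$state
    ke[s] <- energy_metrics(st$v, mesh, 1, 0.2)$ke
  }
  expect_true(all(diff(ke) <= 1e-12))
})

test_that("backflow stabilization keeps a reversed jet bounded over 200 steps", {
  mesh <- mesh_rectangle(10, 10, 1, 1)
  cfg <- solver_config(rho = 1, mu = 0.01, dt = 0.01, beta = 0.3,
                       linear_solver = "direct")
  # suction through the Neumann boundary: the flow enters against the
  # outward normal, which is exactly the destabilizing configuration
  bcs <- boundary_spec(dirichlet = list(left = c(-0.5, 0), bottom = 0, top = 0),
                       neumann = list(right = 0), beta = 0.3)
  st <- flow_state_rest(mesh)
  kes <- numeric(200)
  for (s in 1:200) {
    st <- advance_generalized_alpha(st, mesh, bcs, cfg)$state
    kes[s] <- energy_metrics(st$v, mesh, 1, 0.01)$ke
  }
  expect_true(all(is.finite(kes)))
  expect_lt(max(kes), 10)
})

test_that("mesh motion: rigid translation propagates exactly, zero stays zero", {
  fx <- fixture_capped_disc()
  mesh <- fx$mesh
  nv <- mesh$surf_nv
  shift <- c(2e-4, -1e-4)
  mm <- solve_mesh_motion(mesh, matrix(shift, nv, 2, byrow = TRUE),
                          nodes = seq_len(nv))
  expect_equal(mm$disp, matrix(shift, nrow(mesh$nodes), 2, byrow = TRUE),
               tolerance = 1e-9)
  mm0 <- solve_mesh_motion(mesh, matrix(0, nv, 2), nodes = seq_len(nv))
  expect_equal(max(abs(mm0$disp)), 0, tolerance = 1e-12)
})

test_that("Jacobian stiffening keeps quality at least as good as the unstiffened solve", {
  fx <- fixture_capped_disc()
  mesh <- fx$mesh
  nv <- mesh$surf_nv
  ctr <- colMeans(mesh$ref_nodes[seq_len(nv), ])
  infl <- sweep(sweep(mesh$ref_nodes[seq_len(nv), ], 2, ctr, "-") * 1.05,
                2, ctr, "+") - mesh$ref_nodes[seq_len(nv), ]
  m1 <- solve_mesh_motion(mesh, infl, nodes = seq_len(nv), chi = 1)
  m0 <- solve_mesh_motion(mesh, infl, nodes = seq_len(nv), chi = 0)
  expect_gt(m1$min_jacobian, 0)
  q1 <- min(hemoflow:::element_quality(m1$new_nodes, mesh$elems))
  q0 <- min(hemoflow:::element_quality(m0$new_nodes, mesh$elems))
  expect_gte(q1, q0 - 1e-9)
})

test_that("phase switching follows the sign of dV/dt with upcoming-phase ties", {
  vs <- tibble::tibble(t = seq(0, 0.35, by = 0.05),
                       volume = c(1, 1.2, 1.4, 1.5, 1.4, 1.2, 1.0, 0.9))
  rising <- phase_switch_bcs(vs, 0.07, period = 0.4)
  expect_identical(rising$phase, "diastole")
  expect_identical(rising$neumann, "inlet_cap")
  expect_identical(rising$dirichlet, "outlet_cap")
  falling <- phase_switch_bcs(vs, 0.27, period = 0.4)
  expect_identical(falling$phase, "systole")
  expect_identical(falling$neumann, "outlet_cap")
  # plateau: dV/dt = 0 on [0.10, 0.15); the upcoming interval is falling
  vs2 <- tibble::tibble(t = seq(0, 0.35, by = 0.05),
                        volume = c(1, 1.2, 1.4, 1.4, 1.2, 1.1, 1.0, 0.9))
  tie <- phase_switch_bcs(vs2, 0.12, period = 0.4)
  expect_identical(tie$phase, "systole")
})

test_that("zero wall motion and zero inflow keep the fluid exactly at rest", {
  fx <- fixture_capped_disc()
  motion <- make_synthetic_motion(fx$surf, M = 4, amplitude = 0)
  cfg <- solver_config(dt = 0.05, n_cycles = 2, linear_solver = "direct")
  series <- run_cycle_simulation(motion, fx$mesh, cfg)
  vmax <- max(vapply(series$snapshots, function(sn) max(abs(sn$v)), numeric(1)))
  expect_equal(vmax, 0)
})

test_that("a 0.3-amplitude pulsation completes all cycles and triggers remeshing", {
  fx <- fixture_capped_disc()
  motion <- make_synthetic_motion(fx$surf, M = 8, amplitude = 0.3)
  cfg <- solver_config(dt = 0.4 / 16, n_cycles = 2, linear_solver = "direct")
  series <- run_cycle_simulation(motion, fx$mesh, cfg)
  expect_identical(length(series$snapshots), 16L)
  expect_gte(series$n_remesh, 1L)
  # global mass conservation at every output step
  expect_lt(max(series$log$mass_residual), 1e-2)
})
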