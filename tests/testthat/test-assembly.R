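# VMS assembly: consistency against a dense independent oracle, exactness of
# the tangent, and residual consistency on the manufactured solution.

two_elem_mesh_2d <- function() {
  nodes <- rbind(c(0, 0), c(1, 0), c(1.1, 1), c(0, 0.9))
  elems <- rbind(c(1, 2, 3), c(1, 3, 4))
  faces <- hemoflow:::boundary_faces_of(elems, 2L)
  flow_mesh(nodes, elems, faces, rep("wall", nrow(faces)))
}

two_elem_mesh_3d <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.1, 0.2, 1), c(1, 1, 0.2))
  elems <- rbind(c(1, 2, 3, 4), c(2, 5, 3, 4))
  elems <- hemoflow:::fix_orientation(nodes, elems)
  faces <- hemoflow:::boundary_faces_of(elems, 3L)
  flow_mesh(nodes, elems, faces, rep("wall", nrow(faces)))
}

test_that("uniform velocity with zero pressure gives zero residual (r_M = r_C = 0)", {
  for (mesh in list(two_elem_mesh_2d(), two_elem_mesh_3d())) {
    d <- mesh$d
    n <- nrow(mesh$nodes)
    v <- matrix(rep(seq_len(d), each = n), n, d)
    out <- assemble_vms(mesh, v, 0 * v, numeric(n), config = solver_config(),
                        want_tangent = FALSE)
    expect_lt(max(abs(out$residual)), 1e-12)
  }
})

test_that("assembled residual matches the dense element-by-element oracle", {
  set.seed(12)
  for (mesh in list(two_elem_mesh_2d(), two_elem_mesh_3d())) {
    d <- mesh$d
    n <- nrow(mesh$nodes)
    v <- matrix(rnorm(n * d), n, d)
    vdot <- matrix(rnorm(n * d), n, d)
    vhat <- matrix(rnorm(n * d), n, d)
    p <- rnorm(n)
    cfg <- solver_config(rho = 1.3, mu = 0.07, fb = c(0.2, -0.1, 0.3)[1:d],
                         dt = 0.02)
    out <- assemble_vms(mesh, v, vdot, p, vhat, cfg, want_tangent = FALSE)
    oracle <- oracle_vms_residual(mesh, v, vdot, p, vhat, rho = 1.3, mu = 0.07,
                                  fb = c(0.2, -0.1, 0.3)[1:d], dt = 0.02)
    expect_equal(out$residual, oracle, tolerance = 1e-13)
  }
})

test_that("the assembled tangent matches a finite-difference Jacobian to 1e-6", {
  # evaluated where the modified-Newton omissions vanish identically:
  # v = vhat uniform and r_M = 0
  mesh <- two_elem_mesh_2d()
  n <- nrow(mesh$nodes)
  cfg <- solver_config(rho = 1.2, mu = 0.03, dt = 0.01)
  v <- matrix(rep(c(2, 1), each = n), n, 2)
  vhat <- v
  vd <- matrix(0, n, 2)
  p <- numeric(n)
  ga <- hemoflow:::gen_alpha_params(0.5)
  cm <- ga$alpha_m; cv <- ga$alpha_f * ga$gamma * cfg$dt
  K <- as.matrix(assemble_vms(mesh, v, vd, p, vhat, cfg,
                              cm = cm, cv = cv)$tangent)
  ndof <- n * 3
  eps <- 1e-6
  Kfd <- matrix(0, ndof, ndof)
  for (j in seq_len(ndof)) {
    node <- (j - 1) %/% 3 + 1
    comp <- (j - 1) %% 3 + 1
    pert <- function(sgn) {
      v2 <- v; vd2 <- vd; p2 <- p
      if (comp <= 2) {
        vd2[node, comp] <- vd2[node, comp] + sgn * cm * eps
        v2[node, comp] <- v2[node, comp] + sgn * cv * eps
      } else p2[node] <- p2[node] + sgn * eps
      assemble_vms(mesh, v2, vd2, p2, vhat, cfg, cm = cm, cv = cv,
                   want_tangent = FALSE)$residual
    }
    Kfd[, j] <- (pert(1) - pert(-1)) / (2 * eps)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(Kfd)), 1e-6)
})

test_that("interior momentum residual of injected Taylor-Green fields vanishes at O(h) or better", {
  tg <- generate_manufactured_flow("taylor_green2d", list(nu = 0.05, rho = 1))
  resnorm <- function(m) {
    mesh <- mesh_rectangle(m, m, pi, pi)
    cfg <- solver_config(rho = 1, mu = 0.05, dt = 1e9)
    v <- tg$velocity(mesh$nodes, 0)
    vd <- -2 * 0.05 * v          # exact dv/dt of the decaying vortex
    p <- tg$pressure(mesh$nodes, 0)
    out <- assemble_vms(mesh, v, vd, p, config = cfg, want_tangent = FALSE)
    R <- matrix(out$residual, ncol = 3, byrow = TRUE)
    interior <- setdiff(seq_len(nrow(mesh$nodes)),
                        unique(as.vector(mesh$boundary$faces)))
    sqrt(sum(R[interior, 1:2]^2) / length(interior))
  }
  e <- vapply(c(8, 16, 32), resnorm, numeric(1))
  rates <- log2(e[-3] / e[-1])
  expect_true(all(rates >= 0.9))
})

test_that("non-finite states are rejected with diagnostics", {
  mesh <- two_elem_mesh_2d()
  n <- nrow(mesh$nodes)
  v <- matrix(0, n, 2); v[2, 1] <- NaN
  expect_error(assemble_vms(mesh, v, 0 * v, numeric(n), config = solver_config()),
               "non-finite residual")
})
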