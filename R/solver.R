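# Moving-domain incompressible Navier-Stokes solver: solver configuration,
# boundary conditions, VMS assembly wrapper, Jacobi-preconditioned GMRES,
# and the generalized-alpha implicit time stepper (modified Newton,
# quasi-direct mesh coupling).

#' Solver configuration
#'
#' Defaults follow embryonic-zebrafish blood properties: density 1.06 g/cm^3
#' and viscosity 4 cP (0.04 g/(cm s)), time step 0.2 ms, backflow
#' coefficient 0.3, and 4 simulated cardiac cycles with the first discarded
#' from averaging.  `viscosity_scale` rescales viscosity (0.25 models the
#' reduced-hematocrit case).
#'
#' @param rho density (g/cm^3).
#' @param mu dynamic viscosity (g/(cm s)).
#' @param fb body force per unit volume (vector, recycled to dimension).
#' @param dt time step (s).
#' @param beta backflow stabilization coefficient in `[0, 1]`.
#' @param Ct,CI stabilization constants (standard linear-element values).
#' @param rho_inf generalized-alpha spectral radius in `[0, 1]`.
#' @param newton_tol,newton_max relative Newton tolerance and max iterations.
#' @param gmres_tol,gmres_restart,gmres_max_restarts GMRES controls.
#' @param linear_solver `"gmres"` (Jacobi-preconditioned) or `"direct"`.
#' @param n_cycles number of cardiac cycles to simulate.
#' @param viscosity_scale multiplier on `mu` (1 = baseline).
#' @param chi Jacobian-based stiffening exponent for mesh motion.
#' @param remesh_quality_floor scaled-Jacobian floor triggering a remesh.
#' @param remesh_disp_factor boundary-displacement remesh trigger, in units
#'   of the mesh target edge length.
#' @return a `solver_config`.
#' @export
solver_config <- function(rho = 1.06, mu = 0.04, fb = 0, dt = 2e-4,
                          beta = 0.3, Ct = 4, CI = 36, rho_inf = 0.5,
                          newton_tol = 1e-4, newton_max = 10L,
                          gmres_tol = 1e-6, gmres_restart = 200L,
                          gmres_max_restarts = 10L,
                          linear_solver = c("gmres", "direct"),
                          n_cycles = 4L, viscosity_scale = 1,
                          chi = 1, remesh_quality_floor = 0.05,
                          remesh_disp_factor = 1) {
  assert_that(rho > 0 && mu > 0 && dt > 0, "rho, mu and dt must be positive")
  assert_that(beta >= 0 && beta <= 1, "beta must lie in [0, 1]")
  assert_that(rho_inf >= 0 && rho_inf <= 1, "rho_inf must lie in [0, 1]")
  structure(list(rho = rho, mu = mu, fb = fb, dt = dt, beta = beta,
                 Ct = Ct, CI = CI, rho_inf = rho_inf,
                 newton_tol = newton_tol, newton_max = as.integer(newton_max),
                 gmres_tol = gmres_tol, gmres_restart = as.integer(gmres_restart),
                 gmres_max_restarts = as.integer(gmres_max_restarts),
                 linear_solver = match.arg(linear_solver),
                 n_cycles = as.integer(n_cycles),
                 viscosity_scale = viscosity_scale, chi = chi,
                 remesh_quality_floor = remesh_quality_floor,
                 remesh_disp_factor = remesh_disp_factor),
            class = "solver_config")
}

# generalized-alpha parameters for a first-order system
gen_alpha_params <- function(rho_inf) {
  am <- 0.5 * (3 - rho_inf) / (1 + rho_inf)
  af <- 1 / (1 + rho_inf)
  list(alpha_m = am, alpha_f = af, gamma = 0.5 + am - af)
}

#' Boundary conditions for the flow solver
#'
#' Dirichlet entries prescribe velocity on all nodes of facets carrying the
#' label (a constant vector, or `function(x, t)` returning one row per
#' node); entries listed later override earlier ones on shared nodes.
#' Neumann entries prescribe a boundary traction (constant vector or
#' function), plus backflow stabilization with coefficient `beta`.
#' `moving_labels` marks labels whose velocity is taken from the mesh
#' motion (the tracked wall).
#'
#' @param dirichlet named list, label -> value.
#' @param neumann named list, label -> traction.
#' @param beta backflow coefficient.
#' @param pin_pressure node index whose pressure is pinned (use for fully
#'   Dirichlet problems), or `NA`.
#' @param moving_labels labels whose Dirichlet value is the wall velocity.
#' @return a `boundary_spec`.
#' @export
boundary_spec <- function(dirichlet = list(), neumann = list(), beta = 0.3,
                          pin_pressure = NA_integer_,
                          moving_labels = character(0)) {
  overlap <- intersect(names(dirichlet), names(neumann))
  assert_that(length(overlap) == 0,
              "labels cannot be both Dirichlet and Neumann: %s",
              paste(overlap, collapse = ", "))
  structure(list(dirichlet = dirichlet, neumann = neumann, beta = beta,
                 pin_pressure = pin_pressure, moving_labels = moving_labels),
            class = "boundary_spec")
}

# nodes of all boundary facets carrying any of the given labels
label_nodes <- function(mesh, labels) {
  sel <- mesh$boundary$labels %in% labels
  sort(unique(as.vector(mesh$boundary$faces[sel, , drop = FALSE])))
}

# resolve Dirichlet node ids and values at time t; `vhat` supplies values
# for moving labels
resolve_dirichlet <- function(bcs, mesh, t, vhat = NULL) {
  d <- mesh$d
  nodes <- integer(0)
  vals <- matrix(0, 0, d)
  add <- function(ids, vv) {
    keep <- !(nodes %in% ids)
    nodes <<- c(nodes[keep], ids)
    vals <<- rbind(vals[keep, , drop = FALSE], vv)
  }
  for (lab in names(bcs$dirichlet)) {
    ids <- label_nodes(mesh, lab)
    if (!length(ids)) next
    val <- bcs$dirichlet[[lab]]
    vv <- if (is.function(val)) {
      out <- val(mesh$nodes[ids, , drop = FALSE], t)
      matrix(out, length(ids), d)
    } else matrix(val, length(ids), d, byrow = length(val) == d)
    add(ids, vv)
  }
  if (length(bcs$moving_labels) && !is.null(vhat)) {
    ids <- label_nodes(mesh, bcs$moving_labels)
    if (length(ids)) add(ids, vhat[ids, , drop = FALSE])
  }
  list(nodes = nodes, values = vals)
}

# Neumann faces (indices into boundary faces) and per-face tractions at t
resolve_neumann <- function(bcs, mesh, t) {
  d <- mesh$d
  sel <- which(mesh$boundary$labels %in% names(bcs$neumann))
  if (!length(sel)) return(NULL)
  faces <- mesh$boundary$faces[sel, , drop = FALSE]
  trac <- matrix(0, length(sel), d)
  g <- facet_geometry(surface_mesh(mesh$nodes, faces,
                                   rep("x", nrow(faces))))
  for (lab in names(bcs$neumann)) {
    rows <- which(mesh$boundary$labels[sel] == lab)
    if (!length(rows)) next
    val <- bcs$neumann[[lab]]
    trac[rows, ] <- if (is.function(val))
      matrix(val(g$centroids[rows, , drop = FALSE], t), length(rows), d)
    else matrix(val, length(rows), d, byrow = length(val) == d)
  }
  list(faces = faces, traction = trac)
}

#' Assemble the VMS residual and tangent
#'
#' Global residual of the stabilized ALE weak form (interior + Neumann and
#' backflow boundary terms) with a consistent modified-Newton tangent.
#' `cm` and `cv` are the generalized-alpha factors relating the unknown
#' acceleration increments to the evaluated rate and velocity
#' (`cm = alpha_m`, `cv = alpha_f * gamma * dt`); unity gives the plain
#' Jacobians with respect to `vdot` frozen and `v` free.
#'
#' @param mesh a `flow_mesh` (geometry at the evaluation configuration).
#' @param v,vdot nodal velocity and acceleration (n x d) at the evaluation
#'   state.
#' @param p nodal pressure.
#' @param vhat nodal mesh velocity (n x d); zero for a static mesh.
#' @param config a [solver_config()].
#' @param bcs optional [boundary_spec()] for Neumann/backflow terms.
#' @param t time (passed to traction functions).
#' @param cm,cv tangent combination factors.
#' @param want_tangent assemble the sparse tangent matrix.
#' @return list with `residual`, `tangent` (dgCMatrix or `NULL`).
#' @export
assemble_vms <- function(mesh, v, vdot, p, vhat = NULL, config = solver_config(),
                         bcs = NULL, t = 0, cm = 1, cv = 1,
                         want_tangent = TRUE) {
  d <- mesh$d
  n <- nrow(mesh$nodes)
  if (is.null(vhat)) vhat <- matrix(0, n, d)
  mu_eff <- config$mu * config$viscosity_scale
  fb <- rep(config$fb, length.out = d)
  out <- assemble_vms_cpp(mesh$nodes, mesh$elems - 1L, v, vdot, p, vhat,
                          config$rho, mu_eff, fb, config$dt,
                          config$Ct, config$CI, cm, cv, want_tangent)
  if (out$n_bad_elements > 0)
    stop_hf("assembly failed: %d element(s) with non-positive Jacobian",
            out$n_bad_elements)
  R <- out$residual
  trip <- if (want_tangent) list(i = out$i, j = out$j, x = out$x)
  if (!is.null(bcs)) {
    nm <- resolve_neumann(bcs, mesh, t)
    if (!is.null(nm)) {
      bout <- assemble_boundary_cpp(mesh$nodes, nm$faces - 1L, nm$traction,
                                    v, config$rho, bcs$beta, cv, want_tangent)
      R <- R + bout$residual
      if (want_tangent && length(bout$i)) {
        trip$i <- c(trip$i, bout$i)
        trip$j <- c(trip$j, bout$j)
        trip$x <- c(trip$x, bout$x)
      }
    }
  }
  if (!all(is.finite(R))) {
    bad <- which(!is.finite(R))
    stop_hf("non-finite residual in %d dof(s); first at node %d",
            length(bad), (bad[1] - 1) %/% (d + 1) + 1)
  }
  K <- NULL
  if (want_tangent)
    K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(n * (d + 1), n * (d + 1)))
  list(residual = R, tangent = K)
}

#' Restarted GMRES with Jacobi (diagonal) preconditioning
#'
#' @param A sparse system matrix.
#' @param b right-hand side.
#' @param x0 initial guess (zero if `NULL`).
#' @param tol relative residual tolerance (in the preconditioned norm).
#' @param restart Krylov subspace size per cycle.
#' @param max_restarts maximum restart cycles.
#' @return list with `x`, `iters`, `converged`, `relres`.
#' @export
gmres_solve <- function(A, b, x0 = NULL, tol = 1e-6, restart = 200L,
                        max_restarts = 10L) {
  n <- length(b)
  Di <- Matrix::diag(A)
  Di[Di == 0 | !is.finite(Di)] <- 1
  Dinv <- 1 / Di
  x <- x0 %||% numeric(n)
  bn <- sqrt(sum((Dinv * b)^2))
  if (bn == 0) return(list(x = numeric(n), iters = 0L, converged = TRUE, relres = 0))
  iters <- 0L
  for (outer in seq_len(max_restarts)) {
    r <- Dinv * (b - as.vector(A %*% x))
    beta <- sqrt(sum(r^2))
    if (beta / bn < tol)
      return(list(x = x, iters = iters, converged = TRUE, relres = beta / bn))
    m <- min(restart, n)
    V <- matrix(0, n, m + 1)
    H <- matrix(0, m + 1, m)
    cs <- numeric(m); sn <- numeric(m); g <- numeric(m + 1)
    V[, 1] <- r / beta
    g[1] <- beta
    relres <- beta / bn
    j_used <- 0L
    for (j in seq_len(m)) {
      w <- Dinv * as.vector(A %*% V[, j])
      h <- crossprod(V[, seq_len(j), drop = FALSE], w)[, 1]
      w <- w - V[, seq_len(j), drop = FALSE] %*% h
      H[seq_len(j), j] <- h
      H[j + 1, j] <- sqrt(sum(w^2))
      happy <- H[j + 1, j] < 1e-30
      if (!happy) V[, j + 1] <- as.vector(w) / H[j + 1, j]
      for (i in seq_len(j - 1)) {
        tmp <- cs[i] * H[i, j] + sn[i] * H[i + 1, j]
        H[i + 1, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1, j]
        H[i, j] <- tmp
      }
      dnm <- sqrt(H[j, j]^2 + H[j + 1, j]^2)
      cs[j] <- H[j, j] / dnm; sn[j] <- H[j + 1, j] / dnm
      H[j, j] <- dnm; H[j + 1, j] <- 0
      g[j + 1] <- -sn[j] * g[j]
      g[j] <- cs[j] * g[j]
      iters <- iters + 1L
      relres <- abs(g[j + 1]) / bn
      j_used <- j
      if (relres < tol || happy) break
    }
    y <- backsolve(H[seq_len(j_used), seq_len(j_used), drop = FALSE], g[seq_len(j_used)])
    x <- x + as.vector(V[, seq_len(j_used), drop = FALSE] %*% y)
    if (relres < tol)
      return(list(x = x, iters = iters, converged = TRUE, relres = relres))
  }
  warning(sprintf("GMRES did not converge (relres %.2e)", relres), call. = FALSE)
  list(x = x, iters = iters, converged = FALSE, relres = relres)
}

linear_solve <- function(A, b, config) {
  if (config$linear_solver == "direct") {
    # symmetric diagonal equilibration: momentum and continuity rows differ
    # by many orders of magnitude in CGS units at micrometre scale
    dg <- abs(Matrix::diag(A))
    dg[dg == 0 | !is.finite(dg)] <- 1
    s <- 1 / sqrt(dg)
    As <- Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
    as.vector(s * Matrix::solve(As, s * b))
  } else {
    gmres_solve(A, b, tol = config$gmres_tol, restart = config$gmres_restart,
                max_restarts = config$gmres_max_restarts)$x
  }
}

#' Initial (rest) flow state
#' @param mesh a `flow_mesh`.
#' @param t initial time.
#' @return a `flow_state` with zero velocity, acceleration and pressure.
#' @export
flow_state_rest <- function(mesh, t = 0) {
  n <- nrow(mesh$nodes)
  structure(list(v = matrix(0, n, mesh$d), vdot = matrix(0, n, mesh$d),
                 p = numeric(n), t = t,
                 vhat = matrix(0, n, mesh$d)),
            class = "flow_state")
}

#' Advance the flow one implicit generalized-alpha step
#'
#' One time step of the VMS-stabilized ALE Navier-Stokes system: predictor,
#' modified-Newton corrections to a relative residual tolerance, linear
#' solves by Jacobi-preconditioned GMRES.  When `target_nodes` is given the
#' mesh motion (already solved, quasi-direct) enters through the moved
#' geometry and the mesh velocity `vhat = (x1 - x0)/dt`.
#'
#' @param state a `flow_state` at time t.
#' @param mesh the `flow_mesh` at time t.
#' @param bcs a [boundary_spec()].
#' @param config a [solver_config()].
#' @param target_nodes node coordinates at t + dt (`NULL` for a static mesh).
#' @param dt time step override (defaults to `config$dt`).
#' @return list with `state` (at t + dt), `nodes` (mesh nodes at t + dt),
#'   `newton_iters`, `res0`, `res`.
#' @export
advance_generalized_alpha <- function(state, mesh, bcs, config,
                                      target_nodes = NULL, dt = NULL) {
  d <- mesh$d
  n <- nrow(mesh$nodes)
  dt <- dt %||% config$dt
  ga <- gen_alpha_params(config$rho_inf)
  am <- ga$alpha_m; af <- ga$alpha_f; gam <- ga$gamma

  x0 <- mesh$nodes
  x1 <- target_nodes %||% x0
  moving <- !is.null(target_nodes)
  vhat <- (x1 - x0) / dt

  v0 <- state$v; vd0 <- state$vdot; p0 <- state$p
  # predictor (same-velocity)
  vd1 <- (gam - 1) / gam * vd0
  v1 <- v0
  p1 <- p0

  dir <- resolve_dirichlet(bcs, structure(list(nodes = x1, d = d,
                                               boundary = mesh$boundary),
                                          class = "flow_mesh"),
                           state$t + dt, vhat = vhat)
  set_dirichlet <- function(v1, vd1) {
    if (length(dir$nodes)) {
      v1[dir$nodes, ] <- dir$values
      vd1[dir$nodes, ] <- (v1[dir$nodes, , drop = FALSE] - v0[dir$nodes, , drop = FALSE]) / (gam * dt) +
        (1 - 1 / gam) * vd0[dir$nodes, , drop = FALSE]
    }
    list(v1 = v1, vd1 = vd1)
  }
  sd <- set_dirichlet(v1, vd1)
  v1 <- sd$v1; vd1 <- sd$vd1

  ndof <- n * (d + 1)
  dir_dofs <- if (length(dir$nodes))
    as.vector(outer(0:(d - 1), (dir$nodes - 1) * (d + 1), "+")) + 1L else integer(0)
  if (!is.na(bcs$pin_pressure))
    dir_dofs <- c(dir_dofs, (bcs$pin_pressure - 1L) * (d + 1L) + d + 1L)
  free <- setdiff(seq_len(ndof), dir_dofs)

  res0 <- NA_real_
  res <- NA_real_
  iters <- 0L
  for (it in seq_len(config$newton_max)) {
    vm <- vd0 + am * (vd1 - vd0)
    vf <- v0 + af * (v1 - v0)
    xf <- x0 + af * (x1 - x0)
    emesh <- mesh
    emesh$nodes <- xf
    cfg_dt <- config; cfg_dt$dt <- dt
    asm <- assemble_vms(emesh, vf, vm, p1, vhat, cfg_dt, bcs = bcs,
                        t = state$t + af * dt, cm = am, cv = af * gam * dt,
                        want_tangent = TRUE)
    R <- asm$residual
    R[dir_dofs] <- 0
    res <- sqrt(sum(R^2))
    if (it == 1L) res0 <- res
    if (res <= config$newton_tol * max(res0, 1e-300) || res < 1e-13) break
    K <- asm$tangent
    if (length(dir_dofs)) {
      K[dir_dofs, ] <- 0
      K[cbind(dir_dofs, dir_dofs)] <- 1
    }
    delta <- linear_solve(K, -R, config)
    dmat <- matrix(delta, ncol = d + 1, byrow = TRUE)
    vd1 <- vd1 + dmat[, seq_len(d), drop = FALSE]
    v1 <- v1 + gam * dt * dmat[, seq_len(d), drop = FALSE]
    p1 <- p1 + dmat[, d + 1]
    sd <- set_dirichlet(v1, vd1)
    v1 <- sd$v1; vd1 <- sd$vd1
    iters <- it
  }
  if (res > config$newton_tol * max(res0, 1e-300) && res >= 1e-13)
    attr(iters, "converged") <- FALSE

  st <- structure(list(v = v1, vdot = vd1, p = p1, t = state$t + dt,
                       vhat = if (moving) vhat else matrix(0, n, d)),
                  class = "flow_state")
  list(state = st, nodes = x1, newton_iters = iters, res0 = res0, res = res)
}

#' Time-march a flow on a fixed or externally moved mesh
#'
#' Convenience driver for verification problems: repeatedly applies
#' [advance_generalized_alpha()]; an optional `mesh_motion(t)` function
#' returns the node coordinates at time t (for prescribed-motion tests).
#'
#' @param mesh a `flow_mesh`.
#' @param bcs a [boundary_spec()].
#' @param config a [solver_config()].
#' @param n_steps number of steps.
#' @param dt step size (defaults to `config$dt`).
#' @param init initial `flow_state` (rest if `NULL`).
#' @param mesh_motion optional `function(t)` giving node coordinates.
#' @return list with final `state`, final `mesh`, and a tibble `log`.
#' @export
simulate_flow <- function(mesh, bcs, config, n_steps, dt = NULL,
                          init = NULL, mesh_motion = NULL) {
  dt <- dt %||% config$dt
  state <- init %||% flow_state_rest(mesh)
  log <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    tn <- state$t + dt
    target <- if (!is.null(mesh_motion)) mesh_motion(tn) else NULL
    stp <- advance_generalized_alpha(state, mesh, bcs, config,
                                     target_nodes = target, dt = dt)
    state <- stp$state
    mesh$nodes <- stp$nodes
    log[[s]] <- tibble::tibble(step = s, t = state$t,
                               newton_iters = stp$newton_iters,
                               res = stp$res,
                               ke = 0.5 * config$rho * mean(rowSums(state$v^2)))
  }
  list(state = state, mesh = mesh, log = do.call(rbind, log))
}
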