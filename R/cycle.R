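# Cardiac-cycle simulation: phase-switched boundary conditions driven by
# the rate of change of cavity volume, wall Dirichlet velocity from the
# tracked frame positions (piecewise-constant between frames, i.e. the time
# derivative of linearly interpolated vertex positions), elastostatic mesh
# motion, and dynamic remeshing with field transfer.

#' Phase-switched boundary conditions from the volume curve
#'
#' A rising cavity volume (filling, diastole) gives a traction-free inflow
#' with backflow stabilization and a closed (zero-velocity) outflow; a
#' falling volume (ejection, systole) reverses the two.  The volume curve
#' is treated as periodic and piecewise linear, so the phase is constant on
#' each frame interval; an exactly zero rate is assigned to the upcoming
#' phase.
#'
#' @param volume_series data frame with columns `t` and `volume` covering
#'   one cycle (uniform sampling).
#' @param frame_time time at which the phase is required.
#' @param period cycle duration (defaults to the sampling extent).
#' @return list with `phase` (`"diastole"` or `"systole"`), `dVdt`, and the
#'   cap treatment: `neumann` (traction-free label) and `dirichlet`
#'   (zero-velocity label).
#' @export
phase_switch_bcs <- function(volume_series, frame_time, period = NULL) {
  t <- volume_series$t
  V <- volume_series$volume
  M <- length(t)
  assert_that(M >= 2, "need at least two volume samples")
  Tc <- period %||% (t[M] - t[1] + (t[2] - t[1]))
  # piecewise-constant dV/dt on each (periodic) interval
  dV <- (V[c(2:M, 1)] - V) / (t[c(2:M, 1)] - t + c(rep(0, M - 1), Tc))
  tf <- (frame_time - t[1]) %% Tc + t[1]
  k <- findInterval(tf, t, rightmost.closed = FALSE)
  k <- min(max(k, 1L), M)
  slope <- dV[k]
  if (slope == 0) {
    # tie-break: the upcoming phase
    for (j in seq_len(M)) {
      s2 <- dV[((k - 1L + j) %% M) + 1L]
      if (s2 != 0) { slope <- s2; break }
    }
  }
  phase <- if (slope > 0) "diastole" else "systole"
  list(phase = phase, dVdt = dV[k],
       neumann = if (phase == "diastole") "inlet_cap" else "outlet_cap",
       dirichlet = if (phase == "diastole") "outlet_cap" else "inlet_cap")
}

# total boundary flux of `values` (n x d nodal field) through facets `sel`
boundary_flux <- function(mesh, values, sel = NULL) {
  faces <- mesh$boundary$faces
  if (!is.null(sel)) faces <- faces[sel, , drop = FALSE]
  if (!nrow(faces)) return(0)
  g <- facet_geometry(surface_mesh(mesh$nodes, faces, rep("x", nrow(faces))))
  vface <- matrix(0, nrow(faces), mesh$d)
  for (k in seq_len(ncol(faces)))
    vface <- vface + values[faces[, k], , drop = FALSE] / ncol(faces)
  sum(rowSums(vface * g$normals) * g$areas)
}

#' Simulate blood flow through full cardiac cycles in the moving ventricle
#'
#' Runs the VMS-ALE solver for `config$n_cycles` cycles of the tracked wall
#' motion.  The wall (and orifice extrusions) carry the Dirichlet wall
#' velocity; the caps switch between traction-free (with backflow
#' stabilization) and closed following the sign of dV/dt.  The mesh moves
#' by elastostatics with Jacobian-based stiffening, and is rebuilt (with
#' barycentric field transfer) whenever an element Jacobian would turn
#' non-positive, the scaled-Jacobian quality drops below the configured
#' floor, or the accumulated boundary displacement exceeds the configured
#' fraction of the mesh edge length.
#'
#' @param motion a `motion_track`.
#' @param mesh0 `flow_mesh` of the cavity at the template frame (from
#'   [mesh_interior()] on the tracked surface).
#' @param config a [solver_config()].
#' @param progress print a line per frame.
#' @return a `flow_series`: per-frame snapshots (state + mesh + volume +
#'   phase), a step log, remesh count, and diagnostics (peak velocity,
#'   inflow diameter, Re, CFL).
#' @export
run_cycle_simulation <- function(motion, mesh0, config = solver_config(),
                                 progress = FALSE) {
  M <- length(motion$positions_cm)
  Tc <- motion$period_s
  d <- mesh0$d
  nv <- mesh0$surf_nv
  assert_that(!is.na(nv) && nv == nrow(motion$surface$vertices),
              "mesh0 must be built from the tracked template surface")
  dt_frame <- Tc / M
  nsub <- max(1L, ceiling(dt_frame / config$dt))
  dt <- dt_frame / nsub

  mesh <- mesh0
  state <- flow_state_rest(mesh, t = 0)
  vol_series <- motion$volumes

  wall_labels <- intersect(unique(mesh$boundary$labels),
                           c("wall", "inlet_extrusion", "outlet_extrusion"))
  start <- motion$template_frame
  n_frames_total <- config$n_cycles * M

  snapshots <- vector("list", n_frames_total)
  log <- vector("list", n_frames_total * nsub)
  logi <- 0L
  n_remesh <- 0L
  Up <- 0
  t_global <- 0

  for (fi in seq_len(n_frames_total)) {
    a <- ((start - 1L + fi - 1L) %% M) + 1L
    b <- ((start - 1L + fi) %% M) + 1L
    Xa <- motion$positions_cm[[a]]
    Xb <- motion$positions_cm[[b]]
    frame_t <- motion$frame_times_s[a]
    ph <- phase_switch_bcs(vol_series, frame_t + dt_frame / 2, period = Tc)
    bc_list <- list()
    bc_list[[ph$dirichlet]] <- 0
    bcs <- boundary_spec(dirichlet = bc_list,
                         neumann = setNames(list(0), ph$neumann),
                         beta = config$beta,
                         moving_labels = wall_labels)
    # pressure gauge: if every node of the traction-free cap is claimed by a
    # Dirichlet label (tiny caps), pin the pressure at one cap node
    free_open <- setdiff(label_nodes(mesh, ph$neumann),
                         label_nodes(mesh, c(ph$dirichlet, wall_labels)))
    if (!length(free_open))
      bcs$pin_pressure <- label_nodes(mesh, ph$neumann)[1]
    for (s in seq_len(nsub)) {
      frac <- s / nsub
      Xt <- Xa + frac * (Xb - Xa)
      bdisp <- Xt - mesh$ref_nodes[seq_len(nv), , drop = FALSE]
      mm <- solve_mesh_motion(mesh, bdisp, nodes = seq_len(nv),
                              chi = config$chi)
      if (mm$min_jacobian <= 0) {
        rt <- remesh_and_transfer(mesh, fields = list(v = state$v,
                                                      vdot = state$vdot,
                                                      p = state$p))
        mesh <- rt$mesh
        state$v <- rt$fields$v; state$vdot <- rt$fields$vdot
        state$p <- rt$fields$p
        state$vhat <- matrix(0, nrow(mesh$nodes), d)
        n_remesh <- n_remesh + 1L
        bdisp <- Xt - mesh$ref_nodes[seq_len(nv), , drop = FALSE]
        mm <- solve_mesh_motion(mesh, bdisp, nodes = seq_len(nv),
                                chi = config$chi)
        if (mm$min_jacobian <= 0)
          stop_hf("mesh motion still inverts elements after remeshing (frame %d, step %d)",
                  fi, s)
      }
      stp <- advance_generalized_alpha(state, mesh, bcs, config,
                                       target_nodes = mm$new_nodes, dt = dt)
      state <- stp$state
      mesh$nodes <- stp$nodes
      t_global <- t_global + dt

      # remesh triggers: element inversion is caught above; here quality
      # floor and boundary travel since the last remesh
      qual <- min(element_quality(mesh$nodes, mesh$elems))
      trav <- max(row_norms(mesh$nodes[seq_len(nv), , drop = FALSE] -
                              mesh$ref_nodes[seq_len(nv), , drop = FALSE]))
      if (qual < config$remesh_quality_floor ||
          trav > config$remesh_disp_factor * mesh$target_edge) {
        rt <- remesh_and_transfer(mesh, fields = list(v = state$v,
                                                      vdot = state$vdot,
                                                      p = state$p))
        mesh <- rt$mesh
        state$v <- rt$fields$v; state$vdot <- rt$fields$vdot
        state$p <- rt$fields$p
        state$vhat <- matrix(0, nrow(mesh$nodes), d)
        n_remesh <- n_remesh + 1L
      }

      open_sel <- which(mesh$boundary$labels == ph$neumann)
      flux_open <- boundary_flux(mesh, state$v, open_sel)
      flux_tot <- boundary_flux(mesh, state$v)
      wall_flux <- boundary_flux(mesh, state$vhat,
                                 which(mesh$boundary$labels %in% wall_labels))
      char_flux <- max(abs(flux_open), abs(wall_flux), 1e-30)
      logi <- logi + 1L
      log[[logi]] <- tibble::tibble(
        t = t_global, frame = b, cycle = (fi - 1L) %/% M + 1L,
        phase = ph$phase, dVdt = ph$dVdt,
        min_jacobian = mm$min_jacobian, min_quality = qual,
        newton_iters = as.integer(stp$newton_iters),
        flux_open = flux_open, mass_residual = abs(flux_tot) / char_flux,
        remesh = FALSE)
    }
    # open-boundary mean speed for diagnostics
    if (length(open_sel)) {
      gsel <- facet_geometry(surface_mesh(mesh$nodes,
                                          mesh$boundary$faces[open_sel, , drop = FALSE],
                                          rep("x", length(open_sel))))
      Up <- max(Up, abs(flux_open) / sum(gsel$areas))
    }
    snapshots[[fi]] <- list(
      t = t_global, frame = b, cycle = (fi - 1L) %/% M + 1L,
      v = state$v, p = state$p, vhat = state$vhat,
      mesh = mesh, phase = ph$phase,
      volume = volume_from_surface(mesh_surface(mesh)))
    if (progress)
      message(sprintf("cycle %d frame %d: V=%.4g, phase=%s, remeshes=%d",
                      (fi - 1L) %/% M + 1L, b, snapshots[[fi]]$volume,
                      ph$phase, n_remesh))
  }

  # inflow annulus diameter at the template configuration
  in_sel <- which(mesh0$boundary$labels == "inlet_cap")
  Di <- if (length(in_sel)) {
    g0 <- facet_geometry(surface_mesh(mesh0$nodes,
                                      mesh0$boundary$faces[in_sel, , drop = FALSE],
                                      rep("x", length(in_sel))))
    A <- sum(g0$areas)
    if (d == 3) 2 * sqrt(A / pi) else A
  } else NA_real_
  mu_eff <- config$mu * config$viscosity_scale
  structure(list(
    snapshots = snapshots,
    log = do.call(rbind, log[seq_len(logi)]),
    n_remesh = n_remesh,
    frames_per_cycle = M, n_cycles = config$n_cycles,
    period_s = Tc, dt = dt,
    motion = motion, config = config,
    diagnostics = list(U_p = Up, D_i = Di,
                       CFL = Up * dt / mesh0$target_edge,
                       Re = config$rho * Up * Di / mu_eff)
  ), class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("flow_series: %d cycles x %d frames, dt=%.3g s, %d remeshes, Re=%.3g, CFL=%.3g\n",
              x$n_cycles, x$frames_per_cycle, x$dt, x$n_remesh,
              x$diagnostics$Re, x$diagnostics$CFL))
  invisible(x)
}
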