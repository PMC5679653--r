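# Shared fixtures, memoised so expensive objects (phantoms, tracked cycles,
# flow runs) are built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

# default desk-scale beating disc phantom (mild noise)
fixture_disc_phantom <- function() {
  cached_fixture("disc_phantom", function() {
    generate_beating_phantom(phantom_spec("disc", pulsation_amplitude = 0.2,
                                          noise_sigma = 0.02, seed = 5))
  })
}

# corrugated 2-D phantom frame and a known smooth warp (max |u| < 4 px)
fixture_warped_pair <- function() {
  cached_fixture("warped_pair", function() {
    spec <- phantom_spec("ventricle2d", pulsation_amplitude = 0, n_frames = 4,
                         noise_sigma = 0, seed = 3)
    I <- generate_beating_phantom(spec)$seq$frames[[1]]
    n <- dim(I)
    tr0 <- bspline_transform(n, 12)
    co <- tr0$coef
    co[, , 1] <- 4 * sin(seq(0, pi, length.out = dim(co)[1])) %o%
      cos(seq(0, 2, length.out = dim(co)[2]))
    co[, , 2] <- -3 * cos(seq(0, 2, length.out = dim(co)[1])) %o%
      sin(seq(0, pi, length.out = dim(co)[2]))
    true_tr <- bspline_transform(n, 12, co)
    list(fixed = warp_image(I, true_tr), moving = I, true_transform = true_tr)
  })
}

# template surface + tracked motion of the beating disc phantom, uncapped
# (pure cavity, for volume validation) and capped (for flow simulation)
fixture_tracked_disc <- function() {
  cached_fixture("tracked_disc", function() {
    ph <- fixture_disc_phantom()
    tmpl <- select_template_frame(ph$seq)
    mask <- segment_template(ph$seq$frames[[tmpl]])
    h <- 3 * min(ph$seq$spacing_um) * 1e-4
    surf_wall <- extract_surface(mask, ph$seq$spacing_um, target_edge = h)
    motion_wall <- track_motion(ph$seq, surf_wall, tmpl)
    surf_cap <- extract_surface(mask, ph$seq$spacing_um,
                                ph$seq$orifice_markers, target_edge = h)
    list(phantom = ph, template = tmpl, h = h,
         surf_wall = surf_wall, motion_wall = motion_wall,
         surf_cap = surf_cap)
  })
}

# Taylor-Green runner: solve on an m x m mesh of [0,pi]^2 with exact
# Dirichlet data, from the exact initial condition, and return the final
# state + mesh
run_taylor_green <- function(m, nstep, Tend = 0.2, nu = 0.05,
                             linear_solver = "direct", newton_tol = 1e-4) {
  tg <- generate_manufactured_flow("taylor_green2d", list(nu = nu, rho = 1))
  mesh <- mesh_rectangle(m, m, pi, pi)
  cfg <- solver_config(rho = 1, mu = nu, dt = Tend / nstep,
                       linear_solver = linear_solver, newton_tol = newton_tol,
                       newton_max = 15L)
  bcs <- boundary_spec(
    dirichlet = list(left = function(x, t) tg$velocity(x, t),
                     right = function(x, t) tg$velocity(x, t),
                     bottom = function(x, t) tg$velocity(x, t),
                     top = function(x, t) tg$velocity(x, t)),
    pin_pressure = 1L)
  st <- flow_state_rest(mesh)
  st$v <- tg$velocity(mesh$nodes, 0)
  st$p <- tg$pressure(mesh$nodes, 0) - tg$pressure(mesh$nodes[1, , drop = FALSE], 0)[1]
  st$vdot <- -2 * nu * st$v
  res <- simulate_flow(mesh, bcs, cfg, n_steps = nstep, init = st)
  res$exact <- tg
  res
}

# L2 velocity error against a callable exact solution (degree-2 quadrature)
l2_velocity_error <- function(mesh, v, vel_fun, t) {
  qp <- rbind(c(.5, .5, 0), c(0, .5, .5), c(.5, 0, .5))
  wq <- rep(1 / 3, 3)
  vols <- element_volumes(mesh)
  err2 <- 0
  for (e in seq_len(nrow(mesh$elems))) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    ve <- v[mesh$elems[e, ], ]
    for (q in 1:3) {
      xq <- colSums(qp[q, ] * X)
      vh <- colSums(qp[q, ] * ve)
      err2 <- err2 + wq[q] * vols[e] * sum((vh - vel_fun(rbind(xq), t))^2)
    }
  }
  sqrt(err2)
}

# independent dense assembly oracle for the stabilized weak form, written
# directly from the integrals with explicit per-term quadrature loops
oracle_vms_residual <- function(mesh, v, vdot, p, vhat, rho, mu, fb, dt,
                                Ct = 4, CI = 36) {
  d <- mesh$d
  nen <- d + 1
  n <- nrow(mesh$nodes)
  R <- numeric(n * (d + 1))
  if (d == 2) {
    bq <- rbind(c(.5, .5, 0), c(0, .5, .5), c(.5, 0, .5)); wq <- rep(1 / 3, 3)
  } else {
    aa <- 0.585410196624969; bb <- 0.138196601125011
    bq <- matrix(bb, 4, 4); diag(bq) <- aa; wq <- rep(1 / 4, 4)
  }
  fb <- rep(fb, length.out = d)
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]
    X <- mesh$nodes[en, , drop = FALSE]
    Jm <- t(X[-1, , drop = FALSE]) - X[1, ]
    A <- solve(Jm)
    vol <- det(Jm) / factorial(d)
    gradN <- rbind(-colSums(A), A)
    G <- t(A) %*% A
    gvec <- colSums(A)
    ve <- v[en, , drop = FALSE]
    gradv <- t(ve) %*% gradN
    divv <- sum(diag(gradv))
    gradp <- colSums(p[en] * gradN)
    for (q in seq_len(nrow(bq))) {
      N <- bq[q, seq_len(nen)]
      vq <- colSums(N * ve)
      vdq <- colSums(N * vdot[en, , drop = FALSE])
      vhq <- colSums(N * vhat[en, , drop = FALSE])
      pq <- sum(N * p[en])
      aq <- vq - vhq
      tauM <- 1 / sqrt(Ct / dt^2 + sum(aq * (G %*% aq)) +
                         CI * (mu / rho)^2 * sum(G * G))
      tauC <- 1 / (tauM * sum(gvec^2))
      rM <- rho * (vdq + as.vector(gradv %*% aq) - fb) + gradp
      tmr <- tauM * rM
      s <- sum(tmr * (G %*% tmr))
      tauB <- if (s > 1e-24) 1 / sqrt(s) else 0
      w <- wq[q] * vol
      for (a in seq_len(nen)) {
        rowb <- (en[a] - 1) * (d + 1)
        gNa <- gradN[a, ]
        for (i in seq_len(d)) {
          r <- N[a] * rho * (vdq[i] + sum(gradv[i, ] * aq) - fb[i]) -
            gNa[i] * pq +
            mu * sum((gradv[i, ] + gradv[, i]) * gNa) +
            sum(aq * gNa) * tmr[i] -
            N[a] * sum(gradv[i, ] * tmr) -
            (1 / rho) * tmr[i] * sum(tmr * gNa) +
            rho * tauC * divv * gNa[i] +
            tauB * sum(tmr * gNa) * sum(gradv[i, ] * tmr)
          R[rowb + i] <- R[rowb + i] + w * r
        }
        R[rowb + d + 1] <- R[rowb + d + 1] +
          w * (N[a] * divv + (1 / rho) * sum(tmr * gNa))
      }
    }
  }
  R
}

# analytic motion track: radial pulsation of a capped surface about its
# centroid (no registration involved); template at frame 1 (lambda = 1)
make_synthetic_motion <- function(surf, M = 8L, Tc = 0.4, amplitude = 0.2) {
  ctr <- colMeans(surf$vertices)
  tms <- (seq_len(M) - 1) / M * Tc
  lam <- 1 + amplitude * sin(2 * pi * tms / Tc)
  pos <- lapply(lam, function(l)
    sweep(sweep(surf$vertices, 2, ctr, "-") * l, 2, ctr, "+"))
  vols <- vapply(pos, function(p)
    volume_from_surface(surface_mesh(p, surf$facets, surf$labels)), numeric(1))
  structure(list(surface = surf, template_frame = 1L, positions_cm = pos,
                 displacements_cm = lapply(pos, function(p) p - pos[[1]]),
                 volumes = tibble::tibble(frame = seq_len(M), t = tms,
                                          volume = vols),
                 closure_error_vox = 0, frame_times_s = tms, period_s = Tc,
                 spacing_um = surf$spacing_um),
            class = "motion_track")
}

# small capped disc surface + mesh for solver-level tests
fixture_capped_disc <- function() {
  cached_fixture("capped_disc", function() {
    spec <- phantom_spec("disc", pulsation_amplitude = 0, noise_sigma = 0, seed = 1)
    ph <- generate_beating_phantom(spec)
    h <- 3 * 0.65e-4
    surf <- extract_surface(ph$truth$cavity_mask(1), spec$spacing_um,
                            ph$seq$orifice_markers, target_edge = h)
    list(surf = surf, h = h, mesh = mesh_interior(surf, target_edge = h))
  })
}

# one full end-to-end pipeline run at the default desk configuration,
# shared between the acceptance and pipeline test files
fixture_pipeline_run <- function() {
  cached_fixture("pipeline_run1", function() {
    dir <- file.path(tempdir(), "hemoflow-pipeline-run1")
    cfg <- pipeline_config(seed = 1)
    res <- run_pipeline(cfg, dir)
    list(dir = dir, config = cfg, result = res)
  })
}
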