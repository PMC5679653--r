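# Synthetic beating-ventricle phantoms and manufactured flow cases.
#
# The phantom renders a bright-walled, dark-lumen cavity whose inner boundary
# follows an analytic radial pulsation, so every downstream stage (threshold +
# level-set segmentation, B-spline registration, meshing, flow simulation,
# metrics) can be validated against known ground truth without any external
# data.

#' Specification of a synthetic beating-ventricle phantom
#'
#' @param shape_kind one of `"sphere"`, `"ellipsoid"`, `"disc"` (2-D),
#'   `"ventricle"` (sphere with trabecula-like surface corrugations) or
#'   `"ventricle2d"` (disc with corrugations).
#' @param base_radius cavity radius at the template phase, in cm.
#' @param pulsation_amplitude dimensionless fraction `a` of radial pulsation;
#'   the cavity scales by `1 + a*sin(2*pi*t/period)`.
#' @param period_s cardiac period T_c in seconds.
#' @param n_frames number of image frames per cycle (M >= 4).
#' @param grid_dims integer voxel counts per axis (length 2 or 3).
#' @param spacing_um physical voxel spacing per axis, micrometres.
#' @param noise_sigma standard deviation of additive Gaussian intensity noise
#'   (intensity units; the noise-free wall peaks at 1).
#' @param bump_count,bump_depth number and relative depth of the
#'   trabecula-like corrugations (used by `"ventricle"`).
#' @param wall_thickness_vox rendered myocardial wall thickness in voxels
#'   (must resolve to at least 2 voxels).
#' @param ellipsoid_ratios semi-axis ratios for `"ellipsoid"`.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_kind = c("sphere", "ellipsoid", "disc", "ventricle",
                                        "ventricle2d"),
                         base_radius = 2e-3,
                         pulsation_amplitude = 0.2,
                         period_s = 0.4,
                         n_frames = 20L,
                         grid_dims = NULL,
                         spacing_um = NULL,
                         noise_sigma = 0,
                         bump_count = 8L,
                         bump_depth = 0.12,
                         wall_thickness_vox = 3,
                         ellipsoid_ratios = c(1, 0.85, 0.75),
                         seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  d <- if (shape_kind %in% c("disc", "ventricle2d")) 2L else 3L
  if (is.null(grid_dims)) grid_dims <- if (d == 2) c(96L, 96L) else c(64L, 64L, 48L)
  if (is.null(spacing_um)) spacing_um <- if (d == 2) c(0.65, 0.65) else c(0.65, 0.65, 0.9)
  assert_that(length(grid_dims) == d, "grid_dims must have length %d for shape '%s'", d, shape_kind)
  assert_that(length(spacing_um) == d, "spacing_um must have length %d", d)
  assert_that(all(spacing_um > 0), "spacing must be positive")
  assert_that(n_frames >= 4, "n_frames must be at least 4")
  assert_that(pulsation_amplitude >= 0 && pulsation_amplitude < 1,
              "pulsation_amplitude must lie in [0, 1)")
  assert_that(period_s > 0, "period_s must be positive")
  assert_that(base_radius > 0, "base_radius must be positive")
  if (wall_thickness_vox < 2)
    stop_hf("wall thickness of %.2f voxels cannot be resolved (need >= 2 voxels)",
            wall_thickness_vox)
  structure(list(
    shape_kind = shape_kind, d = d,
    base_radius = base_radius,
    pulsation_amplitude = pulsation_amplitude,
    period_s = period_s,
    n_frames = as.integer(n_frames),
    grid_dims = as.integer(grid_dims),
    spacing_um = spacing_um,
    noise_sigma = noise_sigma,
    bump_count = as.integer(bump_count),
    bump_depth = bump_depth,
    wall_thickness_vox = wall_thickness_vox,
    ellipsoid_ratios = ellipsoid_ratios,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s, %s voxels @ %s um, M=%d frames, T=%.3g s, a=%.2f\n",
              x$shape_kind, paste(x$grid_dims, collapse = "x"),
              paste(signif(x$spacing_um, 3), collapse = "x"),
              x$n_frames, x$period_s, x$pulsation_amplitude))
  invisible(x)
}

# directional base radius (cm) for unit directions `u` (n x d matrix)
phantom_radius_dir <- function(spec, u) {
  r0 <- spec$base_radius
  switch(spec$shape_kind,
    sphere = ,
    disc = rep(r0, nrow(u)),
    ellipsoid = {
      ax <- r0 * spec$ellipsoid_ratios[seq_len(spec$d)]
      1 / sqrt(rowSums(sweep(u, 2, ax, "/")^2))
    },
    ventricle = ,
    ventricle2d = {
      theta <- atan2(u[, 2], u[, 1])
      env <- if (spec$d == 3) {
        # corrugations strongest at the equator, vanishing at the poles
        1 - u[, 3]^2
      } else 1
      r0 * (1 + spec$bump_depth * cos(spec$bump_count * theta) * env)
    })
}

# radial scale factor lambda(t) of the pulsation
phantom_lambda <- function(spec, t) 1 + spec$pulsation_amplitude * sin(2 * pi * t / spec$period_s)

# enclosed cavity volume (cm^3, or cm^2 in 2-D) at the template phase
phantom_base_volume <- function(spec) {
  d <- spec$d
  r0 <- spec$base_radius
  switch(spec$shape_kind,
    sphere = 4 / 3 * pi * r0^3,
    disc = pi * r0^2,
    ellipsoid = 4 / 3 * pi * prod(r0 * spec$ellipsoid_ratios[1:3]),
    ventricle = ,
    ventricle2d = {
      # exact to quadrature: V = (1/d) * integral of R(dir)^d over directions
      if (d == 2) {
        th <- seq(0, 2 * pi, length.out = 2049)[-1]
        u <- cbind(cos(th), sin(th))
        R <- phantom_radius_dir(spec, u)
        mean(R^2) / 2 * 2 * pi
      } else {
        nth <- 256; nph <- 128
        th <- (seq_len(nth) - 0.5) / nth * 2 * pi
        cph <- (seq_len(nph) - 0.5) / nph * 2 - 1  # cos(polar), uniform
        gr <- expand.grid(th = th, cph = cph)
        sph <- sqrt(1 - gr$cph^2)
        u <- cbind(sph * cos(gr$th), sph * sin(gr$th), gr$cph)
        R <- phantom_radius_dir(spec, u)
        mean(R^3) / 3 * 4 * pi
      }
    })
}

#' Generate a synthetic beating-ventricle image sequence with ground truth
#'
#' Renders `n_frames` intensity volumes of a bright wall around a dark cavity
#' whose boundary pulses radially as `R(dir) * (1 + a*sin(2*pi*t/T))`.  The
#' returned ground truth carries the analytic wall displacement field, cavity
#' volume curve, contractility indices, exact cavity masks, and inlet/outlet
#' orifice marker points.
#'
#' @param spec a [phantom_spec()].
#' @return a list with components `seq` (an `image_sequence`) and
#'   `truth` (a `ground_truth`).
#' @export
generate_beating_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$d
  dims <- spec$grid_dims
  sp_cm <- spec$spacing_um * UM_TO_CM
  min_sp <- min(sp_cm)
  w_wall <- spec$wall_thickness_vox * min_sp
  ramp <- 0.75 * min_sp
  centre_vox <- (dims - 1) / 2
  centre_cm <- centre_vox * sp_cm

  # check the wall is resolved on this grid
  if (w_wall < 2 * min_sp)
    stop_hf("grid too coarse to resolve the wall (wall thickness < 2 voxels)")

  # physical offsets of all voxel centres from the cavity centre
  xyz <- grid_coords(dims)
  off <- sweep(sweep(xyz, 2, centre_vox, "-"), 2, sp_cm, "*")
  r <- row_norms(off)
  u <- off / pmax(r, 1e-30)
  u[r == 0, ] <- 0
  Rdir <- phantom_radius_dir(spec, u)
  Rdir[r == 0] <- phantom_radius_dir(spec, matrix(c(1, rep(0, d - 1)), 1))[1]

  tms <- (seq_len(spec$n_frames) - 1) / spec$n_frames * spec$period_s
  lam <- phantom_lambda(spec, tms)

  sig <- function(x) 0.5 * (1 + tanh(x))
  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    Rt <- lam[k] * Rdir
    img <- sig((r - Rt) / ramp) * sig((Rt + w_wall - r) / ramp)
    if (spec$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sigma)
    dim(img) <- dims
    frames[[k]] <- img
  }

  # orifice markers: boundary points near the "top" of the cavity at the
  # template phase, given in voxel coordinates
  mk_dir <- if (d == 2) {
    rbind(c(cos(pi / 2 + 0.55), sin(pi / 2 + 0.55)),
          c(cos(pi / 2 - 0.55), sin(pi / 2 - 0.55)))
  } else {
    a <- 0.5
    rbind(c(sin(a), 0, cos(a)), c(-sin(a), 0, cos(a)))
  }
  mk_R <- phantom_radius_dir(spec, mk_dir)
  markers <- sweep(mk_dir * mk_R, 2, sp_cm, "/")
  markers <- sweep(markers, 2, centre_vox, "+")
  rownames(markers) <- c("inlet", "outlet")

  iseq <- structure(list(
    frames = frames, dims = dims, spacing_um = spec$spacing_um,
    frame_times_s = tms, period_s = spec$period_s,
    orifice_markers = markers
  ), class = "image_sequence")

  V0 <- phantom_base_volume(spec)
  truth <- structure(list(
    spec = spec,
    lambda = lam,
    frame_times_s = tms,
    # analytic displacement (voxel units) of material points from the
    # template frame to frame k
    displacement = function(points_vox, frame) {
      lk <- lam[frame]
      sweep(points_vox, 2, centre_vox, "-") * (lk - 1)
    },
    volume = function(t) V0 * phantom_lambda(spec, t)^d,
    volumes = V0 * lam^d,
    EDV = V0 * (1 + spec$pulsation_amplitude)^d,
    ESV = V0 * (1 - spec$pulsation_amplitude)^d,
    SV = V0 * ((1 + spec$pulsation_amplitude)^d - (1 - spec$pulsation_amplitude)^d),
    EF = 100 * (1 - ((1 - spec$pulsation_amplitude) / (1 + spec$pulsation_amplitude))^d),
    cavity_mask = function(frame) {
      m <- r < lam[frame] * Rdir
      dim(m) <- dims
      m
    },
    centre_vox = centre_vox,
    spacing_cm = sp_cm
  ), class = "ground_truth")

  list(seq = iseq, truth = truth)
}

#' Manufactured flow cases with exact solutions
#'
#' Returns exact velocity/pressure fields (with fluid properties attached)
#' for solver verification: plane Poiseuille flow, the decaying 2-D
#' Taylor-Green vortex, and a uniform free stream.
#'
#' @param case_name one of `"poiseuille2d"`, `"taylor_green2d"`,
#'   `"uniform_stream"`.
#' @param params named list of case parameters; defaults are supplied for
#'   any not given.  Common entries: `rho`, `mu`; Poiseuille: `H` (channel
#'   height), `L` (length), `U` (peak velocity); Taylor-Green: `nu`
#'   (kinematic viscosity); uniform stream: `U` (velocity vector).
#' @return a `manufactured_flow` object with callable `velocity(x, t)` and
#'   `pressure(x, t)`.
#' @export
generate_manufactured_flow <- function(case_name, params = list()) {
  p <- params
  switch(case_name,
    poiseuille2d = {
      H <- p$H %||% 1; L <- p$L %||% (2 * (p$H %||% 1))
      U <- p$U %||% 1; mu <- p$mu %||% 0.04; rho <- p$rho %||% 1.06
      structure(list(
        name = "poiseuille2d", d = 2L, rho = rho, mu = mu,
        H = H, L = L, U = U,
        velocity = function(x, t = 0) cbind(4 * U * x[, 2] * (H - x[, 2]) / H^2, 0 * x[, 2]),
        pressure = function(x, t = 0) -8 * mu * U / H^2 * (x[, 1] - L),
        wall_shear = 4 * mu * U / H,
        domain = c(L, H)
      ), class = "manufactured_flow")
    },
    taylor_green2d = {
      nu <- p$nu %||% 0.05; rho <- p$rho %||% 1
      structure(list(
        name = "taylor_green2d", d = 2L, rho = rho, mu = nu * rho, nu = nu,
        velocity = function(x, t = 0) {
          f <- exp(-2 * nu * t)
          cbind(sin(x[, 1]) * cos(x[, 2]), -cos(x[, 1]) * sin(x[, 2])) * f
        },
        pressure = function(x, t = 0) {
          rho / 4 * (cos(2 * x[, 1]) + cos(2 * x[, 2])) * exp(-4 * nu * t)
        },
        domain = c(2 * pi, 2 * pi)
      ), class = "manufactured_flow")
    },
    uniform_stream = {
      U <- p$U %||% c(1, 0)
      rho <- p$rho %||% 1.06; mu <- p$mu %||% 0.04
      structure(list(
        name = "uniform_stream", d = length(U), rho = rho, mu = mu, U = U,
        velocity = function(x, t = 0) matrix(U, nrow(x), length(U), byrow = TRUE),
        pressure = function(x, t = 0) rep(0, nrow(x)),
        wall_shear = 0, dissipation = 0
      ), class = "manufactured_flow")
    },
    stop_hf("unknown manufactured flow case '%s'", case_name))
}
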