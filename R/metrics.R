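# Mechanobiologic force metrics: wall shear stress (the tangential viscous
# traction 2 mu (grad^s v) n), its area average (AAWSS) and space-time
# average (AWSS), the oscillatory shear index (OSI), volume-averaged kinetic
# energy density and viscous dissipation rate, contractility indices
# (EDV/ESV/SV/EF), phase averaging, and the printed-pressure cardiac-work
# estimate.

# owner element of each boundary face (the element containing all its nodes)
face_owner_elements <- function(mesh) {
  d <- mesh$d
  el <- mesh$elems
  if (d == 2) {
    fc <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  } else {
    fc <- rbind(el[, c(2, 3, 4)], el[, c(1, 4, 3)], el[, c(1, 2, 4)],
                el[, c(1, 3, 2)])
  }
  own <- rep(seq_len(nrow(el)), d + 1)
  key <- apply(fc, 1, function(r) paste(sort(r), collapse = "_"))
  bkey <- apply(mesh$boundary$faces, 1, function(r) paste(sort(r), collapse = "_"))
  own[match(bkey, key)]
}

# element-constant velocity gradients, one d x d matrix per element
element_velocity_gradients <- function(mesh, v) {
  d <- mesh$d
  ne <- nrow(mesh$elems)
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    Jm <- t(X[-1, , drop = FALSE] ) - X[1, ]
    A <- solve(Jm)                       # rows dxi_k/dx
    gradN <- rbind(-colSums(A), A)       # (d+1) x d : dN_k/dx
    out[[e]] <- t(v[mesh$elems[e, ], , drop = FALSE]) %*% gradN
  }
  out
}

#' Wall shear stress field at one instant
#'
#' Per-boundary-facet shear vectors from the P1 velocity gradient of the
#' adjacent element: `tau_n = 2 mu (grad^s v) n`, `tau_w = tau_n -
#' (tau_n.n) n`, so `tau_w.n = 0` on every facet.
#'
#' @param v nodal velocity (n x d).
#' @param mesh a `flow_mesh`.
#' @param mu dynamic viscosity (g/(cm s)).
#' @return list with per-facet `vectors` (nb x d), `areas`, `normals`,
#'   `labels`.
#' @export
wall_shear_stress <- function(v, mesh, mu) {
  faces <- mesh$boundary$faces
  g <- facet_geometry(surface_mesh(mesh$nodes, faces, mesh$boundary$labels))
  own <- face_owner_elements(mesh)
  grads <- element_velocity_gradients(mesh, v)
  nb <- nrow(faces)
  tw <- matrix(0, nb, mesh$d)
  for (f in seq_len(nb)) {
    gv <- grads[[own[f]]]
    n <- g$normals[f, ]
    tn <- mu * (gv + t(gv)) %*% n
    tw[f, ] <- tn - sum(tn * n) * n
  }
  list(vectors = tw, areas = g$areas, normals = g$normals,
       labels = mesh$boundary$labels)
}

#' Wall shear stress time series of a cycle simulation
#'
#' Computes the per-facet shear vectors and instantaneous facet areas for
#' every stored frame.  Facets of the artificially extruded collars and the
#' caps are flagged for exclusion from the averaged metrics.
#'
#' @param series a `flow_series` from [run_cycle_simulation()].
#' @return a `wall_shear_field`: `times`, list of per-time `vectors` and
#'   `areas`, facet `labels`, and logical `include` (wall facets).
#' @export
wall_shear_series <- function(series) {
  mu_eff <- series$config$mu * series$config$viscosity_scale
  snaps <- series$snapshots
  vec <- vector("list", length(snaps))
  are <- vector("list", length(snaps))
  for (k in seq_along(snaps)) {
    w <- wall_shear_stress(snaps[[k]]$v, snaps[[k]]$mesh, mu_eff)
    vec[[k]] <- w$vectors
    are[[k]] <- w$areas
  }
  labels <- snaps[[1]]$mesh$boundary$labels
  structure(list(times = vapply(snaps, `[[`, numeric(1), "t"),
                 vectors = vec, areas = are, labels = labels,
                 include = labels == "wall",
                 d = snaps[[1]]$mesh$d),
            class = "wall_shear_field")
}

#' Area-averaged wall shear stress AAWSS(t)
#'
#' `AAWSS(t) = (1/A_e) * integral of |tau_w| over the included wall`, using
#' the instantaneous facet areas; extruded collars and caps are excluded.
#'
#' @param field a `wall_shear_field` (or a list with `vectors`, `areas` and
#'   optionally `include` for a single instant).
#' @param time optional time (nearest stored sample); all samples if `NULL`.
#' @return scalar (or vector over samples) in g/(cm s^2).
#' @export
aawss <- function(field, time = NULL) {
  one <- function(vectors, areas, include) {
    A <- sum(areas[include])
    if (A <= 0) stop_hf("zero included wall area in AAWSS")
    sum(row_norms(vectors[include, , drop = FALSE]) * areas[include]) / A
  }
  if (!inherits(field, "wall_shear_field")) {
    inc <- field$include %||% rep(TRUE, nrow(field$vectors))
    return(one(field$vectors, field$areas, inc))
  }
  vals <- vapply(seq_along(field$times), function(k)
    one(field$vectors[[k]], field$areas[[k]], field$include), numeric(1))
  if (is.null(time)) return(setNames(vals, signif(field$times, 8)))
  vals[which.min(abs(field$times - time))]
}

#' Space-time averaged wall shear stress AWSS
#'
#' The time average of AAWSS(t) over the sampled interval (trapezoid rule),
#' i.e. the space-time average of `|tau_w|` with the instantaneous area in
#' the spatial normalization.
#'
#' @param field a `wall_shear_field`.
#' @return scalar in g/(cm s^2).
#' @export
awss <- function(field) {
  vals <- aawss(field)
  t <- field$times
  if (length(t) < 2) return(unname(vals[1]))
  trapz(t, as.numeric(vals)) / (t[length(t)] - t[1])
}

# OSI of one shear-vector time history (nt x d), trapezoid quadrature for
# both numerator and denominator; an all-zero history gives 0 by convention
osi_history <- function(times, vecs) {
  w <- trapz_weights(times)
  den <- sum(w * row_norms(vecs))
  if (den <= 0) return(0)
  num <- vnorm(colSums(w * vecs))
  0.5 * (1 - num / den)
}

#' Oscillatory shear index
#'
#' `OSI = (1/2) (1 - |time-mean tau_w| / time-mean |tau_w|)`, computed with
#' the same trapezoid quadrature for numerator and denominator; the range
#' is `[0, 0.5]`, 0 for a direction-constant history and 0.5 for a perfect
#' zero-mean reversal.  An identically zero history gives 0 by convention.
#'
#' @param field a `wall_shear_field` (per-facet OSI) or an nt x d matrix
#'   (single history).
#' @param times sample times when `field` is a matrix (uniform spacing
#'   assumed if omitted).
#' @return per-facet vector, or scalar for a single history.
#' @export
osi <- function(field, times = NULL) {
  if (inherits(field, "wall_shear_field")) {
    nt <- length(field$times)
    nf <- nrow(field$vectors[[1]])
    out <- numeric(nf)
    arr <- array(unlist(field$vectors), c(nf, field$d, nt))
    for (f in seq_len(nf))
      out[f] <- osi_history(field$times, t(arr[f, , ]))
    return(out)
  }
  vecs <- as.matrix(field)
  osi_history(times %||% seq_len(nrow(vecs)), vecs)
}

#' Volume-averaged kinetic energy density and viscous dissipation rate
#'
#' `KE = (1/V_d) * integral of rho |v|^2 / 2` (exact P1 mass-matrix
#' quadrature) and `Phi = (1/V_d) * integral of mu (grad^s v : grad^s v)`
#' (element-constant gradients).
#'
#' @param v nodal velocity (n x d).
#' @param mesh a `flow_mesh`.
#' @param rho,mu fluid density and viscosity.
#' @return list with `ke` (g/(cm s^2)) and `phi` (g/(cm s^3)) and the
#'   domain volume `V`.
#' @export
energy_metrics <- function(v, mesh, rho, mu) {
  d <- mesh$d
  vols <- element_volumes(mesh)
  V <- sum(vols)
  nen <- d + 1
  cf <- 1 / ((d + 1) * (d + 2))
  ke_int <- 0
  grads <- element_velocity_gradients(mesh, v)
  phi_int <- 0
  for (e in seq_len(nrow(mesh$elems))) {
    ve <- v[mesh$elems[e, ], , drop = FALSE]
    Gram <- ve %*% t(ve)
    ke_int <- ke_int + vols[e] * cf * (sum(Gram) + sum(diag(Gram)))
    gs <- (grads[[e]] + t(grads[[e]])) / 2
    phi_int <- phi_int + vols[e] * sum(gs * gs)
  }
  list(ke = 0.5 * rho * ke_int / V, phi = mu * phi_int / V, V = V)
}

#' Cardiac contractility indices from a volume curve
#'
#' EDV is the maximum cavity volume over the cycle, ESV the minimum,
#' `SV = EDV - ESV`, and `EF = 100 * SV / EDV` (percent).
#'
#' @param volume_series numeric vector of cavity volumes covering one full
#'   cycle (or a data frame with a `volume` column).
#' @return list with `EDV`, `ESV`, `SV`, `EF`.
#' @export
contractility <- function(volume_series) {
  v <- if (is.data.frame(volume_series)) volume_series$volume else volume_series
  assert_that(all(is.finite(v)), "volumes must be finite")
  if (any(v <= 0)) stop_hf("non-positive cavity volume in contractility()")
  EDV <- max(v); ESV <- min(v)
  list(EDV = EDV, ESV = ESV, SV = EDV - ESV, EF = 100 * (EDV - ESV) / EDV)
}

#' Cardiac work per unit volume from systolic/diastolic pressures
#'
#' Converts the pressure difference to CGS units
#' (1 mmHg = 1333.22 dyn/cm^2): with the printed embryonic pressures of
#' 0.47 and 0.08 mmHg this gives about 520 g/(cm s^2).
#'
#' @param p_sys peak systolic pressure (mmHg).
#' @param p_dia end-diastolic pressure (mmHg).
#' @return work per unit volume in g/(cm s^2).
#' @export
cardiac_work_per_volume <- function(p_sys, p_dia) {
  assert_that(p_dia >= 0, "pressures must be nonnegative")
  if (p_sys < p_dia) stop_hf("p_sys must not be smaller than p_dia")
  mmhg_to_cgs(p_sys - p_dia)
}

#' Phase average of a multi-cycle periodic signal
#'
#' Pointwise mean over the last `n_cycles - 1` cycles; the first cycle is
#' discarded as the initial transient.  `x` may be a vector or matrix whose
#' rows sample `n_cycles` consecutive cycles uniformly; cycles of unequal
#' length are resampled to a common within-cycle grid first.
#'
#' @param x vector (length `n_cycles * M`), matrix (rows are samples), or
#'   list of per-cycle vectors/matrices (possibly ragged).
#' @param n_cycles number of cycles contained in `x`.
#' @return one cycle: vector or matrix of `M` samples.
#' @export
phase_average <- function(x, n_cycles) {
  assert_that(n_cycles >= 2, "phase averaging requires >= 2 cycles")
  if (is.list(x) && !is.data.frame(x)) {
    M <- max(vapply(x, NROW, numeric(1)))
    x <- lapply(x, function(ci) {
      if (is.null(dim(ci))) ci <- matrix(ci, ncol = 1)
      if (NROW(ci) == M) return(ci)
      s0 <- seq(0, 1, length.out = NROW(ci))
      s1 <- seq(0, 1, length.out = M)
      apply(ci, 2, function(col) approx(s0, col, s1)$y)
    })
    keep <- x[-1]
    return(Reduce(`+`, keep) / length(keep))
  }
  vec <- is.null(dim(x))
  xm <- rbind(x)
  if (vec) xm <- matrix(x, ncol = 1)
  assert_that(nrow(xm) %% n_cycles == 0,
              "signal length is not a multiple of n_cycles")
  M <- nrow(xm) %/% n_cycles
  acc <- 0
  for (c in 2:n_cycles) acc <- acc + xm[(c - 1) * M + seq_len(M), , drop = FALSE]
  out <- acc / (n_cycles - 1)
  if (vec) as.vector(out) else out
}

# phase-averaged wall shear field (facet correspondence is exact: remeshing
# preserves boundary facets)
phase_average_shear <- function(field, n_cycles, frames_per_cycle) {
  M <- frames_per_cycle
  assert_that(length(field$times) == n_cycles * M,
              "shear series length does not match cycles")
  nf <- nrow(field$vectors[[1]])
  d <- field$d
  vecs <- vector("list", M)
  ares <- vector("list", M)
  for (k in seq_len(M)) {
    idx <- k + M * (1:(n_cycles - 1))
    vecs[[k]] <- Reduce(`+`, field$vectors[idx]) / length(idx)
    ares[[k]] <- Reduce(`+`, field$areas[idx]) / length(idx)
  }
  structure(list(times = field$times[seq_len(M)] - field$times[1] +
                   diff(field$times)[1],
                 vectors = vecs, areas = ares, labels = field$labels,
                 include = field$include, d = d),
            class = "wall_shear_field")
}
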