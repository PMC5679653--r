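# HemodynamicSummary: the per-simulation bundle of contractility indices,
# shear metrics, energy metrics and diagnostics, with broom-style tidy()/
# glance() methods and a ggplot2 autoplot().

#' Summarize the hemodynamics of a cycle simulation
#'
#' Phase-averages the last `n_cycles - 1` simulated cycles (the first cycle
#' is the start-up transient), then computes: the cavity volume curve and
#' contractility indices (EDV, ESV, SV, EF) from the tracked motion;
#' AAWSS(t), AWSS and per-facet OSI from the phase-averaged wall shear
#' history (collars and caps excluded); volume-averaged kinetic energy
#' density and viscous dissipation rate; and the printed-pressure cardiac
#' work estimate for comparison with the flow energy scales.
#'
#' @param series a `flow_series` from [run_cycle_simulation()].
#' @param p_sys,p_dia systolic/diastolic pressures (mmHg) for the cardiac
#'   work estimate.
#' @return a `hemodynamic_summary`.
#' @export
summarize_hemodynamics <- function(series, p_sys = 0.47, p_dia = 0.08) {
  M <- series$frames_per_cycle
  nc <- series$n_cycles
  assert_that(nc >= 2, "phase averaging requires >= 2 cycles")
  cfg <- series$config
  mu_eff <- cfg$mu * cfg$viscosity_scale

  shear <- wall_shear_series(series)
  shear_pa <- phase_average_shear(shear, nc, M)
  aawss_t <- as.numeric(aawss(shear_pa))
  AWSS <- awss(shear_pa)
  osi_f <- osi(shear_pa)
  osi_cycles <- vapply(seq_len(nc), function(c) {
    idx <- (c - 1) * M + seq_len(M)
    sub <- structure(list(times = shear$times[idx],
                          vectors = shear$vectors[idx],
                          areas = shear$areas[idx],
                          labels = shear$labels, include = shear$include,
                          d = shear$d), class = "wall_shear_field")
    mean(osi(sub)[shear$include])
  }, numeric(1))

  en <- t(vapply(series$snapshots, function(sn) {
    e <- energy_metrics(sn$v, sn$mesh, cfg$rho, mu_eff)
    c(ke = e$ke, phi = e$phi, V = e$V)
  }, numeric(3)))
  ke_pa <- phase_average(en[, "ke"], nc)
  phi_pa <- phase_average(en[, "phi"], nc)
  vol_snap <- vapply(series$snapshots, `[[`, numeric(1), "volume")
  vol_pa <- phase_average(vol_snap, nc)

  ctr <- contractility(series$motion$volumes)
  tt <- shear_pa$times
  structure(list(
    time_series = tibble::tibble(t = tt, volume = vol_pa, aawss = aawss_t,
                                 ke = ke_pa, phi = phi_pa),
    EDV = ctr$EDV, ESV = ctr$ESV, SV = ctr$SV, EF = ctr$EF,
    T_c = series$period_s,
    AWSS = AWSS,
    osi = osi_f, osi_labels = shear_pa$labels,
    osi_included = shear_pa$include,
    osi_per_cycle = osi_cycles,
    work_per_volume = cardiac_work_per_volume(p_sys, p_dia),
    diagnostics = series$diagnostics,
    n_remesh = series$n_remesh,
    n_cycles = nc, frames_per_cycle = M
  ), class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat("hemodynamic_summary\n")
  cat(sprintf("  EDV %.4g  ESV %.4g  SV %.4g  EF %.1f%%\n", x$EDV, x$ESV, x$SV, x$EF))
  cat(sprintf("  AWSS %.4g g/(cm s^2); mean wall OSI %.3f\n",
              x$AWSS, mean(x$osi[x$osi_included])))
  cat(sprintf("  peak KE %.4g; peak dissipation %.4g; work/volume %.4g g/(cm s^2)\n",
              max(x$time_series$ke), max(x$time_series$phi), x$work_per_volume))
  cat(sprintf("  Re %.3g, CFL %.3g, %d remeshes\n",
              x$diagnostics$Re, x$diagnostics$CFL, x$n_remesh))
  invisible(x)
}

#' Tidy the phase-averaged time series of a hemodynamic summary
#' @param x a `hemodynamic_summary`.
#' @param ... unused.
#' @return a tibble with columns `t`, `volume`, `aawss`, `ke`, `phi`.
#' @export
tidy.hemodynamic_summary <- function(x, ...) x$time_series

#' One-row overview of a hemodynamic summary
#' @param x a `hemodynamic_summary`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.hemodynamic_summary <- function(x, ...) {
  tibble::tibble(EDV = x$EDV, ESV = x$ESV, SV = x$SV, EF = x$EF,
                 AWSS = x$AWSS, mean_osi = mean(x$osi[x$osi_included]),
                 peak_ke = max(x$time_series$ke),
                 peak_phi = max(x$time_series$phi),
                 work_per_volume = x$work_per_volume,
                 Re = x$diagnostics$Re, CFL = x$diagnostics$CFL,
                 n_remesh = x$n_remesh)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the phase-averaged hemodynamic time series
#'
#' @param object a `hemodynamic_summary`.
#' @param ... unused.
#' @return a ggplot object (volume, AAWSS, kinetic energy and dissipation
#'   over the phase-averaged cycle).
#' @export
autoplot.hemodynamic_summary <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_hf("ggplot2 is required for autoplot()")
  ts <- object$time_series
  long <- tibble::tibble(
    t = rep(ts$t / object$T_c, 4),
    value = c(ts$volume, ts$aawss, ts$ke, ts$phi),
    metric = rep(c("volume [cm^3]", "AAWSS [g/(cm s^2)]",
                   "KE [g/(cm s^2)]", "dissipation [g/(cm s^3)]"),
                 each = nrow(ts)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "t / T_c", y = NULL,
                  title = "Phase-averaged ventricular hemodynamics")
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Write a hemodynamic summary to CSV + JSON
#'
#' @param x a `hemodynamic_summary`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_summary <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$time_series, file.path(dir, "time_series.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(EDV = x$EDV, ESV = x$ESV, SV = x$SV, EF = x$EF, T_c = x$T_c,
         AWSS = x$AWSS, mean_osi = mean(x$osi[x$osi_included]),
         osi_per_cycle = x$osi_per_cycle,
         work_per_volume = x$work_per_volume,
         Re = x$diagnostics$Re, CFL = x$diagnostics$CFL,
         U_p = x$diagnostics$U_p, D_i = x$diagnostics$D_i,
         n_remesh = x$n_remesh),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
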