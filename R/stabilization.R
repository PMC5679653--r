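# Element metric tensors and VMS stabilization parameters.
#
# For the affine map of a P1 simplex, G_ij = sum_k dxi_k/dx_i dxi_k/dx_j and
# g_i = sum_j dxi_j/dx_i are computed from the inverse element Jacobian; the
# stabilization scales are
#   tau_M = (C_t/dt^2 + a.Ga + C_I (mu/rho)^2 G:G)^(-1/2),  a = v - vhat
#   tau_C = (tau_M g.g)^(-1)
#   tau_B = (tau_M r_M . G tau_M r_M)^(-1/2)
# so tau_C * tau_M * (g.g) = 1 identically.

# per-element inverse-map metrics: G (d x d x ne) and g (ne x d)
element_metrics <- function(nodes, elems) {
  d <- ncol(nodes)
  ne <- nrow(elems)
  G <- array(0, c(d, d, ne))
  g <- matrix(0, ne, d)
  for (e in seq_len(ne)) {
    X <- nodes[elems[e, ], , drop = FALSE]
    Jm <- t(X[-1, , drop = FALSE]) - X[1, ]   # columns are edge vectors
    A <- solve(Jm)                            # rows: dxi_k/dx
    G[, , e] <- t(A) %*% A
    g[e, ] <- colSums(A)
  }
  list(G = G, g = g)
}

#' VMS stabilization parameters for one element
#'
#' @param G the d x d element metric tensor (symmetric positive definite).
#' @param g the element metric vector.
#' @param v,vhat fluid and mesh velocity at the evaluation point.
#' @param dt time-step size (s).
#' @param config a [solver_config()] (supplies `rho`, `mu`, `Ct`, `CI`).
#' @param r_M optional momentum residual vector; `tau_B` is `NA` without it.
#' @return list with `tau_M`, `tau_C`, `tau_B`.
#' @export
stabilization_params <- function(G, g, v, vhat, dt, config, r_M = NULL) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) || !all(is.finite(ev)))
    stop_hf("degenerate element metric tensor G")
  a <- v - vhat
  nu <- config$mu * config$viscosity_scale / config$rho
  tau_M <- 1 / sqrt(config$Ct / dt^2 + sum(a * (G %*% a)) + config$CI * nu^2 * sum(G * G))
  tau_C <- 1 / (tau_M * sum(g * g))
  tau_B <- NA_real_
  if (!is.null(r_M)) {
    tmr <- tau_M * r_M
    s <- sum(tmr * (G %*% tmr))
    tau_B <- if (s > 1e-24) 1 / sqrt(s) else 0
  }
  list(tau_M = tau_M, tau_C = tau_C, tau_B = tau_B)
}

#' Backflow stabilization traction
#'
#' The traction modification added on Neumann boundaries,
#' `-rho * beta * (v.n)_- * v` with `(.)_- = min(., 0)`: zero for outflow,
#' and a stabilizing reaction of magnitude `rho*beta*u^2` for a normal
#' inflow of speed `u`.
#'
#' @param v velocity row vector (or matrix of rows).
#' @param n unit outward normal (vector, or matrix of rows).
#' @param beta backflow coefficient in `[0, 1]`.
#' @param rho fluid density.
#' @return traction vector(s), same shape as `v`.
#' @export
backflow_term <- function(v, n, beta, rho) {
  v <- rbind(v); n <- rbind(n)
  vn <- rowSums(v * n)
  out <- -rho * beta * pmin(vn, 0) * v
  dimnames(out) <- NULL
  out
}
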