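# Element metric tensors and VMS stabilization scales.

test_that("right triangle with legs h has G = I/h^2 and g.g = 2/h^2", {
  h <- 0.25
  nodes <- rbind(c(0, 0), c(h, 0), c(0, h))
  em <- hemoflow:::element_metrics(nodes, rbind(c(1, 2, 3)))
  expect_equal(em$G[, , 1], diag(2) / h^2, tolerance = 1e-12)
  expect_equal(sum(em$g[1, ]^2), 2 / h^2, tolerance = 1e-12)
})

test_that("tau_M limits to h^2/(nu*sqrt(2*CI)) for v = vhat and dt -> infinity", {
  h <- 0.25
  G <- diag(2) / h^2
  g <- c(1, 1) / h
  cfg <- solver_config(rho = 1.2, mu = 0.05, Ct = 4, CI = 36)
  nu <- 0.05 / 1.2
  st <- stabilization_params(G, g, v = c(3, 1), vhat = c(3, 1), dt = 1e12,
                             config = cfg)
  expect_equal(st$tau_M, h^2 / (nu * sqrt(2 * cfg$CI)), tolerance = 1e-10)
})

test_that("tau_C * tau_M * (g.g) = 1 identically; tau_B follows its definition", {
  set.seed(4)
  for (k in 1:10) {
    A <- matrix(rnorm(4), 2)
    G <- crossprod(A) + diag(2) * 0.1
    g <- rnorm(2)
    cfg <- solver_config()
    rM <- rnorm(2)
    st <- stabilization_params(G, g, rnorm(2), rnorm(2), dt = 0.01,
                               config = cfg, r_M = rM)
    expect_equal(st$tau_C * st$tau_M * sum(g^2), 1, tolerance = 1e-12)
    tmr <- st$tau_M * rM
    expect_equal(st$tau_B, 1 / sqrt(sum(tmr * (G %*% tmr))), tolerance = 1e-12)
    expect_true(st$tau_M > 0 && st$tau_C > 0 && st$tau_B > 0)
  }
})

test_that("tau_M decreases as the convective velocity |v - vhat| grows", {
  G <- diag(2) * 16
  g <- c(4, 4)
  cfg <- solver_config()
  taus <- vapply(c(0, 1, 5, 25), function(s)
    stabilization_params(G, g, v = c(s, 0), vhat = c(0, 0), dt = 0.01,
                         config = cfg)$tau_M, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("degenerate metric tensors are rejected", {
  expect_error(stabilization_params(matrix(0, 2, 2), c(1, 1), c(0, 0), c(0, 0),
                                    0.01, solver_config()), "degenerate")
})

test_that("backflow traction is zero for outflow and rho*beta*u^2 for normal inflow", {
  expect_equal(backflow_term(c(2, 0), c(1, 0), 0.3, 1.06), rbind(c(0, 0)))
  u <- 1.7
  tr <- backflow_term(c(-u, 0), c(1, 0), 0.3, 1.06)
  expect_equal(vnorm <- sqrt(sum(tr^2)), 1.06 * 0.3 * u^2, tolerance = 1e-12)
})
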