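# Wall shear stress, OSI, energy metrics, contractility, phase averaging.

test_that("linear shear u = (gamma*y, 0) gives |tau_w| = mu*gamma exactly on flat walls", {
  mesh <- mesh_rectangle(6, 6, 1, 1)
  gam <- 2.3; mu <- 0.04
  v <- cbind(gam * mesh$nodes[, 2], 0)
  w <- wall_shear_stress(v, mesh, mu)
  sel <- w$labels %in% c("bottom", "top")
  expect_equal(row_norms(w$vectors[sel, , drop = FALSE]),
               rep(mu * gam, sum(sel)), tolerance = 1e-12)
  # tangency: tau_w . n = 0 on every facet
  dots <- abs(rowSums(w$vectors * w$normals)) /
    pmax(row_norms(w$vectors), 1e-30)
  expect_lt(max(dots), 1e-12)
})

test_that("AAWSS equals the brute-force area-weighted sum", {
  set.seed(21)
  nf <- 40
  vecs <- matrix(rnorm(nf * 3), nf, 3)
  areas <- runif(nf, 0.1, 2)
  include <- rep(c(TRUE, FALSE), each = 20)
  got <- aawss(list(vectors = vecs, areas = areas, include = include))
  oracle <- 0
  for (f in which(include)) oracle <- oracle + sqrt(sum(vecs[f, ]^2)) * areas[f]
  oracle <- oracle / sum(areas[include])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(aawss(list(vectors = vecs, areas = areas,
                          include = rep(FALSE, nf))), "zero included")
})

test_that("constant shear gives AAWSS = AWSS = tau0; masking matters iff caps carry shear", {
  tau0 <- 1.7
  nt <- 9; nf <- 12
  fld <- structure(list(
    times = seq(0, 0.4, length.out = nt),
    vectors = replicate(nt, cbind(rep(tau0, nf), 0), simplify = FALSE),
    areas = replicate(nt, rep(0.5, nf), simplify = FALSE),
    labels = rep(c("wall", "inlet_cap"), times = c(9, 3)),
    include = rep(c(TRUE, FALSE), times = c(9, 3)), d = 2L),
    class = "wall_shear_field")
  expect_equal(unname(aawss(fld)[1]), tau0)
  expect_equal(awss(fld), tau0)
  # zero the cap shear: including or excluding caps now changes the average
  fld2 <- fld
  fld2$vectors <- lapply(fld2$vectors, function(v) { v[10:12, 1] <- 0; v })
  all_in <- fld2; all_in$include <- rep(TRUE, nf)
  expect_equal(awss(fld2), tau0)
  expect_lt(awss(all_in), tau0)
})

test_that("OSI: aligned history 0, perfect reversal 0.5, random histories within [0, 0.5]", {
  t <- seq(0, 1, length.out = 64)
  aligned <- cbind(1 + 0.5 * sin(2 * pi * t), 0, 0)
  expect_equal(osi(aligned, t), 0)
  square <- cbind(rep(c(1, -1), each = 32), 0, 0)
  expect_equal(osi(square, t), 0.5, tolerance = 1e-12)
  expect_equal(osi(matrix(0, 64, 3), t), 0)  # documented all-zero convention
  set.seed(99)
  vals <- replicate(300, osi(matrix(rnorm(64 * 3), 64, 3), t))
  expect_true(all(vals >= 0 & vals <= 0.5))
})

test_that("OSI quadrature is consistent under temporal refinement", {
  f <- function(t) cbind(sin(2 * pi * t) + 0.3, cos(2 * pi * t), 0.2 * t)
  t64 <- seq(0, 1, length.out = 64)
  t128 <- seq(0, 1, length.out = 128)
  expect_lt(abs(osi(f(t64), t64) - osi(f(t128), t128)), 1e-3)
})

test_that("energy metrics: uniform flow, simple shear, and a dense quadrature oracle", {
  mesh <- mesh_rectangle(5, 7, 1.3, 0.8)
  rho <- 1.06; mu <- 0.04
  vuni <- matrix(c(3, -1), nrow(mesh$nodes), 2, byrow = TRUE)
  em <- energy_metrics(vuni, mesh, rho, mu)
  expect_equal(em$ke, 0.5 * rho * 10, tolerance = 1e-12)
  expect_equal(em$phi, 0, tolerance = 1e-12)
  gam <- 1.9
  vsh <- cbind(gam * mesh$nodes[, 2], 0)
  expect_equal(energy_metrics(vsh, mesh, rho, mu)$phi, mu * gam^2 / 2,
               tolerance = 1e-12)
  # arbitrary nodal field vs an element-loop quadrature oracle
  set.seed(5)
  v <- matrix(rnorm(nrow(mesh$nodes) * 2), ncol = 2)
  em2 <- energy_metrics(v, mesh, rho, mu)
  qp <- rbind(c(.5, .5, 0), c(0, .5, .5), c(.5, 0, .5)); wq <- rep(1 / 3, 3)
  keo <- phio <- 0
  vols <- element_volumes(mesh)
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]
    X <- mesh$nodes[en, ]
    A <- solve(t(X[-1, ]) - X[1, ])
    gradN <- rbind(-colSums(A), A)
    gv <- t(v[en, ]) %*% gradN
    gs <- (gv + t(gv)) / 2
    phio <- phio + vols[e] * mu * sum(gs * gs)
    for (q in 1:3)
      keo <- keo + wq[q] * vols[e] * 0.5 * rho * sum(colSums(qp[q, ] * v[en, ])^2)
  }
  V <- sum(vols)
  expect_equal(em2$ke, keo / V, tolerance = 1e-10)
  expect_equal(em2$phi, phio / V, tolerance = 1e-10)
})

test_that("contractility indices follow their definitions", {
  ctr <- contractility(c(2, 1))
  expect_equal(ctr$SV, 1)
  expect_equal(ctr$EF, 50)
  flat <- contractility(rep(3, 10))
  expect_equal(flat$SV, 0)
  expect_equal(flat$EF, 0)
  expect_error(contractility(c(1, -2, 3)), "non-positive")
})

test_that("cardiac work per unit volume converts printed pressures to CGS", {
  expect_equal(cardiac_work_per_volume(1, 0), 1333.22)
  expect_equal(cardiac_work_per_volume(0.3, 0.3), 0)
  expect_equal(cardiac_work_per_volume(0.47, 0.08), 519.9558, tolerance = 1e-6)
  expect_error(cardiac_work_per_volume(0.1, 0.4), "smaller")
})

test_that("phase averaging drops the first cycle and averages the rest", {
  # exactly periodic input: the average equals any single cycle
  cyc <- sin(seq(0, 2 * pi, length.out = 21))[-21]
  x <- rep(cyc, 4)
  expect_equal(phase_average(x, 4), cyc)
  expect_equal(phase_average(rep(2.5, 40), 4), rep(2.5, 10))
  # randomized cycles vs a direct loop oracle over cycles 2..4
  set.seed(13)
  xs <- matrix(rnorm(4 * 15), ncol = 1)
  got <- phase_average(as.vector(xs), 4)
  oracle <- (xs[16:30] + xs[31:45] + xs[46:60]) / 3
  expect_equal(got, as.vector(oracle))
  expect_error(phase_average(1:10, 1), ">= 2 cycles")
  # ragged cycles are resampled to a common grid
  rag <- list(seq(0, 1, length.out = 11), seq(0, 1, length.out = 21),
              seq(0, 1, length.out = 21))
  expect_equal(as.vector(phase_average(rag, 3)), seq(0, 1, length.out = 21))
})

test_that("volume_from_surface: cube exact, fine sphere within 1%", {
  cube <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
          c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
          c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
          c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8)))
  expect_equal(volume_from_surface(cube), 1, tolerance = 1e-12)
  sph <- icosphere(4, radius = 2)   # 5120 facets
  expect_gt(nrow(sph$facets), 5000)
  expect_equal(volume_from_surface(sph), 4 / 3 * pi * 8, tolerance = 0.01)
  open_surf <- surface_mesh(cube$vertices, cube$facets[-1, ])
  expect_error(volume_from_surface(open_surf), "watertight")
})

test_that("AWSS is the time average of AAWSS on a fixed-area history", {
  set.seed(7)
  nt <- 11; nf <- 8
  t <- seq(0, 0.4, length.out = nt)
  areas <- rep(0.3, nf)
  vecs <- lapply(seq_len(nt), function(k) matrix(rnorm(nf * 2), nf, 2))
  fld <- structure(list(times = t, vectors = vecs,
                        areas = replicate(nt, areas, simplify = FALSE),
                        labels = rep("wall", nf), include = rep(TRUE, nf),
                        d = 2L), class = "wall_shear_field")
  aa <- as.numeric(aawss(fld))
  expect_equal(awss(fld), hemoflow:::trapz(t, aa) / (t[nt] - t[1]),
               tolerance = 1e-12)
})
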