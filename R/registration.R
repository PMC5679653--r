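# Intensity-based non-rigid registration: SSD similarity + cubic B-spline
# free-form deformation + gradient regularization, minimized by gradient
# descent with a backtracking line search inside a coarse-to-fine
# multiresolution schedule (image downsampled x2 per level, control lattice
# refined x2 per level).

#' Registration configuration
#'
#' @param lambda regularization weight trading image-alignment accuracy
#'   against deformation smoothness.
#' @param n_levels number of multiresolution levels (coarse to fine).
#' @param knot_spacing_px control-point (knot) spacing in pixels, applied at
#'   every level of the refined lattice.
#' @param tol relative objective-change convergence tolerance per level.
#' @param max_iters maximum accepted descent iterations per level.
#' @return a `registration_config`.
#' @export
registration_config <- function(lambda = 0.1, n_levels = 4L,
                                knot_spacing_px = 5, tol = 1e-8,
                                max_iters = 200L) {
  assert_that(lambda >= 0, "lambda must be nonnegative")
  assert_that(n_levels >= 1, "n_levels must be at least 1")
  assert_that(tol > 0, "tol must be positive")
  structure(list(lambda = lambda, n_levels = as.integer(n_levels),
                 knot_spacing_px = knot_spacing_px, tol = tol,
                 max_iters = as.integer(max_iters)),
            class = "registration_config")
}

#' Registration objective and its components
#'
#' Computes `E_obj = E_sim + lambda * E_reg` for a fixed image `I`, moving
#' image `J` and transform `T`:  `E_sim` is the mean squared intensity
#' difference between `I` and the warped `J`, `E_reg` one half the squared
#' norm of the displacement-field gradient.
#'
#' @param I,J fixed and moving image arrays (same dimensions).
#' @param transform a [bspline_transform()].
#' @param lambda regularization weight.
#' @return list with `esim`, `ereg`, `eobj`.
#' @export
registration_objective <- function(I, J, transform, lambda = 0.1) {
  assert_that(identical(dim(I), dim(J)), "image dimension mismatch")
  assert_that(identical(as.integer(dim(I)), transform$dims),
              "transform does not match image dimensions")
  gradJ <- image_gradient(J)
  out <- ffd_objective_cpp(as.vector(I), as.vector(J),
                           lapply(gradJ, as.vector), transform$dims,
                           transform$coef, transform$knot_spacing, lambda, FALSE)
  out[c("esim", "ereg", "eobj")]
}

# single-level gradient descent with backtracking line search:
# halve the step on an objective increase, accept on decrease, mild growth
# after acceptance; stop on relative objective change < tol.
optimize_level <- function(I, J, coef, delta, lambda, tol, max_iters) {
  dims <- as.integer(dim(I))
  gradJ <- lapply(image_gradient(J), as.vector)
  Iv <- as.vector(I); Jv <- as.vector(J)
  ob <- ffd_objective_cpp(Iv, Jv, gradJ, dims, coef, delta, lambda, TRUE)
  E <- ob$eobj
  if (!is.finite(E))
    stop_hf("non-finite registration objective at start (esim=%g, ereg=%g)",
            ob$esim, ob$ereg)
  g <- ob$grad
  gmax <- max(abs(g))
  if (gmax == 0) return(list(coef = coef, value = E, iters = 0L))
  step <- 0.4 / gmax          # first trial moves at most 0.4 px
  iters <- 0L
  while (iters < max_iters) {
    cand <- coef - step * g
    Ec <- ffd_objective_cpp(Iv, Jv, gradJ, dims, cand, delta, lambda, FALSE)$eobj
    if (!is.finite(Ec))
      stop_hf("non-finite registration objective (step %g, iter %d)", step, iters)
    if (Ec < E) {
      rel <- (E - Ec) / max(abs(E), .Machine$double.xmin)
      coef <- cand
      E <- Ec
      iters <- iters + 1L
      if (rel < tol) break
      ob <- ffd_objective_cpp(Iv, Jv, gradJ, dims, coef, delta, lambda, TRUE)
      g <- ob$grad
      gmax <- max(abs(g))
      if (gmax == 0) break
      step <- step * 1.2
    } else {
      step <- step / 2
      if (step * gmax < 1e-9) break   # line search exhausted
    }
  }
  list(coef = coef, value = E, iters = iters)
}

# crop a dyadically refined lattice to the lattice required for `dims`
crop_refined <- function(coef, dims, delta) {
  d <- length(dims)
  K <- pmax(ceiling((dims - 1) / delta), 1L)
  idx <- lapply(seq_len(d), function(ax) {
    want <- K[ax] + 3L
    pmin(seq(2L, length.out = want), dim(coef)[ax])
  })
  do.call(`[`, c(list(coef), idx, list(seq_len(d)), list(drop = FALSE)))
}

#' Register a pair of images with a B-spline free-form deformation
#'
#' Minimizes `E_sim + lambda*E_reg` by gradient descent with backtracking,
#' using a hierarchical multiresolution approach: the image is downsampled
#' by 2 per level and the control lattice is refined by 2 per level, coarse
#' to fine.  The returned transform maps fixed-image coordinates to the
#' corresponding moving-image coordinates, `T(x) = x + u(x)`.
#'
#' @param fixed,moving image arrays of identical dimensions.
#' @param config a [registration_config()].
#' @param init optional initial [bspline_transform()] on the full-resolution
#'   grid (used to warm-start sequential tracking).
#' @return a [bspline_transform()] with attributes `objective` (final
#'   objective components) and `history` (per-level iteration counts and
#'   values).
#' @export
register_pair <- function(fixed, moving, config = registration_config(),
                          init = NULL) {
  assert_that(identical(dim(fixed), dim(moving)), "image dimension mismatch")
  dims <- as.integer(dim(fixed))
  d <- length(dims)
  delta <- config$knot_spacing_px

  history <- list()
  if (!is.null(init)) {
    # warm start (sequential tracking): the remaining deformation is small,
    # so optimize at full resolution only, starting from the given transform
    assert_that(identical(init$dims, dims) && init$knot_spacing == delta,
                "init transform does not match image dims / knot spacing")
    res <- optimize_level(fixed, moving, init$coef, delta, config$lambda,
                          config$tol, config$max_iters)
    coef <- res$coef
    history[[1L]] <- list(level = 1L, dims = dims, value = res$value,
                          iters = res$iters)
  } else {
    # image pyramid, fine to coarse; drop levels that are too coarse
    pyrI <- list(fixed); pyrJ <- list(moving)
    L <- 1L
    while (L < config$n_levels && all(dim(pyrI[[L]]) %/% 2L >= 12L)) {
      pyrI[[L + 1L]] <- downsample2(pyrI[[L]])
      pyrJ[[L + 1L]] <- downsample2(pyrJ[[L]])
      L <- L + 1L
    }
    coef <- NULL
    for (lev in rev(seq_len(L))) {
      Il <- pyrI[[lev]]; Jl <- pyrJ[[lev]]
      dl <- as.integer(dim(Il))
      Kl <- pmax(ceiling((dl - 1) / delta), 1L)
      coef <- if (is.null(coef)) array(0, c(Kl + 3L, d))
              else crop_refined(2 * refine_lattice(coef), dl, delta)
      res <- optimize_level(Il, Jl, coef, delta, config$lambda, config$tol,
                            config$max_iters)
      coef <- res$coef
      history[[length(history) + 1L]] <- list(level = lev, dims = dl,
                                              value = res$value, iters = res$iters)
    }
  }

  tr <- bspline_transform(dims, delta, coef)
  attr(tr, "objective") <- registration_objective(fixed, moving, tr, config$lambda)
  attr(tr, "history") <- history
  tr
}
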