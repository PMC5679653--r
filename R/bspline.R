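# Cubic B-spline free-form deformation transforms.
#
# A transform stores per-axis displacement coefficients on a control-point
# lattice with uniform knot spacing (in voxels).  Zero coefficients give the
# identity map; by the partition of unity of the cubic basis, uniform
# coefficients translate every interior point by exactly that amount.

#' Create a cubic B-spline free-form deformation transform
#'
#' @param dims image dimensions (voxels per axis) the transform is defined on.
#' @param knot_spacing control-point (knot) spacing in voxels.
#' @param coef optional coefficient array of dimension
#'   `c(n_cp_per_axis, n_axes)`; zero (identity) if omitted.
#' @return a `bspline_transform`.
#' @export
bspline_transform <- function(dims, knot_spacing = 5, coef = NULL) {
  dims <- as.integer(dims)
  d <- length(dims)
  assert_that(d %in% c(2L, 3L), "only 2-D and 3-D transforms are supported")
  assert_that(knot_spacing > 0, "knot_spacing must be positive")
  K <- pmax(ceiling((dims - 1) / knot_spacing), 1L)
  cdim <- c(K + 3L, d)
  if (is.null(coef)) coef <- array(0, cdim)
  assert_that(identical(as.integer(dim(coef)), as.integer(cdim)),
              "coef must have dimension (%s)", paste(cdim, collapse = ", "))
  structure(list(dims = dims, d = d, knot_spacing = knot_spacing,
                 n_spans = K, coef = coef),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf("bspline_transform: %d-D, lattice %s, knot spacing %g px, max|u| = %.3g px\n",
              x$d, paste(head(dim(x$coef), -1), collapse = "x"),
              x$knot_spacing, max(abs(x$coef))))
  invisible(x)
}

#' Evaluate B-spline displacements at points
#'
#' Points outside the image domain are evaluated with the lattice support
#' clamped (a warning reports how many were clamped).
#'
#' @param transform a [bspline_transform()].
#' @param points n x d matrix of voxel coordinates (0-based).
#' @return n x d matrix of displacements in voxels.
#' @export
bspline_displacement <- function(transform, points) {
  points <- as.matrix(points)
  assert_that(ncol(points) == transform$d, "points must have %d columns", transform$d)
  out <- ffd_eval_points_cpp(transform$coef, transform$knot_spacing,
                             points, as.numeric(transform$dims))
  ncl <- attr(out, "clamped")
  if (!is.null(ncl) && ncl > 0)
    warning(sprintf("%d point(s) outside the lattice support were clamped", ncl),
            call. = FALSE)
  attr(out, "clamped") <- NULL
  out
}

# displacement at every voxel centre (column-major order)
bspline_grid_displacement <- function(transform) {
  ffd_eval_grid_cpp(transform$coef, transform$knot_spacing, transform$dims)
}

#' Map points through a B-spline transform (x + u(x))
#' @inheritParams bspline_displacement
#' @return n x d matrix of mapped voxel coordinates.
#' @export
bspline_map <- function(transform, points) {
  as.matrix(points) + bspline_displacement(transform, points)
}

#' Warp an image through a B-spline transform
#'
#' Resamples `J` at `x + u(x)` with linear interpolation and nearest-edge
#' border fill, i.e. computes the moving image term of the similarity
#' functional.
#'
#' @param J image array (matching the transform's dimensions).
#' @param transform a [bspline_transform()].
#' @return the warped image array.
#' @export
warp_image <- function(J, transform) {
  assert_that(identical(as.integer(dim(J)), transform$dims),
              "image dimensions do not match the transform")
  disp <- bspline_grid_displacement(transform)
  out <- warp_linear_cpp(as.vector(J), transform$dims, disp)
  dim(out) <- dim(J)
  out
}

#' Sum-of-squared-differences similarity between two images
#'
#' `mean((I - J)^2)`: nonnegative, zero iff the images are identical.
#'
#' @param I,J image arrays of identical dimensions.
#' @return scalar SSD value.
#' @export
ssd_similarity <- function(I, J) {
  if (!identical(dim(I), dim(J)))
    stop_hf("image dimension mismatch: (%s) vs (%s)",
            paste(dim(I), collapse = ","), paste(dim(J), collapse = ","))
  mean((I - J)^2)
}

#' Regularization energy of a B-spline transform
#'
#' One half the squared norm of the displacement-field gradient, evaluated
#' by forward differences and averaged over the voxel grid (voxel units),
#' so that it shares the per-voxel scale of the SSD similarity and the
#' trade-off weight lambda is dimensionless.  Zero iff the displacement
#' field is spatially constant.
#'
#' @param transform a [bspline_transform()].
#' @return nonnegative scalar.
#' @export
regularization_energy <- function(transform) {
  u <- bspline_grid_displacement(transform)
  dims <- transform$dims
  d <- transform$d
  e <- 0
  for (c in seq_len(d)) {
    uc <- array(u[, c], dims)
    for (ax in seq_len(d)) {
      n <- dims[ax]
      if (n < 2) next
      idx1 <- lapply(dims, seq_len); idx1[[ax]] <- 1:(n - 1)
      idx2 <- idx1; idx2[[ax]] <- 2:n
      dif <- do.call(`[`, c(list(uc), idx2)) - do.call(`[`, c(list(uc), idx1))
      e <- e + 0.5 * sum(dif^2)
    }
  }
  e / prod(dims)
}

# dyadic refinement of a uniform cubic B-spline coefficient lattice along
# every axis (exact subdivision), used by the multiresolution schedule
refine_lattice <- function(coef) {
  cd <- dim(coef)
  d <- length(cd) - 1L
  refine1 <- function(x) {
    n <- length(x)
    xe <- c(x[1], x, x[n])     # replicate ends for boundary stencils
    even <- (xe[1:n] + 6 * xe[2:(n + 1)] + xe[3:(n + 2)]) / 8
    odd <- (x[1:(n - 1)] + x[2:n]) / 2
    out <- numeric(2 * n - 1)
    out[seq(1, 2 * n - 1, by = 2)] <- even
    out[seq(2, 2 * n - 2, by = 2)] <- odd
    out
  }
  for (ax in seq_len(d)) {
    others <- setdiff(seq_len(d + 1), ax)
    coef <- apply(coef, others, refine1)  # refined axis comes first
    coef <- aperm(coef, match(seq_len(d + 1), c(ax, others)))
  }
  coef
}
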