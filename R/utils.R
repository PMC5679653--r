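# Internal helpers and unit constants.

# 1 mmHg in CGS pressure units (dyn/cm^2 = g/(cm s^2))
MMHG_TO_CGS <- 1333.22
UM_TO_CM <- 1e-4

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_hf(msg, ...)
  invisible(TRUE)
}

#' Convert a pressure difference in mmHg to CGS units
#'
#' @param p_mmhg pressure in mmHg
#' @return pressure in g/(cm s^2) (dyn/cm^2)
#' @keywords internal
mmhg_to_cgs <- function(p_mmhg) p_mmhg * MMHG_TO_CGS

# voxel-centre coordinates along each axis (0-based, voxel units)
grid_axes <- function(dims) lapply(dims, function(n) seq(0, n - 1))

# coordinates of every voxel centre as a matrix (column-major voxel order)
grid_coords <- function(dims) {
  ax <- grid_axes(dims)
  as.matrix(do.call(expand.grid, ax))
}

# block-mean downsample an array by a factor of 2 per axis
downsample2 <- function(img) {
  d <- length(dim(img))
  dm <- dim(img)
  nd <- pmax(dm %/% 2L, 1L)
  if (d == 2) {
    i1 <- seq_len(nd[1]) * 2L - 1L
    j1 <- seq_len(nd[2]) * 2L - 1L
    i2 <- pmin(i1 + 1L, dm[1])
    j2 <- pmin(j1 + 1L, dm[2])
    (img[i1, j1, drop = FALSE] + img[i2, j1, drop = FALSE] +
       img[i1, j2, drop = FALSE] + img[i2, j2, drop = FALSE]) / 4
  } else {
    i1 <- seq_len(nd[1]) * 2L - 1L
    j1 <- seq_len(nd[2]) * 2L - 1L
    k1 <- seq_len(nd[3]) * 2L - 1L
    i2 <- pmin(i1 + 1L, dm[1]); j2 <- pmin(j1 + 1L, dm[2]); k2 <- pmin(k1 + 1L, dm[3])
    (img[i1, j1, k1, drop = FALSE] + img[i2, j1, k1, drop = FALSE] +
       img[i1, j2, k1, drop = FALSE] + img[i2, j2, k1, drop = FALSE] +
       img[i1, j1, k2, drop = FALSE] + img[i2, j1, k2, drop = FALSE] +
       img[i1, j2, k2, drop = FALSE] + img[i2, j2, k2, drop = FALSE]) / 8
  }
}

# central-difference gradient components of an image (one array per axis)
image_gradient <- function(img) {
  d <- length(dim(img))
  out <- vector("list", d)
  for (ax in seq_len(d)) {
    n <- dim(img)[ax]
    idx_hi <- pmin(seq_len(n) + 1L, n)
    idx_lo <- pmax(seq_len(n) - 1L, 1L)
    sel <- function(i) {
      args <- rep(list(quote(expr = )), d)
      args[[ax]] <- i
      do.call(`[`, c(list(img), args, list(drop = FALSE)))
    }
    g <- (sel(idx_hi) - sel(idx_lo)) / (idx_hi - idx_lo)
    dim(g) <- dim(img)
    out[[ax]] <- g
  }
  out
}

# trapezoid weights for possibly non-uniform time samples
trapz_weights <- function(t) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

trapz <- function(t, y) sum(trapz_weights(t) * y)

vnorm <- function(x) sqrt(sum(x^2))
row_norms <- function(m) sqrt(rowSums(m^2))
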