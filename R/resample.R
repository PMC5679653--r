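# Isotropic resampling of star-shaped cavity surfaces: the extracted
# boundary (contour polygon or smoothed voxel-face triangulation) is
# re-sampled at a prescribed edge length as a radius function about the
# enclosed centroid - a uniform-angle polygon in 2-D, a subdivided
# icosahedron with direction-averaged radii in 3-D.

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param subdiv number of 4-to-1 subdivisions (0 = icosahedron).
#' @param radius sphere radius.
#' @param centre centre (length 3).
#' @return a `surface_mesh` with outward-oriented facets.
#' @export
icosphere <- function(subdiv = 3, radius = 1, centre = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    nv <- nrow(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / vnorm(m)
      v <<- rbind(v, m)
      id <- nrow(v)
      assign(key, id, envir = mid)
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(c, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  surface_mesh(sweep(v * radius, 2, centre, "+"), f)
}

# resample a star-shaped surface at edge length h about its enclosed
# centroid; returns a new all-wall surface_mesh
resample_star_surface <- function(surf, h) {
  ctr <- enclosed_centroid(surf)
  off <- sweep(surf$vertices, 2, ctr, "-")
  rad <- row_norms(off)
  Rm <- mean(rad)
  if (surf$d == 2) {
    th <- atan2(off[, 2], off[, 1])
    o <- order(th)
    ths <- th[o]; rs <- rad[o]
    # periodic extension for interpolation
    thp <- c(ths - 2 * pi, ths, ths + 2 * pi)
    rp <- c(rs, rs, rs)
    n <- max(16L, ceiling(2 * pi * Rm / h))
    tq <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
    rq <- approx(thp, rp, xout = tq)$y
    verts <- cbind(ctr[1] + rq * cos(tq), ctr[2] + rq * sin(tq))
    facets <- cbind(seq_len(n), c(2:n, 1L))
    surface_mesh(verts, facets, spacing_um = surf$spacing_um)
  } else {
    L <- max(1L, min(5L, ceiling(log2(1.0515 * Rm / h))))
    ico <- icosphere(L, 1, c(0, 0, 0))
    dirs <- ico$vertices
    u <- off / rad
    sigma <- 1.0515 / 2^L          # angular footprint of one edge
    # direction-weighted mean radius around each sample direction
    rq <- numeric(nrow(dirs))
    cosang <- tcrossprod(dirs, u)  # ndirs x nvert
    for (k in seq_len(nrow(dirs))) {
      ang <- acos(pmin(pmax(cosang[k, ], -1), 1))
      w <- exp(-(ang / sigma)^2)
      if (sum(w) < 1e-12) w <- as.numeric(ang <= min(ang) + 1e-9)
      rq[k] <- sum(w * rad) / sum(w)
    }
    verts <- sweep(dirs * rq, 2, ctr, "+")
    surface_mesh(verts, ico$facets, spacing_um = surf$spacing_um)
  }
}
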