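# Labeled watertight boundary surfaces of the cavity.
#
# 2-D: the boundary is a CCW polygon (facets are segments).  3-D: a closed
# triangulation built by voxel-face extraction from the segmentation mask and
# Taubin (non-shrinking) smoothing.  Orifices are opened at marker points,
# extruded by a short collar and capped, so inflow/outflow boundary
# conditions can be prescribed on planar faces away from the wall.

#' Construct a labeled surface mesh
#'
#' @param vertices nv x d matrix of physical coordinates (cm).
#' @param facets nf x d integer matrix (segments in 2-D, triangles in 3-D),
#'   consistently oriented with outward normals.
#' @param labels per-facet label (`wall`, `inlet_cap`, `outlet_cap`,
#'   `inlet_extrusion`, `outlet_extrusion`); defaults to `wall`.
#' @param spacing_um voxel spacing carried along for image-coordinate
#'   conversions (optional).
#' @return a `surface_mesh`.
#' @export
surface_mesh <- function(vertices, facets, labels = NULL, spacing_um = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  facets <- as.matrix(facets)
  dimnames(facets) <- NULL
  storage.mode(facets) <- "integer"
  d <- ncol(vertices)
  assert_that(d %in% c(2L, 3L), "vertices must be 2-D or 3-D")
  assert_that(ncol(facets) == d, "facets must have %d vertices each", d)
  if (is.null(labels)) labels <- rep("wall", nrow(facets))
  assert_that(length(labels) == nrow(facets), "one label per facet required")
  structure(list(vertices = vertices, facets = facets,
                 labels = as.character(labels), d = d,
                 spacing_um = spacing_um),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d-D, %d vertices, %d facets (%s)\n",
              x$d, nrow(x$vertices), nrow(x$facets),
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# per-facet unit outward normals, areas and centroids
facet_geometry <- function(surf) {
  v <- surf$vertices; f <- surf$facets
  if (surf$d == 2) {
    t_ <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    len <- row_norms(t_)
    n <- cbind(t_[, 2], -t_[, 1]) / len
    ctr <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE]) / 2
    list(normals = n, areas = len, centroids = ctr)
  } else {
    u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    a2 <- row_norms(cr)
    ctr <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
              v[f[, 3], , drop = FALSE]) / 3
    list(normals = cr / a2, areas = a2 / 2, centroids = ctr)
  }
}

# undirected edge list (3-D) as a 2-column matrix
surface_edges <- function(surf) {
  f <- surf$facets
  if (surf$d == 2) return(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  t(apply(e, 1, sort))
}

#' Is a surface watertight?
#'
#' In 3-D every edge must be shared by exactly two facets; in 2-D every
#' vertex referenced must bound exactly two segments.
#'
#' @param surf a `surface_mesh`.
#' @return logical.
#' @export
is_watertight <- function(surf) {
  if (surf$d == 2) {
    cnt <- tabulate(surf$facets, nbins = nrow(surf$vertices))
    all(cnt[unique(as.vector(surf$facets))] == 2L)
  } else {
    e <- surface_edges(surf)
    key <- paste(e[, 1], e[, 2])
    all(table(key) == 2L)
  }
}

#' Euler characteristic V - E + F of a surface mesh
#' @param surf a `surface_mesh` (3-D).
#' @return integer.
#' @export
euler_characteristic <- function(surf) {
  nv <- length(unique(as.vector(surf$facets)))
  e <- surface_edges(surf)
  ne <- nrow(unique(as.data.frame(e)))
  nv - ne + nrow(surf$facets)
}

#' Enclosed volume of a closed oriented surface
#'
#' Divergence theorem: `V = (1/d) * sum over facets of (x_c . n) * area`.
#' Fails for non-watertight surfaces; a negative result is rejected as an
#' inward-flipped (inconsistently oriented) surface.
#'
#' @param surf a `surface_mesh`.
#' @param signed return the signed value instead of failing when negative.
#' @return volume in cm^3 (area in cm^2 for 2-D).
#' @export
volume_from_surface <- function(surf, signed = FALSE) {
  if (!is_watertight(surf)) stop_hf("surface is not watertight")
  g <- facet_geometry(surf)
  V <- sum(rowSums(g$centroids * g$normals) * g$areas) / surf$d
  if (!signed && V < 0)
    stop_hf("negative enclosed volume: surface normals are inward-flipped")
  V
}

# mean facet edge length
mean_edge_length <- function(surf) {
  v <- surf$vertices; f <- surf$facets
  if (surf$d == 2) {
    mean(row_norms(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]))
  } else {
    e <- surface_edges(surf)
    mean(row_norms(v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE]))
  }
}

# ---- 3-D voxel-face extraction ----

# shift with FALSE padding (treat outside the array as background)
shift0 <- function(m, ax, dir) {
  dims <- dim(m)
  n <- dims[ax]
  idx <- lapply(dims, seq_len)
  out <- array(FALSE, dims)
  src <- lapply(dims, seq_len)
  if (dir > 0) { idx[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
  else { idx[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
  out_idx <- do.call(`[<-`, c(list(out), idx, list(do.call(`[`, c(list(m), src)))))
  out_idx
}

voxel_surface_3d <- function(mask) {
  dims <- dim(mask)
  nxc <- dims + 1L  # corner grid
  corner_id <- function(cx, cy, cz) 1L + cx + nxc[1] * (cy + nxc[2] * cz)
  quads <- list()
  # offsets of the 4 quad corners in the (a1, a2) plane for each axis,
  # ordered CCW about the outward (+) direction
  for (ax in 1:3) {
    for (s in c(1L, -1L)) {
      expose <- mask & !shift0(mask, ax, -s)  # neighbour in +s direction empty
      idx <- which(expose, arr.ind = TRUE) - 1L  # 0-based voxel indices
      if (nrow(idx) == 0) next
      # right-handed in-plane axes so the winding is CCW about +ax
      oth <- switch(ax, c(2L, 3L), c(3L, 1L), c(1L, 2L))
      # face plane corner coordinate along ax
      cax <- idx[, ax] + (s + 1L) / 2L  # s=+1 -> i+1 ; s=-1 -> i
      off <- if (s > 0) rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
             else rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
      corn <- matrix(0L, nrow(idx), 4)
      for (k in 1:4) {
        cc <- matrix(0L, nrow(idx), 3)
        cc[, ax] <- cax
        cc[, oth[1]] <- idx[, oth[1]] + off[k, 1]
        cc[, oth[2]] <- idx[, oth[2]] + off[k, 2]
        corn[, k] <- corner_id(cc[, 1], cc[, 2], cc[, 3])
      }
      quads[[length(quads) + 1L]] <- corn
    }
  }
  quads <- do.call(rbind, quads)
  used <- sort(unique(as.vector(quads)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  tri <- rbind(cbind(quads[, 1], quads[, 2], quads[, 3]),
               cbind(quads[, 1], quads[, 3], quads[, 4]))
  tri <- matrix(remap[tri], ncol = 3)
  id0 <- used - 1L
  verts <- cbind(id0 %% nxc[1], (id0 %/% nxc[1]) %% nxc[2],
                 id0 %/% (nxc[1] * nxc[2])) - 0.5  # corner -> voxel coords
  list(vertices = verts, facets = tri)
}

# Taubin non-shrinking smoothing (lambda/mu passes)
taubin_smooth <- function(vertices, facets, iters = 10, lambda = 0.5, mu = -0.53) {
  if (iters <= 0) return(vertices)
  nv <- nrow(vertices)
  e <- rbind(facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- vertices
  for (it in seq_len(iters)) {
    V <- V + lambda * (as.matrix(A %*% V) / deg - V)
    V <- V + mu * (as.matrix(A %*% V) / deg - V)
  }
  V
}

# ---- 2-D contour extraction ----

contour_polygon_2d <- function(mask) {
  dims <- dim(mask)
  cl <- grDevices::contourLines(x = seq(0, dims[1] - 1), y = seq(0, dims[2] - 1),
                                z = mask * 1, levels = 0.5)
  assert_that(length(cl) > 0, "no boundary contour found")
  lens <- vapply(cl, function(c) length(c$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  poly <- cbind(cc$x, cc$y)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  # enforce CCW orientation (positive shoelace area)
  a2 <- sum(poly[, 1] * poly[c(2:nrow(poly), 1), 2] -
              poly[c(2:nrow(poly), 1), 1] * poly[, 2])
  if (a2 < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  poly
}

#' Extract a watertight labeled cavity surface from a segmentation mask
#'
#' Builds the cavity boundary (isocontour polygon in 2-D; voxel-face
#' triangulation with Taubin smoothing in 3-D), then opens an orifice at
#' each marker, extrudes it by a short collar (twice the mean edge length)
#' and caps it with planar facets.
#'
#' @param mask logical cavity mask.
#' @param spacing_um voxel spacing (micrometres per axis).
#' @param orifice_markers 2 x d matrix of marker points in voxel
#'   coordinates, rows named or ordered `inlet`, `outlet`; `NULL` keeps the
#'   surface closed and unlabeled (all `wall`).
#' @param smooth_iters Taubin smoothing iterations (3-D).
#' @param orifice_radius opening radius in cm; defaults to 30% of the mean
#'   centre-to-boundary distance.
#' @param target_edge isotropically resample the (star-shaped) surface at
#'   this edge length (cm) before capping; `NULL` keeps the raw
#'   voxel-resolution boundary.
#' @return a `surface_mesh` in physical coordinates (cm).
#' @export
extract_surface <- function(mask, spacing_um, orifice_markers = NULL,
                            smooth_iters = 10, orifice_radius = NULL,
                            target_edge = NULL) {
  assert_that(any(mask), "empty mask")
  d <- length(dim(mask))
  sp_cm <- spacing_um * UM_TO_CM
  if (d == 2) {
    poly <- contour_polygon_2d(mask)
    verts <- sweep(poly, 2, sp_cm, "*")
    n <- nrow(verts)
    facets <- cbind(seq_len(n), c(2:n, 1L))
    surf <- surface_mesh(verts, facets, spacing_um = spacing_um)
  } else {
    vs <- voxel_surface_3d(mask)
    v <- taubin_smooth(vs$vertices, vs$facets, iters = smooth_iters)
    verts <- sweep(v, 2, sp_cm, "*")
    surf <- surface_mesh(verts, vs$facets, spacing_um = spacing_um)
  }
  if (!is.null(target_edge))
    surf <- resample_star_surface(surf, target_edge)
  if (is.null(orifice_markers)) return(surf)
  assert_that(nrow(orifice_markers) == 2, "exactly 2 orifice markers required")
  nms <- rownames(orifice_markers) %||% c("inlet", "outlet")
  markers_cm <- sweep(as.matrix(orifice_markers), 2, sp_cm, "*")
  for (k in 1:2) {
    surf <- open_orifice(surf, markers_cm[k, ], nms[k],
                         orifice_radius = orifice_radius)
  }
  compact_surface(surf)
}

# drop vertices not referenced by any facet and remap indices
compact_surface <- function(surf) {
  used <- sort(unique(as.vector(surf$facets)))
  if (length(used) == nrow(surf$vertices)) return(surf)
  remap <- integer(nrow(surf$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(surf$vertices[used, , drop = FALSE],
               matrix(remap[surf$facets], ncol = ncol(surf$facets)),
               surf$labels, spacing_um = surf$spacing_um)
}

# open, extrude and cap one orifice around a marker point (physical coords)
open_orifice <- function(surf, marker, name, orifice_radius = NULL) {
  g <- facet_geometry(surf)
  ctr <- colMeans(surf$vertices)
  rad <- orifice_radius %||% (0.3 * mean(row_norms(sweep(surf$vertices, 2, ctr, "-"))))
  # marker must sit on the boundary
  dmin <- min(row_norms(sweep(g$centroids, 2, marker, "-")))
  if (dmin > 3 * mean_edge_length(surf) + rad / 2)
    stop_hf("orifice marker '%s' does not lie on the surface (distance %.3g cm)",
            name, dmin)
  near_v <- which.min(row_norms(sweep(surf$vertices, 2, marker, "-")))
  centre <- surf$vertices[near_v, ]
  rm <- which(row_norms(sweep(g$centroids, 2, centre, "-")) < rad &
                surf$labels == "wall")
  assert_that(length(rm) > 0, "orifice radius too small: no facets removed")
  nhat <- colSums(g$normals[rm, , drop = FALSE] * g$areas[rm])
  nhat <- nhat / vnorm(nhat)
  collar <- 2 * mean_edge_length(surf)

  if (surf$d == 2) {
    open_orifice_2d(surf, rm, nhat, collar, name)
  } else {
    open_orifice_3d(surf, rm, nhat, collar, name)
  }
}

open_orifice_2d <- function(surf, rm, nhat, collar, name) {
  v <- surf$vertices; f <- surf$facets; lab <- surf$labels
  keep <- setdiff(seq_len(nrow(f)), rm)
  fk <- f[keep, , drop = FALSE]
  # gap endpoints: vertex counts drop to 1 on the rim
  cnt <- tabulate(fk, nbins = nrow(v))
  ends <- which(cnt == 1L)
  assert_that(length(ends) == 2, "orifice removal did not leave a single gap")
  # e_first ends a kept segment (appears as a segment head), e_last starts one
  e_first <- ends[ends %in% fk[, 2]]
  e_last <- ends[ends %in% fk[, 1]]
  assert_that(length(e_first) == 1 && length(e_last) == 1, "ambiguous orifice gap")
  n0 <- nrow(v)
  p1 <- v[e_first, ] + collar * nhat
  p2 <- v[e_last, ] + collar * nhat
  # subdivide the cap so it carries interior (non-ring) nodes; the
  # traction-free condition needs free test functions on the cap
  ncap <- max(2L, ceiling(vnorm(p2 - p1) / (collar / 2)))
  tseq <- seq(0, 1, length.out = ncap + 1)[-c(1, ncap + 1)]
  capv <- outer(1 - tseq, p1) + outer(tseq, p2)
  v <- rbind(v, p1, p2, capv)
  e1p <- n0 + 1L; e2p <- n0 + 2L
  cap_ids <- c(e1p, n0 + 2L + seq_len(ncap - 1L), e2p)
  newf <- rbind(c(e_first, e1p),
                cbind(cap_ids[-length(cap_ids)], cap_ids[-1]),
                c(e2p, e_last))
  newlab <- c(paste0(name, "_extrusion"), rep(paste0(name, "_cap"), ncap),
              paste0(name, "_extrusion"))
  surface_mesh(v, rbind(fk, newf), c(lab[keep], newlab),
               spacing_um = surf$spacing_um)
}

open_orifice_3d <- function(surf, rm, nhat, collar, name) {
  v <- surf$vertices; f <- surf$facets; lab <- surf$labels
  keep <- setdiff(seq_len(nrow(f)), rm)
  fk <- f[keep, , drop = FALSE]
  # rim half-edges: appear once in kept facets (with kept-facet orientation)
  he <- rbind(fk[, c(1, 2)], fk[, c(2, 3)], fk[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  once <- names(which(table(key) == 1L))
  rimhe <- he[key %in% once, , drop = FALSE]
  assert_that(nrow(rimhe) >= 3, "orifice rim not found")
  n0 <- nrow(v)
  rimv <- sort(unique(as.vector(rimhe)))
  map_up <- integer(nrow(v)); map_up[rimv] <- n0 + seq_along(rimv)
  v <- rbind(v, sweep(v[rimv, , drop = FALSE], 2, collar * nhat, "+"))
  cap_ctr <- colMeans(v[map_up[rimv], , drop = FALSE])
  v <- rbind(v, cap_ctr)
  cidx <- nrow(v)
  side <- NULL; caps <- NULL
  for (k in seq_len(nrow(rimhe))) {
    a <- rimhe[k, 1]; b <- rimhe[k, 2]
    ap <- map_up[a]; bp <- map_up[b]
    side <- rbind(side, c(b, a, ap), c(b, ap, bp))
    caps <- rbind(caps, c(cidx, bp, ap))
  }
  # orient cap facets along the outward extrusion direction
  for (k in seq_len(nrow(caps))) {
    tri <- caps[k, ]
    u <- v[tri[2], ] - v[tri[1], ]; w <- v[tri[3], ] - v[tri[1], ]
    nn <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    if (sum(nn * nhat) < 0) caps[k, ] <- tri[c(1, 3, 2)]
  }
  newf <- rbind(side, caps)
  newlab <- c(rep(paste0(name, "_extrusion"), nrow(side)),
              rep(paste0(name, "_cap"), nrow(caps)))
  surface_mesh(v, rbind(fk, newf), c(lab[keep], newlab),
               spacing_um = surf$spacing_um)
}
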