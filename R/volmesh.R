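# Simplex volume meshes: structured rectangle/box meshes for verification
# cases, a layered-shell mesher for star-shaped cavity surfaces (exact
# boundary conformity, geometrically graded shells so element aspect ratio
# stays bounded towards the centre), element Jacobian/quality metrics, and
# dynamic remeshing with barycentric field transfer.

#' Construct a flow mesh
#'
#' @param nodes n x d matrix of node coordinates (cm).
#' @param elems ne x (d+1) integer matrix of simplices (1-based).
#' @param faces boundary facets (nb x d integer matrix, outward-oriented).
#' @param labels per-boundary-facet labels.
#' @param surf_nv number of leading nodes that are surface vertices (for
#'   meshes built from a `surface_mesh`), or `NA`.
#' @param target_edge nominal edge length used at creation (for remeshing).
#' @return a `flow_mesh`.
#' @export
flow_mesh <- function(nodes, elems, faces, labels, surf_nv = NA_integer_,
                      target_edge = NA_real_) {
  nodes <- as.matrix(nodes)
  dimnames(nodes) <- NULL
  elems <- as.matrix(elems); storage.mode(elems) <- "integer"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  dimnames(elems) <- dimnames(faces) <- NULL
  d <- ncol(nodes)
  assert_that(ncol(elems) == d + 1, "elements must be simplices (d+1 nodes)")
  assert_that(ncol(faces) == d, "boundary facets must have d nodes")
  assert_that(length(labels) == nrow(faces), "one label per boundary facet")
  J <- element_jacobian_all(nodes, elems)
  assert_that(all(J > 0), "mesh has %d non-positive element Jacobians", sum(J <= 0))
  structure(list(nodes = nodes, elems = elems,
                 boundary = list(faces = faces, labels = as.character(labels)),
                 d = d, surf_nv = surf_nv, target_edge = target_edge,
                 ref_nodes = nodes,
                 cache = new.env(parent = emptyenv())),
            class = "flow_mesh")
}

#' @export
print.flow_mesh <- function(x, ...) {
  cat(sprintf("flow_mesh: %d-D, %d nodes, %d elements, %d boundary facets (%s)\n",
              x$d, nrow(x$nodes), nrow(x$elems), nrow(x$boundary$faces),
              paste(unique(x$boundary$labels), collapse = ", ")))
  invisible(x)
}

# signed element Jacobians (det of the reference-to-physical map) for all
# elements; J_e = d! * signed volume
element_jacobian_all <- function(nodes, elems) {
  d <- ncol(nodes)
  if (d == 2) {
    a <- nodes[elems[, 1], , drop = FALSE]
    u <- nodes[elems[, 2], , drop = FALSE] - a
    v <- nodes[elems[, 3], , drop = FALSE] - a
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  } else {
    a <- nodes[elems[, 1], , drop = FALSE]
    u <- nodes[elems[, 2], , drop = FALSE] - a
    v <- nodes[elems[, 3], , drop = FALSE] - a
    w <- nodes[elems[, 4], , drop = FALSE] - a
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  }
}

#' Signed Jacobian of each element of a mesh
#'
#' The determinant of the reference-to-physical map (`d!` times the signed
#' element volume): positive for well-oriented elements, zero for degenerate
#' ones, and sign-flipped when two vertices are swapped.
#'
#' @param mesh a `flow_mesh`, or an ne x (d+1) element matrix with `nodes`.
#' @param nodes node coordinates (only when `mesh` is an element matrix).
#' @return numeric vector of signed Jacobians.
#' @export
element_jacobian <- function(mesh, nodes = NULL) {
  if (inherits(mesh, "flow_mesh")) element_jacobian_all(mesh$nodes, mesh$elems)
  else element_jacobian_all(nodes, as.matrix(mesh))
}

# scale-invariant element shape quality in (0, 1]; 1 for the equilateral
# simplex
element_quality <- function(nodes, elems) {
  d <- ncol(nodes)
  J <- element_jacobian_all(nodes, elems)
  vol <- J / factorial(d)
  nen <- d + 1
  l2 <- 0
  for (i in 1:(nen - 1)) for (j in (i + 1):nen) {
    l2 <- l2 + rowSums((nodes[elems[, i], , drop = FALSE] -
                          nodes[elems[, j], , drop = FALSE])^2)
  }
  lrms <- sqrt(l2 / (nen * (nen - 1) / 2))
  if (d == 2) (4 / sqrt(3)) * vol / lrms^2 else 6 * sqrt(2) * vol / lrms^3
}

#' Element volumes of a mesh
#' @param mesh a `flow_mesh`.
#' @return numeric vector (cm^3, or cm^2 in 2-D).
#' @export
element_volumes <- function(mesh) {
  element_jacobian_all(mesh$nodes, mesh$elems) / factorial(mesh$d)
}

# outward-oriented boundary faces of a simplex mesh (faces occurring once)
boundary_faces_of <- function(elems, d) {
  if (d == 2) {
    fc <- rbind(elems[, c(1, 2)], elems[, c(2, 3)], elems[, c(3, 1)])
  } else {
    fc <- rbind(elems[, c(2, 3, 4)], elems[, c(1, 4, 3)],
                elems[, c(1, 2, 4)], elems[, c(1, 3, 2)])
  }
  key <- apply(fc, 1, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  fc[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

# flip elements with negative Jacobians by swapping the last two vertices
fix_orientation <- function(nodes, elems) {
  J <- element_jacobian_all(nodes, elems)
  bad <- J < 0
  if (any(bad)) {
    nen <- ncol(elems)
    tmp <- elems[bad, nen - 1L]
    elems[bad, nen - 1L] <- elems[bad, nen]
    elems[bad, nen] <- tmp
  }
  elems
}

#' Structured triangle mesh of a rectangle
#'
#' Cells are split along alternating diagonals; boundary facets are labeled
#' `left`, `right`, `bottom`, `top`.
#'
#' @param nx,ny number of cells per axis.
#' @param L,H rectangle extents; the domain is `[0,L] x [0,H]`.
#' @return a `flow_mesh`.
#' @export
mesh_rectangle <- function(nx, ny, L = 1, H = 1) {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, H, length.out = ny + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  nid <- function(i, j) i + (nx + 1) * (j - 1)   # i, j 1-based
  elems <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid(i, j); b <- nid(i + 1, j); c <- nid(i + 1, j + 1); d <- nid(i, j + 1)
    if ((i + j) %% 2 == 0) elems <- rbind(elems, c(a, b, c), c(a, c, d))
    else elems <- rbind(elems, c(a, b, d), c(b, c, d))
  }
  faces <- boundary_faces_of(elems, 2L)
  ctr <- (nodes[faces[, 1], ] + nodes[faces[, 2], ]) / 2
  tol <- 1e-12 * max(L, H)
  labels <- ifelse(ctr[, 1] < tol, "left",
            ifelse(ctr[, 1] > L - tol, "right",
            ifelse(ctr[, 2] < tol, "bottom", "top")))
  flow_mesh(nodes, elems, faces, labels)
}

#' Structured tetrahedral mesh of a box
#'
#' Each hexahedral cell is split into 6 tetrahedra around its main diagonal;
#' boundary facets are labeled `left`/`right` (x), `bottom`/`top` (y),
#' `back`/`front` (z).
#'
#' @param nx,ny,nz cells per axis.
#' @param L extents (length 3); the domain is `[0,L1] x [0,L2] x [0,L3]`.
#' @return a `flow_mesh`.
#' @export
mesh_box <- function(nx, ny, nz, L = c(1, 1, 1)) {
  xs <- seq(0, L[1], length.out = nx + 1)
  ys <- seq(0, L[2], length.out = ny + 1)
  zs <- seq(0, L[3], length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))
  # 6-tet Kuhn subdivision of the unit cube (shared main diagonal 1-7)
  corners <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                   c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  kuhn <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  elems <- matrix(0L, 6 * nx * ny * nz, 4)
  row <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    ids <- vapply(seq_len(8), function(c)
      nid(i + corners[c, 1], j + corners[c, 2], k + corners[c, 3]), numeric(1))
    for (t in 1:6) {
      row <- row + 1L
      elems[row, ] <- as.integer(ids[kuhn[t, ]])
    }
  }
  elems <- fix_orientation(nodes, elems)
  faces <- boundary_faces_of(elems, 3L)
  ctr <- (nodes[faces[, 1], ] + nodes[faces[, 2], ] + nodes[faces[, 3], ]) / 3
  tol <- 1e-12 * max(L)
  labels <- ifelse(ctr[, 1] < tol, "left",
            ifelse(ctr[, 1] > L[1] - tol, "right",
            ifelse(ctr[, 2] < tol, "bottom",
            ifelse(ctr[, 2] > L[2] - tol, "top",
            ifelse(ctr[, 3] < tol, "back", "front")))))
  flow_mesh(nodes, elems, faces, labels)
}

# centroid of the volume enclosed by a closed surface (simplex decomposition
# against the vertex mean)
enclosed_centroid <- function(surf) {
  v <- surf$vertices; f <- surf$facets; d <- surf$d
  p0 <- colMeans(v)
  tot <- 0; ctr <- numeric(d)
  for (k in seq_len(nrow(f))) {
    simp <- rbind(p0, v[f[k, ], , drop = FALSE])
    J <- if (d == 2) {
      u <- simp[2, ] - simp[1, ]; w <- simp[3, ] - simp[1, ]
      u[1] * w[2] - u[2] * w[1]
    } else {
      u <- simp[2, ] - simp[1, ]; w <- simp[3, ] - simp[1, ]; q <- simp[4, ] - simp[1, ]
      u[1] * (w[2] * q[3] - w[3] * q[2]) - u[2] * (w[1] * q[3] - w[3] * q[1]) +
        u[3] * (w[1] * q[2] - w[2] * q[1])
    }
    vol <- J / factorial(d)
    tot <- tot + vol
    ctr <- ctr + vol * colMeans(simp)
  }
  ctr / tot
}

# split a prism (bottom a,b,c / top d,e,f with a-d, b-e, c-f matched) into 3
# tetrahedra consistently across neighbouring prisms (Dompierre et al.)
split_prism <- function(pr) {
  # rotate so the smallest global index sits at position 1 (bottom)
  rots <- list(c(1,2,3,4,5,6), c(2,3,1,5,6,4), c(3,1,2,6,4,5),
               c(4,6,5,1,3,2), c(5,4,6,2,1,3), c(6,5,4,3,2,1))
  best <- rots[[which.min(vapply(rots, function(r) pr[r[1]], numeric(1)))]]
  p <- pr[best]
  if (min(p[2], p[6]) < min(p[3], p[5])) {
    rbind(c(p[1], p[2], p[3], p[6]), c(p[1], p[2], p[6], p[5]),
          c(p[1], p[5], p[6], p[4]))
  } else {
    rbind(c(p[1], p[2], p[3], p[5]), c(p[1], p[5], p[3], p[6]),
          c(p[1], p[5], p[6], p[4]))
  }
}

#' Mesh the interior of a star-shaped labeled surface
#'
#' Builds a simplex mesh whose boundary is exactly the given surface: the
#' surface is shrunk towards the enclosed-volume centroid in geometrically
#' graded shells (ratio set by the surface edge length, so element aspect
#' ratio stays bounded), shells are connected by consistently split prisms,
#' and the innermost shell is joined to the centre by a fan.  Fails with a
#' diagnostic if the surface is not star-shaped about its centroid.
#'
#' @param surface a watertight `surface_mesh`.
#' @param target_edge nominal edge length (cm); defaults to the surface mean
#'   edge length.
#' @return a `flow_mesh` whose first `nrow(surface$vertices)` nodes are the
#'   surface vertices and whose boundary facets mirror the surface facets
#'   and labels.
#' @export
mesh_interior <- function(surface, target_edge = NULL) {
  assert_that(is_watertight(surface), "surface is not watertight")
  d <- surface$d
  v <- surface$vertices
  f <- surface$facets
  ctr <- enclosed_centroid(surface)
  g <- facet_geometry(surface)
  vis <- rowSums(sweep(g$centroids, 2, ctr, "-") * g$normals)
  if (any(vis <= 0))
    stop_hf("surface is not star-shaped about its centroid (%d facets not visible); cannot mesh",
            sum(vis <= 0))
  rad <- row_norms(sweep(v, 2, ctr, "-"))
  Rm <- mean(rad)
  h <- target_edge %||% mean_edge_length(surface)
  q <- min(max(1 - h / Rm, 0.45), 0.92)
  fr <- 1
  fracs <- numeric(0)
  while (fr * q * Rm > 1.4 * h) {
    fr <- fr * q
    fracs <- c(fracs, fr)
  }
  nshell <- length(fracs)
  nv <- nrow(v)
  nodes <- v
  for (k in seq_len(nshell))
    nodes <- rbind(nodes, sweep(sweep(v, 2, ctr, "-") * fracs[k], 2, ctr, "+"))
  nodes <- rbind(nodes, ctr)
  cid <- nrow(nodes)

  elems <- NULL
  if (d == 2) {
    n <- nv   # polygon vertex count; facets are (i, i+1)
    for (k in 0:nshell) {
      o_off <- k * nv; i_off <- (k + 1) * nv
      if (k < nshell) {
        for (s in seq_len(nrow(f))) {
          a <- f[s, 1] + o_off; b <- f[s, 2] + o_off
          ap <- f[s, 1] + i_off; bp <- f[s, 2] + i_off
          elems <- rbind(elems, c(a, b, ap), c(b, bp, ap))
        }
      } else {
        for (s in seq_len(nrow(f)))
          elems <- rbind(elems, c(f[s, 1] + o_off, f[s, 2] + o_off, cid))
      }
    }
  } else {
    for (k in 0:nshell) {
      o_off <- k * nv; i_off <- (k + 1) * nv
      if (k < nshell) {
        tets <- lapply(seq_len(nrow(f)), function(s) {
          split_prism(c(f[s, ] + i_off, f[s, ] + o_off))
        })
        elems <- rbind(elems, do.call(rbind, tets))
      } else {
        elems <- rbind(elems, cbind(matrix(f + o_off, ncol = 3), cid))
      }
    }
  }
  elems <- fix_orientation(nodes, elems)
  mesh <- flow_mesh(nodes, elems, f, surface$labels, surf_nv = nv,
                    target_edge = h)
  mesh
}

# current boundary surface of a mesh built by mesh_interior()
mesh_surface <- function(mesh) {
  surface_mesh(mesh$nodes[seq_len(max(mesh$boundary$faces)), , drop = FALSE],
               mesh$boundary$faces, mesh$boundary$labels)
}

#' Interpolate nodal fields of a mesh at new points
#'
#' Locates each point in the mesh (barycentric weights of the containing
#' element); points outside every element are assigned their
#' nearest-element projection and counted.
#'
#' @param mesh a `flow_mesh`.
#' @param points m x d matrix of query points.
#' @param fields named list of nodal vectors or matrices.
#' @return list with interpolated `fields` and `n_outside`.
#' @export
interpolate_fields <- function(mesh, points, fields) {
  loc <- locate_points_cpp(mesh$nodes, mesh$elems - 1L, as.matrix(points))
  n_out <- sum(!loc$inside)
  en <- mesh$elems[loc$elem, , drop = FALSE]
  out <- lapply(fields, function(fld) {
    if (is.matrix(fld)) {
      acc <- matrix(0, nrow(points), ncol(fld))
      for (k in seq_len(ncol(en)))
        acc <- acc + loc$bary[, k] * fld[en[, k], , drop = FALSE]
      acc
    } else {
      acc <- numeric(nrow(points))
      for (k in seq_len(ncol(en)))
        acc <- acc + loc$bary[, k] * fld[en[, k]]
      acc
    }
  })
  list(fields = out, n_outside = n_out)
}

#' Remesh the current deformed domain and transfer nodal fields
#'
#' Rebuilds the interior mesh of the current boundary surface (the boundary
#' vertices and labels are preserved exactly) and interpolates the given
#' nodal fields from the old mesh onto the new nodes with element location
#' and barycentric weights.
#'
#' @param mesh the current (deformed) `flow_mesh` built by [mesh_interior()].
#' @param fields named list of nodal vectors/matrices on `mesh`.
#' @return list with `mesh` (new `flow_mesh`), `fields`, and `n_outside`
#'   (points interpolated by nearest-element projection).
#' @export
remesh_and_transfer <- function(mesh, fields = list()) {
  assert_that(!is.na(mesh$surf_nv), "mesh does not carry its boundary surface")
  surf <- mesh_surface(mesh)
  newmesh <- mesh_interior(surf, target_edge = mesh$target_edge)
  tr <- interpolate_fields(mesh, newmesh$nodes, fields)
  if (tr$n_outside > 0)
    message(sprintf("remesh transfer: %d node(s) interpolated by nearest-element projection",
                    tr$n_outside))
  list(mesh = newmesh, fields = tr$fields, n_outside = tr$n_outside)
}
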