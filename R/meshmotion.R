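# Elastostatic mesh motion with Jacobian-based stiffening: interior node
# displacements follow a linear-elasticity solve in which each element's
# stiffness is scaled by (Vbar/V_e)^chi, so small elements resist further
# distortion.  The system is assembled on the reference configuration (the
# mesh at creation or at the last remesh) and its factorization is cached
# there, so each time step costs one sparse triangular solve; displacements
# are therefore measured from the reference configuration.  In the
# quasi-direct coupling the mesh system lags the fluid solve; because the
# wall position at t+dt is prescribed, one mesh solve per step suffices.

#' Solve elastostatic mesh motion for prescribed boundary displacement
#'
#' @param mesh a `flow_mesh`; the elasticity operator lives on
#'   `mesh$ref_nodes` (the configuration at creation / last remesh).
#' @param boundary_disp displacement of the boundary nodes *from the
#'   reference configuration*: one row per entry of `nodes`, or a full
#'   n x d matrix from which only boundary rows are used.
#' @param nodes boundary node indices (defaults to all boundary nodes).
#' @param chi Jacobian-based stiffening exponent (0 disables stiffening).
#' @param nu elastic Poisson ratio.
#' @return list with `disp` (n x d displacement of all nodes from the
#'   reference configuration), `new_nodes`, and `min_jacobian` of the moved
#'   mesh (non-positive signals that remeshing is required).
#' @export
solve_mesh_motion <- function(mesh, boundary_disp, nodes = NULL, chi = 1,
                              nu = 0.3) {
  d <- mesh$d
  n <- nrow(mesh$nodes)
  bnodes <- nodes %||% sort(unique(as.vector(mesh$boundary$faces)))
  boundary_disp <- as.matrix(boundary_disp)
  if (nrow(boundary_disp) == n) boundary_disp <- boundary_disp[bnodes, , drop = FALSE]
  assert_that(nrow(boundary_disp) == length(bnodes),
              "boundary displacement must cover every boundary node")

  disp <- matrix(0, n, d)
  disp[bnodes, ] <- boundary_disp
  interior <- setdiff(seq_len(n), bnodes)
  if (length(interior)) {
    key <- sprintf("elast_%g_%g_%d", chi, nu, length(bnodes))
    cache <- mesh$cache
    fac <- if (!is.null(cache)) cache[[key]]
    if (is.null(fac)) {
      trip <- assemble_elasticity_cpp(mesh$ref_nodes, mesh$elems - 1L, chi, nu)
      K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                dims = c(n * d, n * d))
      idof <- as.vector(outer(0:(d - 1), (interior - 1) * d, "+")) + 1L
      bdof <- as.vector(outer(0:(d - 1), (bnodes - 1) * d, "+")) + 1L
      fac <- list(
        chol = Matrix::Cholesky(Matrix::forceSymmetric(K[idof, idof, drop = FALSE])),
        Kib = K[idof, bdof, drop = FALSE])
      if (!is.null(cache)) cache[[key]] <- fac
    }
    rhs <- -(fac$Kib %*% as.vector(t(boundary_disp)))
    ui <- Matrix::solve(fac$chol, rhs, system = "A")
    disp[interior, ] <- matrix(as.vector(ui), ncol = d, byrow = TRUE)
  }
  new_nodes <- mesh$ref_nodes + disp
  minJ <- min(element_jacobian_all(new_nodes, mesh$elems))
  list(disp = disp, new_nodes = new_nodes, min_jacobian = minJ)
}
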