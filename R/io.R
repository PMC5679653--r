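# File IO: multi-page TIFF image sequences with JSON sidecar, ASCII PLY
# surfaces with a JSON label map, and ASCII VTK XML (VTU/VTP) output for
# meshes and fields.

#' Write an image sequence as multi-page TIFF files plus a JSON sidecar
#'
#' One TIFF per frame (one page per z-slice in 3-D), with zero-padded frame
#' index in the file name, and a `sidecar.json` recording voxel spacing,
#' frame times, period and orifice markers.
#'
#' @param iseq an `image_sequence`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_image_sequence <- function(iseq, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- length(iseq$frames)
  fmt <- sprintf("%%s_%%0%dd.tif", max(3, nchar(M)))
  for (k in seq_len(M)) {
    img <- iseq$frames[[k]]
    # clamp to [0,1] for storage; TIFF payload is 32-bit float
    img <- pmin(pmax(img, 0), 1)
    pages <- if (length(dim(img)) == 2) list(t(img)) else
      lapply(seq_len(dim(img)[3]), function(z) t(img[, , z]))
    tiff::writeTIFF(pages, file.path(dir, sprintf(fmt, prefix, k)),
                    bits.per.sample = 32L)
  }
  sidecar <- list(
    spacing_um = iseq$spacing_um,
    frame_times_s = iseq$frame_times_s,
    period_s = iseq$period_s,
    dims = iseq$dims,
    orifice_markers = iseq$orifice_markers
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an image sequence written by [write_image_sequence()]
#'
#' @param dir directory containing the TIFF frames and `sidecar.json`.
#' @param prefix file-name prefix used when writing.
#' @return an `image_sequence`.
#' @export
read_image_sequence <- function(dir, prefix = "frame") {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.tif$"),
                           full.names = TRUE))
  assert_that(length(files) > 0, "no frames found in %s", dir)
  dims <- as.integer(sc$dims)
  frames <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dims) == 2) t(pages[[1]])
    else {
      a <- array(0, dims)
      for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
      a
    }
  })
  mk <- sc$orifice_markers
  if (!is.matrix(mk)) mk <- do.call(rbind, mk)
  structure(list(frames = frames, dims = dims,
                 spacing_um = as.numeric(sc$spacing_um),
                 frame_times_s = as.numeric(sc$frame_times_s),
                 period_s = as.numeric(sc$period_s),
                 orifice_markers = mk),
            class = "image_sequence")
}

#' Write a surface mesh as ASCII PLY with a JSON facet-label map
#'
#' @param surf a `surface_mesh` (3-D triangles or 2-D segments).
#' @param path output file (`.ply`); labels go to `<path>.labels.json`.
#' @export
write_surface_ply <- function(surf, path) {
  v <- surf$vertices
  f <- surf$facets
  d <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y",
               if (d == 3) "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vv <- if (d == 2) cbind(v, 0) else v
  writeLines(apply(format(vv, digits = 17, scientific = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste(ncol(f), apply(f - 1L, 1, paste, collapse = " ")), con)
  jsonlite::write_json(list(labels = surf$labels),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a surface mesh written by [write_surface_ply()]
#' @param path the `.ply` file.
#' @return a `surface_mesh`.
#' @export
read_surface_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  hd <- which(lines == "end_header")
  vl <- lines[(hd + 1):(hd + nv)]
  fl <- lines[(hd + nv + 1):(hd + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), as.numeric))
  fr <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), as.integer))
  nfn <- fr[1, 1]
  f <- fr[, 2:(1 + nfn), drop = FALSE] + 1L
  d <- if (all(v[, 3] == 0) && nfn == 2) 2L else 3L
  labels <- rep("wall", nf)
  lp <- paste0(path, ".labels.json")
  if (file.exists(lp))
    labels <- as.character(jsonlite::read_json(lp, simplifyVector = TRUE)$labels)
  surface_mesh(v[, seq_len(d), drop = FALSE], f, labels)
}

# ---- minimal ASCII VTK XML writers (output only) ----

vtk_cell_type <- function(d, nfn) {
  if (nfn == 2) 3L else if (nfn == 3) if (d == 2) 5L else 5L else 10L
}

vtk_data_array <- function(name, values, ncomp = 1L) {
  c(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
            name, ncomp),
    paste(format(as.vector(t(values)), digits = 12), collapse = " "),
    "</DataArray>")
}

#' Write a volume mesh and nodal fields as an ASCII VTU file
#'
#' Point-data arrays follow the convention `velocity`, `pressure`,
#' `mesh_displacement`.
#'
#' @param mesh a `flow_mesh`.
#' @param path output `.vtu` file.
#' @param point_data named list of nodal scalars (vectors) or vector fields
#'   (matrices, padded to 3 components).
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  nodes <- mesh$nodes
  elems <- mesh$elems
  d <- ncol(nodes)
  pts <- if (d == 2) cbind(nodes, 0) else nodes
  nfn <- ncol(elems)
  ctype <- if (nfn == 3) 5L else 10L
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
           "<UnstructuredGrid>",
           sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nrow(pts), nrow(elems)),
           "<Points>", vtk_data_array("Points", pts, 3L), "</Points>",
           "<Cells>",
           '<DataArray type="Int32" Name="connectivity" format="ascii">',
           paste(as.vector(t(elems - 1L)), collapse = " "), "</DataArray>",
           '<DataArray type="Int32" Name="offsets" format="ascii">',
           paste(seq_len(nrow(elems)) * nfn, collapse = " "), "</DataArray>",
           '<DataArray type="UInt8" Name="types" format="ascii">',
           paste(rep(ctype, nrow(elems)), collapse = " "), "</DataArray>",
           "</Cells>")
  if (length(point_data)) {
    out <- c(out, "<PointData>")
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.matrix(val)) {
        if (ncol(val) == 2) val <- cbind(val, 0)
        out <- c(out, vtk_data_array(nm, val, ncol(val)))
      } else out <- c(out, vtk_data_array(nm, val, 1L))
    }
    out <- c(out, "</PointData>")
  }
  out <- c(out, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(out, path)
  invisible(path)
}

#' Write a PVD collection index for a VTU time series
#' @param paths VTU file paths.
#' @param times time stamps.
#' @param path output `.pvd` file.
#' @export
write_pvd <- function(paths, times, path) {
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="Collection" version="0.1">', "<Collection>",
           sprintf('<DataSet timestep="%.10g" part="0" file="%s"/>', times, basename(paths)),
           "</Collection>", "</VTKFile>")
  writeLines(out, path)
  invisible(path)
}

#' Write a surface mesh (with optional per-facet data) as an ASCII VTP file
#' @param surf a `surface_mesh`.
#' @param path output `.vtp` file.
#' @param cell_data named list of per-facet scalar vectors.
#' @export
write_vtp <- function(surf, path, cell_data = list()) {
  v <- surf$vertices
  d <- ncol(v)
  pts <- if (d == 2) cbind(v, 0) else v
  f <- surf$facets
  nfn <- ncol(f)
  tag <- if (nfn == 2) "Lines" else "Polys"
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
           "<PolyData>",
           sprintf('<Piece NumberOfPoints="%d" NumberOf%s="%d">', nrow(pts), tag, nrow(f)),
           "<Points>", vtk_data_array("Points", pts, 3L), "</Points>",
           sprintf("<%s>", tag),
           '<DataArray type="Int32" Name="connectivity" format="ascii">',
           paste(as.vector(t(f - 1L)), collapse = " "), "</DataArray>",
           '<DataArray type="Int32" Name="offsets" format="ascii">',
           paste(seq_len(nrow(f)) * nfn, collapse = " "), "</DataArray>",
           sprintf("</%s>", tag))
  if (length(cell_data)) {
    out <- c(out, "<CellData>")
    for (nm in names(cell_data))
      out <- c(out, vtk_data_array(nm, cell_data[[nm]], 1L))
    out <- c(out, "</CellData>")
  }
  out <- c(out, "</Piece>", "</PolyData>", "</VTKFile>")
  writeLines(out, path)
  invisible(path)
}
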