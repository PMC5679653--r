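# Template segmentation: histogram thresholding of the bright myocardial
# wall, cavity extraction as the enclosed interior, and a morphological
# curvature-regularized active-contour refinement toward intensity edges
# (a deterministic stand-in for interactive level-set advection, with the
# same contract: an edge-conforming refinement of a threshold mask).

# Otsu threshold from a 256-bin histogram
otsu_threshold <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(pmax(findInterval(x, seq(r[1], r[2], length.out = 257),
                                       all.inside = TRUE), 1L), 256L), 256L)
  w <- h / sum(h)
  mids <- seq(r[1], r[2], length.out = 257)[-257] + diff(r) / 512
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[256]
  sb <- (mt * cw - cm)^2 / (cw * (1 - cw))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# shift an array by one voxel along an axis, replicating the edge
shift1 <- function(a, ax, dir) {
  dims <- dim(a)
  n <- dims[ax]
  idx <- lapply(dims, seq_len)
  idx[[ax]] <- if (dir > 0) c(1L, seq_len(n - 1L)) else c(seq_len(n)[-1L], n)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

dilate_mask <- function(m) {
  out <- m
  for (ax in seq_along(dim(m))) out <- out | shift1(m, ax, 1) | shift1(m, ax, -1)
  out
}

erode_mask <- function(m) !dilate_mask(!m)

largest_component <- function(mask) {
  lab <- conncomp_cpp(as.logical(mask), as.integer(dim(mask)))
  n <- attr(lab, "n")
  if (n == 0) return(array(FALSE, dim(mask)))
  best <- which.max(tabulate(lab[lab > 0L], n))
  out <- array(lab == best, dim(mask))
  out
}

# components of `mask` touching the array border
border_components <- function(mask) {
  dims <- dim(mask)
  lab <- conncomp_cpp(as.logical(mask), as.integer(dims))
  labarr <- array(lab, dims)
  d <- length(dims)
  touch <- integer(0)
  for (ax in seq_len(d)) {
    idx1 <- lapply(dims, seq_len); idx1[[ax]] <- 1L
    idx2 <- lapply(dims, seq_len); idx2[[ax]] <- dims[ax]
    touch <- c(touch, as.vector(do.call(`[`, c(list(labarr), idx1))),
               as.vector(do.call(`[`, c(list(labarr), idx2))))
  }
  touch <- setdiff(unique(touch), 0L)
  array(lab %in% touch, dims)
}

#' Segment the cavity of a template frame
#'
#' Thresholds the bright wall from the intensity histogram (Otsu unless a
#' threshold is given), takes the largest enclosed dark region as the cavity,
#' and refines its boundary with a morphological curvature-regularized
#' active contour driven by the local inside/near-band outside intensity
#' contrast.
#'
#' @param image a single intensity frame (2-D or 3-D array).
#' @param threshold optional wall threshold; Otsu's method if `NULL`.
#' @param levelset_iters refinement iterations (0 disables refinement).
#' @param smoothing number of alternating morphological opening/closing
#'   passes per refinement iteration (curvature regularization weight).
#' @return logical array: the cavity mask.
#' @export
segment_template <- function(image, threshold = NULL, levelset_iters = 50L,
                             smoothing = 1L) {
  assert_that(all(is.finite(image)), "image intensities must be finite")
  thr <- threshold %||% otsu_threshold(as.vector(image))
  wall <- image > thr
  if (!any(wall)) stop_hf("empty foreground: no wall voxels above threshold %.4g", thr)
  # cavity = largest background region fully enclosed by the wall
  holes <- !wall & !border_components(!wall)
  if (!any(holes)) stop_hf("empty foreground: wall encloses no cavity")
  mask <- largest_component(holes)

  for (it in seq_len(levelset_iters)) {
    inside <- image[mask]
    band <- dilate_mask(dilate_mask(dilate_mask(mask))) & !mask
    c_in <- mean(inside)
    c_out <- mean(image[band])
    cut <- (c_in + c_out) / 2
    # region update on the active band (one-voxel shell each way)
    grow <- dilate_mask(mask) & !mask & (abs(image - c_in) < abs(image - c_out))
    shrink <- mask & !erode_mask(mask) & (abs(image - c_in) >= abs(image - c_out))
    new_mask <- (mask | grow) & !shrink
    # curvature regularization: alternate non-biased opening/closing
    if (smoothing > 0) {
      for (s in seq_len(smoothing)) {
        new_mask <- if ((it + s) %% 2 == 0) dilate_mask(erode_mask(new_mask))
                    else erode_mask(dilate_mask(new_mask))
      }
    }
    if (identical(new_mask, mask)) { mask <- new_mask; break }
    mask <- new_mask
  }
  mask <- largest_component(mask)
  if (!any(mask)) stop_hf("empty foreground after refinement")
  mask
}

#' Per-frame cavity volume curve of an image sequence
#'
#' Fast voxel-counting volumes using a fixed mid-range wall threshold
#' (suitable for template selection and contractility estimates on phantom
#' data); volumes are in cm^3 (cm^2 in 2-D).
#'
#' @param iseq an `image_sequence`.
#' @param threshold wall threshold; mid-range if `NULL`.
#' @return a tibble with columns `frame`, `t`, `volume`.
#' @export
cavity_volume_curve <- function(iseq, threshold = NULL) {
  sp_cm <- iseq$spacing_um * UM_TO_CM
  vox <- prod(sp_cm)
  vols <- vapply(seq_along(iseq$frames), function(k) {
    img <- iseq$frames[[k]]
    thr <- threshold %||% (0.5 * max(img))
    wall <- img > thr
    holes <- !wall & !border_components(!wall)
    if (!any(holes)) return(NA_real_)
    sum(largest_component(holes)) * vox
  }, numeric(1))
  tibble::tibble(frame = seq_along(iseq$frames),
                 t = iseq$frame_times_s, volume = vols)
}

#' Choose the template frame for segmentation and tracking
#'
#' The frame whose cavity volume is nearest the mid-diastolic volume
#' `(EDV + ESV)/2`, so the template sits evenly between the volume extremes.
#'
#' @param iseq an `image_sequence`.
#' @return integer frame index.
#' @export
select_template_frame <- function(iseq) {
  vc <- cavity_volume_curve(iseq)
  v <- vc$volume
  assert_that(all(is.finite(v)), "could not segment a cavity in every frame")
  which.min(abs(v - (max(v) + min(v)) / 2))[1]
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
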