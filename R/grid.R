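#' Voxel grid specification
#'
#' Axis-aligned voxel grid with an isotropic-or-not voxel size in mm and the
#' implied voxel-to-mm affine (0-based voxel indices scale to mm; the affine
#' is stored as a 4x4 matrix).
#'
#' @param dim integer vector of 3 grid dimensions.
#' @param voxel_mm numeric vector of 3 voxel edge lengths in mm (default
#'   2 mm isotropic).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(dim = c(24L, 24L, 24L), voxel_mm = c(2, 2, 2)) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1)) stop("'dim' must be 3 positive integers", call. = FALSE)
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0)) stop("'voxel_mm' must be 3 positive lengths", call. = FALSE)
  affine <- diag(c(voxel_mm, 1))
  structure(list(dim = dim, voxel_mm = as.numeric(voxel_mm), affine = affine),
            class = "grid_spec")
}

#' Named boolean region-of-interest mask over a voxel grid
#'
#' @param name ROI name.
#' @param mask logical 3D array matching `grid$dim`, or a vector of linear
#'   voxel indices.
#' @param grid a `grid_spec`.
#' @return object of class `roi_spec` with fields `name`, `mask` (logical
#'   array) and `grid`.
#' @export
roi_spec <- function(name, mask, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(mask)) {
    idx <- as.integer(mask)
    mask <- array(FALSE, grid$dim)
    mask[idx] <- TRUE
  }
  if (!identical(dim(mask), grid$dim)) {
    stop("mask dimensions do not match the grid", call. = FALSE)
  }
  structure(list(name = as.character(name), mask = mask, grid = grid),
            class = "roi_spec")
}

#' Rectangular box ROI
#'
#' Convenience constructor used throughout the simulations: an axis-aligned
#' box of voxels given inclusive index ranges (1-based).
#'
#' @param name ROI name.
#' @param grid a `grid_spec`.
#' @param x,y,z integer index ranges.
#' @return an `roi_spec`.
#' @export
box_roi <- function(name, grid, x, y, z) {
  mask <- array(FALSE, grid$dim)
  mask[x, y, z] <- TRUE
  roi_spec(name, mask, grid)
}

roi_indices <- function(roi) which(roi$mask)

n_voxels <- function(grid) prod(grid$dim)

check_disjoint_rois <- function(rois) {
  if (length(rois) < 2) return(invisible(TRUE))
  counts <- Reduce(`+`, lapply(rois, function(r) r$mask + 0L))
  if (any(counts > 1L)) stop("ROIs must be disjoint", call. = FALSE)
  invisible(TRUE)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter with `sigma = fwhm / (2*sqrt(2*log(2)))` per axis
#' in voxel units; the kernel is truncated at 4 sigma and normalised so that
#' a fully interior delta keeps unit mass. `fwhm = 0` is the identity.
#'
#' @param vol numeric 3D array.
#' @param fwhm full width at half maximum in mm.
#' @param voxel_mm voxel edge lengths in mm (scalar or length 3).
#' @return smoothed array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm, voxel_mm = 2) {
  if (fwhm < 0) stop("'fwhm' must be non-negative", call. = FALSE)
  if (fwhm == 0) return(vol)
  voxel_mm <- rep_len(voxel_mm, 3)
  out <- vol
  for (ax in 1:3) {
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm[ax]
    radius <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(seq(-radius, radius), sd = sigma)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution along one axis with reflective (mirror) boundaries, so
# constants are preserved exactly and total mass is conserved.
convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = dim(v)[1])
  n <- nrow(m)
  radius <- (length(kernel) - 1) / 2
  out <- matrix(0, n, ncol(m))
  for (off in seq_along(kernel)) {
    shift <- off - radius - 1
    src <- seq_len(n) + shift
    src <- ifelse(src < 1, 1 - src, ifelse(src > n, 2 * n + 1 - src, src))
    src <- pmin(pmax(src, 1), n)
    out <- out + kernel[off] * m[src, , drop = FALSE]
  }
  v <- array(out, dim(v))
  aperm(v, order(perm))
}

#' Smooth a masked statistic map
#'
#' Smooths only within the mask by zero-filling outside and renormalising by
#' the smoothed mask, so values at mask edges are proper weighted averages of
#' in-mask neighbours. Voxels outside the mask are returned as `NA`.
#'
#' @param vol numeric 3D array (may contain `NA` outside the mask).
#' @param mask logical array of the same shape.
#' @inheritParams smooth_volume
#' @return smoothed array, `NA` outside `mask`.
#' @export
smooth_masked <- function(vol, mask, fwhm, voxel_mm = 2) {
  if (fwhm == 0) { vol[!mask] <- NA_real_; return(vol) }
  filled <- vol
  filled[!mask | is.na(filled)] <- 0
  num <- smooth_volume(filled, fwhm, voxel_mm)
  den <- smooth_volume(mask + 0, fwhm, voxel_mm)
  out <- num / den
  out[!mask] <- NA_real_
  out
}
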