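#' Gaussian smoothing of a volume
#'
#' Separable 3-D Gaussian filter with a per-axis sigma expressed in voxels
#' (default one voxel on every axis, i.e. anisotropic in physical units when
#' the pitches differ). The kernel is truncated at four sigma and normalized
#' so a constant volume passes through unchanged; boundaries are handled by
#' reflection, which avoids darkening the shallow layers that feed the
#' correction recursion.
#'
#' @param volume an [oct_volume].
#' @param sigma_voxels positive sigma per axis in voxels, in (z, y, x) array
#'   order; a single value is recycled to all three axes.
#' @return Smoothed volume on the same grid.
#' @examples
#' v <- oct_volume(array(5, c(8, 8, 8)), c(8.1, 2.3, 2.2))
#' all.equal(as.vector(gaussian_smooth(v)), rep(5, 512))
#' @export
gaussian_smooth <- function(volume, sigma_voxels = 1) {
  if (length(sigma_voxels) == 1L) sigma_voxels <- rep(sigma_voxels, 3L)
  if (length(sigma_voxels) != 3L || any(!is.finite(sigma_voxels)) ||
      any(sigma_voxels <= 0)) {
    stop("'sigma_voxels' must be positive (one value, or one per axis)", call. = FALSE)
  }
  out <- unclass(volume)
  attributes(out) <- list(dim = dim(volume))
  for (axis in 1:3) {
    out <- convolve_axis(out, gaussian_kernel(sigma_voxels[[axis]]), axis)
  }
  rewrap(out, volume)
}

## Normalized 1-D Gaussian truncated at 4 sigma.
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

## 1-D convolution of a 3-D array along one axis, reflection boundary.
## The axis is permuted to the front, the array flattened to a matrix, and the
## kernel applied tap by tap on reflected row indices.
convolve_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  r <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  idx <- seq_len(n)
  for (t in seq_along(kernel)) {
    src <- reflect_index(idx + (t - 1L - r), n)
    out <- out + kernel[t] * m[src, , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

## Map out-of-range indices back into 1..n by boundary reflection
## (scipy-style "reflect": 1 2 3 | 3 2 1 | 1 2 3 ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - 1L - j, j)
  j + 1L
}

#' Depth window for noise-floor estimation
#'
#' Physical depth bounds (mm) of the deep-tissue region used to estimate the
#' homogeneous noise level; the conventional window is 4-7 mm, deep enough
#' that no tissue signal survives.
#'
#' @param z_min_mm,z_max_mm bounds in mm, `0 <= z_min_mm < z_max_mm`.
#' @return An object of class `depth_window`.
#' @export
depth_window <- function(z_min_mm = 4, z_max_mm = 7) {
  if (!is.finite(z_min_mm) || !is.finite(z_max_mm) ||
      z_min_mm < 0 || z_min_mm >= z_max_mm) {
    stop("need 0 <= z_min_mm < z_max_mm", call. = FALSE)
  }
  structure(list(z_min_mm = z_min_mm, z_max_mm = z_max_mm), class = "depth_window")
}

## Layer indices (0-based) whose voxels fall in the window:
## [ceiling(z_min/pitch), floor(z_max/pitch)) -- half-open at the deep end.
window_layer_indices <- function(volume, window) {
  p <- attr(volume, "pitch_um")[["z"]]
  lo <- as.integer(ceiling(window$z_min_mm * 1000 / p))
  hi <- as.integer(floor(window$z_max_mm * 1000 / p)) - 1L
  hi <- min(hi, n_layers(volume) - 1L)
  if (lo > hi) {
    stop(sprintf(
      "depth window [%g, %g) mm is outside the volume (maximum reachable depth %.4f mm)",
      window$z_min_mm, window$z_max_mm, max_depth_mm(volume)), call. = FALSE)
  }
  lo:hi
}

#' Estimate the deep-tissue noise floor
#'
#' Mean intensity over every voxel whose layer lies inside the depth window,
#' where only homogeneous noise remains. With pitch 8.1 um and a 4-7 mm
#' window this averages layers 494 through 863.
#'
#' @param volume an [oct_volume].
#' @param window a [depth_window] (default 4-7 mm).
#' @return Non-negative scalar noise level.
#' @export
estimate_noise_floor <- function(volume, window = depth_window()) {
  idx <- window_layer_indices(volume, window)
  mean(unclass(volume)[idx + 1L, , , drop = FALSE])
}

#' Subtract a noise floor
#'
#' Elementwise `max(value - floor, 0)`; non-negativity is preserved by
#' construction and re-application with floor 0 is the identity.
#'
#' @param volume an [oct_volume].
#' @param floor non-negative scalar, typically from [estimate_noise_floor()].
#' @return Volume on the same grid.
#' @export
subtract_noise_floor <- function(volume, floor) {
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) || floor < 0) {
    stop("'floor' must be a non-negative scalar", call. = FALSE)
  }
  rewrap(pmax(unclass(volume) - floor, 0), volume)
}

#' Standard preprocessing chain
#'
#' Gaussian smoothing followed by deep-tissue noise-floor subtraction, in that
#' order, as applied to both the structural and the angiographic volume before
#' any correction.
#'
#' @inheritParams gaussian_smooth
#' @param window a [depth_window] for the noise estimate, or `NULL` to skip
#'   the subtraction (e.g. for shallow phantom volumes that never reach 4 mm).
#' @return Preprocessed volume.
#' @export
preprocess_volume <- function(volume, sigma_voxels = 1, window = depth_window()) {
  out <- gaussian_smooth(volume, sigma_voxels)
  if (!is.null(window)) {
    out <- subtract_noise_floor(out, estimate_noise_floor(out, window))
  }
  out
}

#' Extract one A-scan
#'
#' The depth profile at a single lateral position. Indices are 0-based to
#' match the layer-index convention (`x_index = 0` is the first column).
#'
#' @param volume an [oct_volume].
#' @param x_index,y_index 0-based lateral voxel indices.
#' @return A [depth_profile] with `depths_mm[k] = k * pitch_z_um / 1000`.
#' @export
extract_ascan <- function(volume, x_index, y_index) {
  d <- dim(volume)
  if (x_index < 0 || x_index >= d[3L] || y_index < 0 || y_index >= d[2L]) {
    stop(sprintf("lateral index out of bounds: x must be in [0, %d], y in [0, %d]",
                 d[3L] - 1L, d[2L] - 1L), call. = FALSE)
  }
  depth_profile(layer_depths_mm(volume),
                unclass(volume)[, y_index + 1L, x_index + 1L])
}

#' Extract an en face slice
#'
#' The lateral slice at the layer whose physical depth is nearest the
#' requested depth.
#'
#' @param volume an [oct_volume].
#' @param depth_mm requested depth, `0 <= depth_mm <= max_depth_mm(volume)`.
#' @return A y-by-x intensity matrix with attributes `layer` (0-based index of
#'   the realized layer) and `depth_mm` (its physical depth).
#' @export
extract_enface <- function(volume, depth_mm) {
  if (!is.finite(depth_mm) || depth_mm < 0 || depth_mm > max_depth_mm(volume)) {
    stop(sprintf("depth %g mm outside volume depth range [0, %.4f] mm",
                 depth_mm, max_depth_mm(volume)), call. = FALSE)
  }
  layer <- which.min(abs(layer_depths_mm(volume) - depth_mm)) - 1L
  structure(unclass(volume)[layer + 1L, , ],
            layer = layer,
            depth_mm = layer * attr(volume, "pitch_um")[["z"]] / 1000)
}
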