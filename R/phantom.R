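#' Cylindrical vessel specification
#'
#' One straight vessel running along a lateral axis, with circular
#' cross-section in the orthogonal plane and a uniform flow-induced
#' reflectivity variation inside.
#'
#' @param center_mm numeric length-2: position of the cylinder axis in the
#'   cross-section plane, `(z, y)` for a vessel along x or `(z, x)` for a
#'   vessel along y, in mm.
#' @param radius_mm positive radius in mm.
#' @param axis `"x"` or `"y"`: the lateral direction the cylinder runs along.
#' @param delta_r flow-variation amplitude of the reflectivity inside the
#'   vessel (dimensionless, `>= 0`).
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(center_mm, radius_mm, axis = c("x", "y"), delta_r) {
  axis <- match.arg(axis)
  if (length(center_mm) != 2L || any(!is.finite(center_mm))) {
    stop("'center_mm' must be the (depth, lateral) axis position, length 2", call. = FALSE)
  }
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("'radius_mm' must be > 0", call. = FALSE)
  if (!is.finite(delta_r) || delta_r < 0) stop("'delta_r' must be >= 0", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 axis = axis, delta_r = delta_r),
            class = "vessel_spec")
}

#' Phantom specification
#'
#' Full description of a synthetic OCT/OCTA volume: grid geometry, background
#' reflectivity, embedded vessels, the generating weight, transmittance mode
#' and optional multiplicative noise. The defaults mirror a scaled-down
#' swept-source skin acquisition: 2.3 x 2.2 x 8.1 um voxels, a 256-layer
#' (2.07 mm) deep 64 x 64 lateral grid, and a single 0.05 mm-radius vessel
#' (0.1 mm diameter) centred at 1.5 mm depth.
#'
#' @param shape integer length-3 `(n_z, n_y, n_x)` voxel counts.
#' @param pitch_um voxel pitch (z, x, y) in um.
#' @param background_r background reflectivity per layer: a scalar or a
#'   length-`n_z` vector, all `>= 0`.
#' @param vessels list of [vessel_spec] objects.
#' @param w_true positive proportionality weight used in generation; the
#'   correction weight that exactly inverts the phantom.
#' @param unit_transmittance if `TRUE` (default) the forward model assumes
#'   all incident light reaches every layer (`T = 1`); if `FALSE`, `T`
#'   decreases with accumulated reflection and column sums of R must stay
#'   below 1.
#' @param noise_sigma standard deviation of the multiplicative speckle-like
#'   noise factor (0 disables noise).
#' @param seed integer seed for the noise; ignored when `noise_sigma = 0`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 64L, 64L),
                         pitch_um = c(8.1, 2.3, 2.2),
                         background_r = 0.002,
                         vessels = list(vessel_spec(center_mm = c(1.5, 0.0693),
                                                    radius_mm = 0.05,
                                                    axis = "x", delta_r = 0.002)),
                         w_true = 0.02,
                         unit_transmittance = TRUE,
                         noise_sigma = 0,
                         seed = 1L) {
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("'shape' must be three positive voxel counts (n_z, n_y, n_x)", call. = FALSE)
  }
  if (!is.finite(w_true) || w_true <= 0) stop("'w_true' must be > 0", call. = FALSE)
  if (any(background_r < 0)) stop("'background_r' must be >= 0", call. = FALSE)
  if (!length(background_r) %in% c(1L, shape[[1L]])) {
    stop("'background_r' must be a scalar or one value per layer", call. = FALSE)
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("'noise_sigma' must be >= 0", call. = FALSE)
  }
  stopifnot(all(vapply(vessels, inherits, logical(1L), "vessel_spec")))
  structure(list(shape = as.integer(shape), pitch_um = as.numeric(pitch_um),
                 background_r = as.numeric(background_r), vessels = vessels,
                 w_true = w_true, unit_transmittance = isTRUE(unit_transmittance),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec: %d x %d x %d (z,y,x), pitch (%g, %g, %g) um>\n",
              x$shape[1L], x$shape[2L], x$shape[3L],
              x$pitch_um[1L], x$pitch_um[2L], x$pitch_um[3L]))
  cat(sprintf("  %d vessel(s), w_true = %g, %s transmittance, noise sigma %g\n",
              length(x$vessels), x$w_true,
              if (x$unit_transmittance) "unit" else "physical", x$noise_sigma))
  invisible(x)
}

#' Rasterize the reflectivity fields of a phantom
#'
#' Background reflectivity R everywhere; the flow variation dR equals each
#' vessel's `delta_r` on voxels whose centre lies inside the cylinder
#' cross-section and 0 elsewhere. Voxel-centre membership with no
#' anti-aliasing keeps the geometry exactly countable. Deterministic for a
#' given spec.
#'
#' @param spec a [phantom_spec].
#' @return list with 3-D arrays `R` and `delta_R` of dim `spec$shape`.
#' @export
build_reflectivity <- function(spec) {
  d <- spec$shape
  pz <- spec$pitch_um[1L]; px <- spec$pitch_um[2L]; py <- spec$pitch_um[3L]
  R <- array(rep(rep_len(spec$background_r, d[1L]), prod(d[2:3])), dim = d)
  dR <- array(0, dim = d)
  z_mm <- (seq_len(d[1L]) - 1L) * pz / 1000
  y_mm <- (seq_len(d[2L]) - 1L) * py / 1000
  x_mm <- (seq_len(d[3L]) - 1L) * px / 1000
  for (v in spec$vessels) {
    lat_mm <- if (v$axis == "x") y_mm else x_mm
    lat_max <- lat_mm[length(lat_mm)]
    if (v$center_mm[1L] - v$radius_mm < 0 ||
        v$center_mm[1L] + v$radius_mm > z_mm[length(z_mm)] ||
        v$center_mm[2L] - v$radius_mm < 0 ||
        v$center_mm[2L] + v$radius_mm > lat_max) {
      stop("vessel extends outside the grid", call. = FALSE)
    }
    inside <- outer((z_mm - v$center_mm[1L])^2, (lat_mm - v$center_mm[2L])^2, "+") <=
      v$radius_mm^2
    if (v$axis == "x") {
      dR <- dR + v$delta_r * array(rep(inside, d[3L]), dim = d)
    } else {
      # cross-section in (z, x): broadcast over y (axis 2)
      mask3 <- aperm(array(rep(inside, d[2L]), dim = c(d[1L], d[3L], d[2L])),
                     c(1L, 3L, 2L))
      dR <- dR + v$delta_r * mask3
    }
  }
  list(R = R, delta_R = dR)
}

#' Transmittance-variation forward model
#'
#' Simulates co-registered structural and angiographic volumes from
#' reflectivity fields, injecting the tail artifact through the physics that
#' the corrector inverts. Per column, shallow to deep, with generating
#' weight w:
#' \itemize{
#'   \item transmittance `T_n = 1` (unit mode) or `1 - sum_{i<n} R_i`;
#'   \item structural intensity `S_n = T_n R_n / w`;
#'   \item transmitted-light variation `dT_n = sqrt(sum_{i<n} dR_i^2)`
#'         (variations in different layers assumed uncorrelated);
#'   \item angiographic intensity `A_n = (dT_n R_n + T_n dR_n) / w`;
#'   \item ground-truth corrected angiogram `A^corr_n = T_n dR_n / w`.
#' }
#' The term `dT_n R_n / w` is the tail artifact: it is non-negative,
#' non-decreasing with depth below flow, and exactly what
#' [tartes_correct()] (unit mode) or [tartes_correct_full()] (with the
#' returned T) subtracts when run at `w1 = w`.
#'
#' @param R,delta_R reflectivity and flow-variation arrays of equal dim
#'   (from [build_reflectivity()]).
#' @param w_true positive generating weight.
#' @param unit_transmittance logical; see [phantom_spec()].
#' @param pitch_um voxel pitch (z, x, y) in um for the output volumes.
#' @return An object of class `forward_model_output`: list with structural
#'   volume `S`, angiographic volume `A`, ground truth `A_true_corr` (all
#'   [oct_volume]), transmittance array `T`, variation array `delta_T`, and
#'   `w_true`.
#' @export
forward_model <- function(R, delta_R, w_true, unit_transmittance = TRUE,
                          pitch_um = c(8.1, 2.3, 2.2)) {
  if (!identical(dim(R), dim(delta_R))) stop("R and delta_R must have equal dim", call. = FALSE)
  if (!is.finite(w_true) || w_true <= 0) stop("'w_true' must be > 0", call. = FALSE)
  d <- dim(R)
  if (unit_transmittance) {
    T <- array(1, d)
  } else {
    colsum <- colSums(R)                       # (y, x) totals over depth
    if (any(colsum >= 1)) {
      stop("physicality violation: column sums of R must stay below 1", call. = FALSE)
    }
    T <- 1 - (apply(R, c(2L, 3L), cumsum) - R)  # exclusive prefix sum of R
  }
  delta_T <- sqrt(apply(delta_R^2, c(2L, 3L), cumsum) - delta_R^2)
  S <- T * R / w_true
  A_true <- T * delta_R / w_true
  A <- (delta_T * R + T * delta_R) / w_true
  structure(list(
    S = oct_volume(S, pitch_um, kind = "structural"),
    A = oct_volume(A, pitch_um, kind = "angio"),
    A_true_corr = oct_volume(A_true, pitch_um, kind = "angio"),
    T = T, delta_T = delta_T, w_true = w_true),
    class = "forward_model_output")
}

#' @export
print.forward_model_output <- function(x, ...) {
  cat(sprintf("<forward_model_output: %s grid, w_true = %g>\n",
              paste(dim(x$S), collapse = " x "), x$w_true))
  cat(sprintf("  tail-artifact energy (A - A_true_corr): %g\n",
              sum(unclass(x$A) - unclass(x$A_true_corr))))
  invisible(x)
}

#' Simulate a phantom acquisition
#'
#' Convenience wrapper: rasterizes the spec's reflectivity fields, runs the
#' forward model and, if requested, applies multiplicative noise.
#'
#' @param spec a [phantom_spec].
#' @return A `forward_model_output` (see [forward_model()]).
#' @examples
#' fm <- simulate_phantom(phantom_spec(shape = c(64, 16, 16),
#'   vessels = list(vessel_spec(c(0.25, 0.017), 0.012, "x", 0.002))))
#' range(as.vector(fm$A) - as.vector(fm$A_true_corr))  # tail term >= 0
#' @export
simulate_phantom <- function(spec) {
  fields <- build_reflectivity(spec)
  fm <- forward_model(fields$R, fields$delta_R, spec$w_true,
                      spec$unit_transmittance, spec$pitch_um)
  if (spec$noise_sigma > 0) {
    fm <- add_speckle_noise(fm, spec$noise_sigma, spec$seed)
  }
  fm
}

#' Apply multiplicative speckle-like noise
#'
#' Multiplies the structural and angiographic volumes by independent positive
#' random factors with mean 1 and standard deviation `noise_sigma`, drawn
#' from a Gamma distribution (shape `1/sigma^2`, scale `sigma^2`), then clips
#' at zero. A robustness extension for testing corrector stability, not a
#' model of coherent speckle statistics. Ground truth and transmittance are
#' left untouched. Seeded and reproducible; `noise_sigma = 0` is the
#' identity.
#'
#' @param fm a `forward_model_output`.
#' @param noise_sigma noise factor standard deviation, `>= 0`.
#' @param seed integer seed.
#' @return The modified `forward_model_output`.
#' @export
add_speckle_noise <- function(fm, noise_sigma, seed = 1L) {
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("'noise_sigma' must be >= 0", call. = FALSE)
  }
  if (noise_sigma == 0) return(fm)
  d <- dim(fm$S)
  factors <- with_seed(seed, {
    shape <- 1 / noise_sigma^2
    array(stats::rgamma(2L * prod(d), shape = shape, scale = noise_sigma^2),
          dim = c(d, 2L))
  })
  fm$S <- rewrap(pmax(unclass(fm$S) * factors[, , , 1L], 0), fm$S)
  fm$A <- rewrap(pmax(unclass(fm$A) * factors[, , , 2L], 0), fm$A)
  fm
}

## Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Schematic tail-artifact A-scan
#'
#' The textbook depth profile of the artifact: zero signal above the vessel,
#' a sharp rise to `peak_value` at the vessel layer, then a slow exponential
#' decay beneath it (the tail). The matching ideal profile — what a correct
#' angiogram of the same vessel would show — is a symmetric peak with no
#' tail, returned alongside.
#'
#' @param n_layers total number of depth layers.
#' @param vessel_layer 0-based layer of the vessel, `0 < vessel_layer < n_layers - 1`.
#' @param peak_value peak intensity (> 0).
#' @param decay_constant e-folding depth of the tail in layers (> 0); the
#'   value k layers past the vessel is `peak_value * exp(-k / decay_constant)`.
#' @param pitch_z_um axial pitch for the depth coordinates (default 8.1).
#' @return list with [depth_profile]s `artifact` and `ideal`.
#' @export
schematic_ascan <- function(n_layers, vessel_layer, peak_value = 1,
                            decay_constant = 10, pitch_z_um = 8.1) {
  if (vessel_layer <= 0 || vessel_layer >= n_layers - 1L) {
    stop("'vessel_layer' must lie strictly inside the profile", call. = FALSE)
  }
  if (peak_value <= 0 || decay_constant <= 0) {
    stop("'peak_value' and 'decay_constant' must be > 0", call. = FALSE)
  }
  k <- seq_len(n_layers) - 1L
  artifact <- ifelse(k < vessel_layer, 0,
                     peak_value * exp(-(k - vessel_layer) / decay_constant))
  ideal <- ifelse(k == vessel_layer, peak_value, 0)
  depths <- k * pitch_z_um / 1000
  list(artifact = depth_profile(depths, artifact),
       ideal = depth_profile(depths, ideal))
}
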