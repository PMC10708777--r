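#' TAR-TES tail-artifact correction (unit-transmittance form)
#'
#' Removes tail (projection) artifacts from an OCTA volume by subtracting,
#' layer by layer, the contribution of transmittance variation induced by flow
#' in shallower layers. For each lateral position independently, working from
#' shallow to deep,
#'
#' \deqn{A^{corr}_n = A_n - w_1 \, S_n \sqrt{\sum_{i<n} (A^{corr}_i)^2}}
#'
#' with layer 0 returned unchanged. Non-physical negative amplitudes are set
#' to zero immediately, and the zeroed value is what enters the accumulator
#' for deeper layers (feeding a negative amplitude into a sum of squares would
#' inflate the correction). The single weight \eqn{w_1} sets the correction
#' strength; it absorbs the detection-system proportionality between tissue
#' reflectivity and recorded intensity, so it is dataset-specific and tuned
#' per acquisition (see [sweep_weights()]).
#'
#' @param A angiographic [oct_volume] (preprocessed).
#' @param S structural [oct_volume] on the same grid (preprocessed).
#' @param w1 non-negative correction weight.
#' @return Corrected angiographic volume on the same grid, elementwise
#'   `<= A`, with a `correction` attribute recording the method, weight and
#'   number of voxels clipped to zero.
#' @examples
#' S <- oct_volume(array(c(1, 1, 2), c(3, 1, 1)), c(8.1, 2.3, 2.2))
#' A <- oct_volume(array(c(4, 3, 5), c(3, 1, 1)), c(8.1, 2.3, 2.2), kind = "angio")
#' as.vector(tartes_correct(A, S, w1 = 0.5))  # 4, 1, 5 - sqrt(17)
#' @seealso [tartes_correct_full()] for the depth-resolved transmittance form,
#'   [mean_subtract_correct()] and [sdef_correct()] for the comparators.
#' @export
tartes_correct <- function(A, S, w1) {
  check_weight(w1, "w1")
  stopifnot_same_grid(A, S)
  a <- strip(A); s <- strip(S)
  nz <- dim(a)[1L]
  out <- a
  clipped <- 0L
  acc <- a[1L, , ]^2   # running sum of squared corrected amplitudes
  for (n in seq_len(nz)[-1L]) {
    corr <- a[n, , ] - w1 * s[n, , ] * sqrt(acc)
    clipped <- clipped + sum(corr < 0)
    corr <- pmax(corr, 0)
    out[n, , ] <- corr
    acc <- acc + corr^2
  }
  rewrap(out, A, correction = list(method = "tartes", params = list(w1 = w1),
                                   clipped_voxels = clipped))
}

#' TAR-TES correction with depth-resolved transmittance
#'
#' The full form of the TAR-TES recursion, in which the fraction of incident
#' light reaching each layer is not assumed to be 1:
#'
#' \deqn{A^{corr}_n = A_n - w_1 \frac{S_n}{T_n}
#'       \sqrt{\sum_{i<n} (A^{corr}_i)^2 / T_i^2}}
#'
#' With `T` identically 1 this reduces exactly (bit for bit) to
#' [tartes_correct()]. Clipping and layer-0 handling are identical.
#'
#' @inheritParams tartes_correct
#' @param T transmittance: either a vector of per-layer transmitted fractions
#'   (length `n_layers(A)`) or a per-voxel array of `dim(A)`, all values in
#'   (0, 1]; typically from [estimate_transmittance()].
#' @return Corrected angiographic volume, as for [tartes_correct()].
#' @export
tartes_correct_full <- function(A, S, w1, T) {
  check_weight(w1, "w1")
  stopifnot_same_grid(A, S)
  a <- strip(A); s <- strip(S)
  nz <- dim(a)[1L]
  T <- as_transmittance_array(T, dim(a))
  out <- a
  clipped <- 0L
  acc <- (a[1L, , ] / T[1L, , ])^2
  for (n in seq_len(nz)[-1L]) {
    corr <- a[n, , ] - w1 * (s[n, , ] / T[n, , ]) * sqrt(acc)
    clipped <- clipped + sum(corr < 0)
    corr <- pmax(corr, 0)
    out[n, , ] <- corr
    acc <- acc + (corr / T[n, , ])^2
  }
  rewrap(out, A, correction = list(method = "tartes-full", params = list(w1 = w1),
                                   clipped_voxels = clipped))
}

as_transmittance_array <- function(T, d) {
  T <- unclass(T)
  if (is.null(dim(T)) && length(T) == d[1L]) {
    T <- array(rep(as.numeric(T), prod(d[2:3])), d)
  } else if (!identical(dim(T), d)) {
    stop("'T' must be per-layer (length n_z) or per-voxel (dim of the volume)",
         call. = FALSE)
  }
  attributes(T) <- list(dim = d)
  if (any(T <= 0) || any(T > 1)) {
    stop("transmittance values must lie in (0, 1]", call. = FALSE)
  }
  T
}

#' Estimate a depth-resolved transmittance profile
#'
#' Propagates the transmitted fraction of incident light down each column
#' using the structural image: the reflectivity of layer n is
#' `w1 * S_n / T_n`, and what one layer reflects the next never receives, so
#'
#' \deqn{T_0 = 1, \qquad T_n = T_{n-1} - w_1 \, S_{n-1} / T_{n-1}.}
#'
#' T is non-increasing with depth for any non-negative structural volume.
#' When cumulative reflection would drive `T` to zero or below, the value is
#' clamped at `floor_eps` and a warning reports how many voxels were clamped;
#' a clamped profile signals that `w1` is too large for the volume's
#' intensity scale.
#'
#' @param S structural [oct_volume].
#' @param w1 positive weight relating structural intensity to reflectivity.
#' @param floor_eps positive lower clamp for T (default `1e-3`).
#' @return Per-voxel transmittance array of `dim(S)`, values in (0, 1],
#'   layer 0 identically 1.
#' @export
estimate_transmittance <- function(S, w1, floor_eps = 1e-3) {
  if (!is.numeric(w1) || length(w1) != 1L || !is.finite(w1) || w1 <= 0) {
    stop("'w1' must be a positive scalar", call. = FALSE)
  }
  if (floor_eps <= 0 || floor_eps >= 1) {
    stop("'floor_eps' must be in (0, 1)", call. = FALSE)
  }
  s <- strip(S)
  nz <- dim(s)[1L]
  T <- array(1, dim(s))
  clamped <- 0L
  for (n in seq_len(nz)[-1L]) {
    tn <- T[n - 1L, , ] - w1 * s[n - 1L, , ] / T[n - 1L, , ]
    clamped <- clamped + sum(tn < floor_eps)
    T[n, , ] <- pmax(tn, floor_eps)
  }
  if (clamped > 0L) {
    warning(sprintf(
      "transmittance clamped at %g for %d voxel(s); w1 = %g is likely too large for this intensity scale",
      floor_eps, clamped, w1), call. = FALSE)
  }
  T
}

#' Mean-subtraction tail-artifact correction
#'
#' Subtracts from every layer of a column the same baseline, a weighted mean
#' of the *uncorrected* depth profile:
#'
#' \deqn{A^{corr} = \max\!\left(A - \frac{w_2}{N} \sum_{i=1}^{N} A_i,\; 0\right)}
#'
#' where N is the number of layers. The baseline differs between A-scans but
#' not with depth, so the method acts like a per-column window setting; where
#' the original signal falls below the baseline the corrected image has
#' missing (zero) signal, and unlike TAR-TES or SDEF the shallowest layer is
#' not preserved.
#'
#' @param A angiographic [oct_volume].
#' @param w2 non-negative correction weight.
#' @return Corrected angiographic volume with a `correction` attribute.
#' @export
mean_subtract_correct <- function(A, w2) {
  check_weight(w2, "w2")
  a <- strip(A)
  baseline <- w2 * colMeans(a)          # (y, x) mean over depth
  out <- sweep(a, c(2L, 3L), baseline)
  clipped <- sum(out < 0)
  rewrap(pmax(out, 0), A,
         correction = list(method = "msa", params = list(w2 = w2),
                           clipped_voxels = clipped))
}

#' Step-down exponential filtering correction
#'
#' Attenuates each layer by a factor exponential in the summed corrected
#' signal of all shallower layers:
#'
#' \deqn{A^{corr}_n = A_n \, e^{-w_3 \sum_{i<n} A^{corr}_i}}
#'
#' Layer 0 is unchanged. The scaling factor is always positive, so the output
#' stays strictly positive wherever the input is — this corrector never clips
#' — but tail suppression is correspondingly incomplete.
#'
#' @param A angiographic [oct_volume].
#' @param w3 non-negative correction weight.
#' @return Corrected angiographic volume with a `correction` attribute.
#' @examples
#' A <- oct_volume(array(c(2, 3), c(2, 1, 1)), c(8.1, 2.3, 2.2), kind = "angio")
#' as.vector(sdef_correct(A, w3 = 0.5))  # 2, 3*exp(-1)
#' @export
sdef_correct <- function(A, w3) {
  check_weight(w3, "w3")
  a <- strip(A)
  nz <- dim(a)[1L]
  out <- a
  cum <- a[1L, , ]                      # running sum of corrected amplitudes
  for (n in seq_len(nz)[-1L]) {
    corr <- a[n, , ] * exp(-w3 * cum)
    out[n, , ] <- corr
    cum <- cum + corr
  }
  rewrap(out, A, correction = list(method = "sdef", params = list(w3 = w3),
                                   clipped_voxels = 0L))
}

#' Linearized step-down exponential correction
#'
#' First-order expansion of [sdef_correct()],
#' \eqn{A^{corr}_n = A_n (1 - w_3 \sum_{i<n} A^{corr}_i)} clipped at zero,
#' with the recursion running on its own corrected values. Valid only while
#' the exponent argument is small; intended as a small-correction limit
#' oracle, not as a production corrector — the relative gap to the exact form
#' vanishes quadratically in `w3`.
#'
#' @inheritParams sdef_correct
#' @return Corrected angiographic volume with a `correction` attribute.
#' @export
sdef_linearized <- function(A, w3) {
  check_weight(w3, "w3")
  a <- strip(A)
  nz <- dim(a)[1L]
  out <- a
  clipped <- 0L
  cum <- a[1L, , ]
  for (n in seq_len(nz)[-1L]) {
    corr <- a[n, , ] * (1 - w3 * cum)
    clipped <- clipped + sum(corr < 0)
    corr <- pmax(corr, 0)
    out[n, , ] <- corr
    cum <- cum + corr
  }
  rewrap(out, A, correction = list(method = "sdef-linearized",
                                   params = list(w3 = w3),
                                   clipped_voxels = clipped))
}

check_weight <- function(w, name) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0) {
    stop(sprintf("'%s' must be a non-negative scalar", name), call. = FALSE)
  }
  invisible(TRUE)
}

## Drop class/attributes, keep dim; avoids attribute churn inside layer loops.
strip <- function(v) {
  d <- dim(v)
  v <- unclass(v)
  attributes(v) <- list(dim = d)
  v
}
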