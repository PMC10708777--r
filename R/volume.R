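#' OCT / OCTA volume container
#'
#' Wraps a 3-D array of non-negative intensities together with its voxel
#' geometry. The depth (axial) axis is the first array dimension and the layer
#' index increases with depth, so `values[n + 1, , ]` is the en face slice at
#' physical depth `n * pitch_z_um` micrometres (layer 0 sits at the
#' tissue-facing surface). Lateral axes are y (rows of a slice) then x.
#'
#' Intensities are linear-scale arbitrary units: the correction weights are
#' defined relative to whatever scale the input volumes carry, so no unit
#' conversion is ever applied.
#'
#' @param values 3-D numeric array, `dim = c(n_z, n_y, n_x)`, all entries
#'   finite and `>= 0`.
#' @param pitch_um numeric length-3 voxel pitch in micrometres, in (z, x, y)
#'   order, all `> 0`.
#' @param kind `"structural"` (mean OCT intensity) or `"angio"`
#'   (speckle-variance OCTA intensity).
#'
#' @return An object of class `oct_volume`: the array with attributes
#'   `pitch_um` (named z/x/y vector) and `kind`.
#' @examples
#' v <- oct_volume(array(1, c(4, 2, 2)), pitch_um = c(8.1, 2.3, 2.2))
#' n_layers(v)
#' layer_depths_mm(v)
#' @export
oct_volume <- function(values, pitch_um, kind = c("structural", "angio")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3-D array (depth, y, x)", call. = FALSE)
  }
  if (!is.numeric(pitch_um) || length(pitch_um) != 3L || any(!is.finite(pitch_um)) ||
      any(pitch_um <= 0)) {
    stop("'pitch_um' must be three positive pitches in (z, x, y) order", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("volume intensities must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("volume intensities must be non-negative", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(values,
            pitch_um = c(z = pitch_um[[1L]], x = pitch_um[[2L]], y = pitch_um[[3L]]),
            kind = kind,
            class = "oct_volume")
}

## Rebuild a volume from new values, keeping geometry/kind and optionally a
## provenance record; used by every operation that returns "same type".
rewrap <- function(values, template, correction = NULL) {
  out <- structure(values,
                   pitch_um = attr(template, "pitch_um"),
                   kind = attr(template, "kind"),
                   class = "oct_volume")
  if (!is.null(correction)) attr(out, "correction") <- correction
  out
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x)
  p <- attr(x, "pitch_um")
  cat(sprintf("<oct_volume: %s>\n", attr(x, "kind")))
  cat(sprintf("  %d layers x %d y x %d x voxels, pitch (z,x,y) = (%g, %g, %g) um\n",
              d[1L], d[2L], d[3L], p[["z"]], p[["x"]], p[["y"]]))
  cat(sprintf("  depth span 0 - %.4f mm, intensity range [%g, %g]\n",
              (d[1L] - 1L) * p[["z"]] / 1000, min(x), max(x)))
  corr <- attr(x, "correction")
  if (!is.null(corr)) {
    cat(sprintf("  corrected: %s (%s), %d voxel(s) clipped to zero\n",
                corr$method,
                paste(sprintf("%s=%g", names(corr$params), unlist(corr$params)),
                      collapse = ", "),
                corr$clipped_voxels))
  }
  invisible(x)
}

#' Volume geometry helpers
#'
#' `n_layers()` is the number of depth layers; `layer_depths_mm()` the
#' physical depth of every layer (layer 0 at 0 mm); `max_depth_mm()` the depth
#' of the deepest layer.
#'
#' @param volume an [oct_volume].
#' @return integer count, or numeric vector of depths in mm.
#' @export
n_layers <- function(volume) dim(volume)[1L]

#' @rdname n_layers
#' @export
layer_depths_mm <- function(volume) {
  (seq_len(n_layers(volume)) - 1L) * attr(volume, "pitch_um")[["z"]] / 1000
}

#' @rdname n_layers
#' @export
max_depth_mm <- function(volume) {
  (n_layers(volume) - 1L) * attr(volume, "pitch_um")[["z"]] / 1000
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !isTRUE(all.equal(attr(a, "pitch_um"), attr(b, "pitch_um")))) {
    stop("volumes must share one voxel grid (same shape and pitch)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Depth profile (A-scan)
#'
#' One depth profile at a single lateral position: intensities along depth
#' with their physical depth coordinates.
#'
#' @param depths_mm strictly increasing depth coordinates (mm).
#' @param values non-negative intensities, same length as `depths_mm`.
#' @return An object of class `depth_profile` (a list with `depths_mm`,
#'   `values`).
#' @export
depth_profile <- function(depths_mm, values) {
  if (length(depths_mm) != length(values)) {
    stop("'depths_mm' and 'values' must have equal length", call. = FALSE)
  }
  if (length(depths_mm) > 1L && any(diff(depths_mm) <= 0)) {
    stop("'depths_mm' must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("profile intensities must be non-negative", call. = FALSE)
  structure(list(depths_mm = as.numeric(depths_mm), values = as.numeric(values)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile: %d layers, %.4f - %.4f mm, max %g at %.4f mm>\n",
              length(x$values), x$depths_mm[1L], x$depths_mm[length(x$depths_mm)],
              max(x$values), x$depths_mm[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ..., xlab = "depth (mm)", ylab = "OCTA intensity (a.u.)",
                               type = "l") {
  graphics::plot(x$depths_mm, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
length.depth_profile <- function(x) length(x$values)
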