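#' Save a volume to disk
#'
#' Two formats:
#' \describe{
#'   \item{`rds`}{lossless canonical container — the `oct_volume` object
#'     itself, round-tripping values and pitch bit-exactly.}
#'   \item{`tiff`}{interchange form: a multipage TIFF, one 32-bit page per en
#'     face slice ordered shallow to deep, plus a YAML sidecar
#'     (`<path without extension>.yaml`) carrying the pitches, kind and the
#'     intensity scale. Pages are stored max-normalized because TIFF samples
#'     are confined to [0, 1]; the sidecar `scale` restores the original
#'     units on load, at 32-bit float precision.}
#' }
#' Existing files are never silently overwritten.
#'
#' @param volume an [oct_volume].
#' @param path destination path; extension picks the format when
#'   `format = "auto"` (`.rds` vs `.tif`/`.tiff`).
#' @param format `"auto"`, `"rds"` or `"tiff"`.
#' @param overwrite set `TRUE` to allow replacing existing files.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, format = c("auto", "rds", "tiff"),
                        overwrite = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "rds"
  }
  if (!inherits(volume, "oct_volume")) stop("'volume' must be an oct_volume", call. = FALSE)
  targets <- path
  if (format == "tiff") targets <- c(path, sidecar_path(path))
  exists_already <- file.exists(targets)
  if (any(exists_already) && !overwrite) {
    stop(sprintf("refusing to overwrite %s (use overwrite = TRUE)",
                 paste(targets[exists_already], collapse = ", ")), call. = FALSE)
  }
  if (format == "rds") {
    saveRDS(volume, path)
  } else {
    v <- strip(volume)
    scale <- max(v)
    if (scale <= 0) scale <- 1
    pages <- lapply(seq_len(dim(v)[1L]), function(n) v[n, , , drop = TRUE] / scale)
    pages <- lapply(pages, function(pg) {
      if (is.null(dim(pg))) dim(pg) <- dim(v)[2:3]
      pg
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    p <- attr(volume, "pitch_um")
    yaml::write_yaml(list(pitch_um = as.numeric(c(p[["z"]], p[["x"]], p[["y"]])),
                          kind = attr(volume, "kind"),
                          scale = scale,
                          n_pages = dim(v)[1L]),
                     sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".yaml")

#' Load a volume from disk
#'
#' Reads the formats written by [save_volume()]. For TIFF, pitch comes from
#' the YAML sidecar unless overridden; an explicit `pitch_um` always wins
#' over embedded metadata. Each page must be a single-channel (grayscale)
#' slice; pages are stacked shallow to deep.
#'
#' @param path file to read (`.rds`, or `.tif`/`.tiff` with optional sidecar).
#' @param pitch_um optional length-3 pitch override (z, x, y) in um.
#' @param kind optional kind override (`"structural"` or `"angio"`).
#' @return An [oct_volume].
#' @export
load_volume <- function(path, pitch_um = NULL, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    volume <- readRDS(path)
    if (!inherits(volume, "oct_volume")) {
      stop(sprintf("%s does not contain an oct_volume", path), call. = FALSE)
    }
    if (length(dim(volume)) != 3L) stop("stored data is not 3-D", call. = FALSE)
    if (!is.null(pitch_um)) {
      volume <- oct_volume(strip(volume), pitch_um,
                           kind = kind %||% attr(volume, "kind"))
    } else if (!is.null(kind)) {
      attr(volume, "kind") <- match.arg(kind, c("structural", "angio"))
    }
    return(volume)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L)))) {
    stop("TIFF pages must be single-channel en face slices", call. = FALSE)
  }
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else list()
  pitch <- pitch_um %||% meta$pitch_um
  if (is.null(pitch)) {
    stop("no pitch available: supply 'pitch_um' or provide a YAML sidecar", call. = FALSE)
  }
  scale <- meta$scale %||% 1
  d <- c(length(pages), dim(pages[[1L]]))
  values <- array(0, d)
  for (n in seq_along(pages)) values[n, , ] <- pages[[n]] * scale
  oct_volume(values, pitch, kind = kind %||% meta$kind %||% "structural")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
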