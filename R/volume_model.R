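#' Acquisition metadata for an SS-OCT volume
#'
#' Describes the raster geometry and sampling of a swept-source OCT
#' acquisition: a volume is scanned as `n_locations` B-scan positions, each
#' imaged `n_repeats` times (BM scans), with `n_ascans` axial scans per
#' B-scan and either `n_k` spectral samples per A-scan (raw fringe data) or
#' `n_depth` reconstructed depth pixels.
#'
#' The default values describe a 100 kHz swept-source system acquiring
#' 360 A-scans x 1080 B-scan frames (3 repeats at each of 360 positions)
#' with 2048 spectral samples reconstructed to 1024 depth pixels over an
#' approximately 50 x 50 degree field.
#'
#' @param n_locations Number of B-scan positions (slow axis).
#' @param n_repeats BM scans (repeated B-scans) per position.
#' @param n_ascans A-scans per B-scan (fast axis).
#' @param n_k Spectral samples per A-scan; 0 for pre-reconstructed volumes.
#' @param n_depth Depth pixels per A-scan. Must equal `n_k / 2` when
#'   `n_k > 0` (half-spectrum convention for real-valued fringes).
#' @param axial_um_per_px Axial pixel pitch in tissue, micrometres.
#' @param sweep_rate_hz Laser sweep rate (A-scans per second).
#' @param center_wavelength_nm Source centre wavelength.
#' @param tuning_range_nm Source tuning range.
#' @param scan_angle_deg Field of view, degrees.
#' @return An object of class `AcquisitionMeta`.
#' @export
acquisition_meta <- function(n_locations = 360, n_repeats = 3, n_ascans = 360,
                             n_k = 2048, n_depth = if (n_k > 0) n_k / 2 else 1024,
                             axial_um_per_px = 3.0,
                             sweep_rate_hz = 1e5,
                             center_wavelength_nm = 1060,
                             tuning_range_nm = 100,
                             scan_angle_deg = 50) {
  meta <- structure(list(
    n_locations = as.integer(n_locations), n_repeats = as.integer(n_repeats),
    n_ascans = as.integer(n_ascans), n_k = as.integer(n_k),
    n_depth = as.integer(n_depth), axial_um_per_px = axial_um_per_px,
    sweep_rate_hz = sweep_rate_hz,
    center_wavelength_nm = center_wavelength_nm,
    tuning_range_nm = tuning_range_nm, scan_angle_deg = scan_angle_deg
  ), class = "AcquisitionMeta")
  validate_meta(meta)
  meta
}

validate_meta <- function(meta) {
  for (f in c("n_locations", "n_repeats", "n_ascans", "n_depth")) {
    if (!is_count(meta[[f]])) stop_fmt("AcquisitionMeta$%s must be a count >= 1", f)
  }
  if (!(is.numeric(meta$n_k) && meta$n_k >= 0 && meta$n_k == round(meta$n_k))) {
    stop_fmt("AcquisitionMeta$n_k must be a non-negative integer")
  }
  if (meta$n_k > 0 && meta$n_depth != meta$n_k / 2) {
    stop_fmt("n_depth must equal n_k/2 when n_k > 0 (got n_k=%d, n_depth=%d)",
             meta$n_k, meta$n_depth)
  }
  if (!is_scalar_num(meta$axial_um_per_px) || meta$axial_um_per_px <= 0) {
    stop_fmt("axial_um_per_px must be > 0")
  }
  invisible(meta)
}

#' Raw spectral-fringe volume
#'
#' Container for k-linear spectral interferograms, stored as a 4-D array
#' indexed `[location, repeat, ascan, k]`.
#'
#' @param data 4-D numeric array `[location, repeat, ascan, k]`.
#' @param meta [acquisition_meta()] describing the acquisition.
#' @param dtype On-disk element type tag; one of `"float64"`, `"float32"`,
#'   `"int16"`, `"uint16"`, `"int32"`.
#' @return An object of class `FringeVolume`.
#' @export
fringe_volume <- function(data, meta, dtype = "float64") {
  if (length(dim(data)) != 4) stop_fmt("FringeVolume data must be 4-D")
  expect <- c(meta$n_locations, meta$n_repeats, meta$n_ascans, meta$n_k)
  if (!all(dim(data) == expect)) {
    stop_fmt("FringeVolume shape (%s) does not match meta (%s)",
             paste(dim(data), collapse = ","), paste(expect, collapse = ","))
  }
  if (any(dim(data) == 0)) stop_fmt("empty dimensions are not allowed")
  if (!all(is.finite(data))) stop_fmt("FringeVolume data must be finite")
  check_dtype(dtype)
  structure(list(data = data, meta = meta, dtype = dtype),
            class = "FringeVolume")
}

#' Reconstructed OCT intensity volume
#'
#' In BM form the array is `[location, repeat, depth, ascan]`; once the
#' repeats at each position have been averaged the array is
#' `[location, depth, ascan]`. Depth index 1 is the innermost (vitreous)
#' side, increasing toward the choroid. Log-grayscale volumes hold values
#' in \[0, 1\].
#'
#' @param data 4-D (BM form) or 3-D (averaged) numeric array.
#' @param meta [acquisition_meta()].
#' @param is_averaged Logical; `TRUE` for the 3-D averaged form.
#' @param intensity_domain `"linear"` or `"log_grayscale"`.
#' @param dtype On-disk element type tag.
#' @return An object of class `OCTVolume`.
#' @export
oct_volume <- function(data, meta, is_averaged = FALSE,
                       intensity_domain = c("log_grayscale", "linear"),
                       dtype = "float64") {
  intensity_domain <- match.arg(intensity_domain)
  nd <- length(dim(data))
  if (is_averaged && nd != 3) stop_fmt("averaged OCTVolume must be 3-D")
  if (!is_averaged && nd != 4) stop_fmt("BM-form OCTVolume must be 4-D")
  expect <- if (is_averaged) {
    c(meta$n_locations, meta$n_depth, meta$n_ascans)
  } else {
    c(meta$n_locations, meta$n_repeats, meta$n_depth, meta$n_ascans)
  }
  if (!all(dim(data) == expect)) {
    stop_fmt("OCTVolume shape (%s) does not match meta (%s)",
             paste(dim(data), collapse = ","), paste(expect, collapse = ","))
  }
  if (any(dim(data) == 0)) stop_fmt("empty dimensions are not allowed")
  if (intensity_domain == "log_grayscale" &&
      (min(data) < 0 || max(data) > 1)) {
    stop_fmt("log_grayscale OCTVolume values must lie in [0,1]")
  }
  check_dtype(dtype)
  structure(list(data = data, meta = meta, is_averaged = is_averaged,
                 intensity_domain = intensity_domain, dtype = dtype),
            class = "OCTVolume")
}

#' Detected boundary surface
#'
#' Per-(location, A-scan) depth index of a detected boundary; indices are
#' 0-based and may be fractional.
#'
#' @param z 2-D numeric matrix `[location, ascan]` of depth indices.
#' @param label One of `"ILM_NFL"`, `"RPE_BrM"`, `"generic_top"`.
#' @return An object of class `SurfaceMap`.
#' @export
surface_map <- function(z, label = c("generic_top", "ILM_NFL", "RPE_BrM")) {
  label <- match.arg(label)
  if (!is.matrix(z)) stop_fmt("SurfaceMap z must be a matrix")
  if (anyNA(z)) stop_fmt("SurfaceMap must have no missing values")
  if (min(z) < 0) stop_fmt("SurfaceMap depth indices must be >= 0")
  structure(list(z = z, label = label), class = "SurfaceMap")
}

#' En face (fundus-view) image
#'
#' @param data 2-D numeric matrix `[location, ascan]`.
#' @param kind One of `"fundus_sum"`, `"angio_max"`, `"angio_mean"`.
#' @param slab Optional slab descriptor (see [slab_spec()]).
#' @return An object of class `EnFaceImage`.
#' @export
enface_image <- function(data, kind = c("fundus_sum", "angio_max", "angio_mean"),
                         slab = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(data)) stop_fmt("EnFaceImage data must be a matrix")
  structure(list(data = data, kind = kind, slab = slab), class = "EnFaceImage")
}

#' @export
print.OCTVolume <- function(x, ...) {
  cat(sprintf("<OCTVolume %s %s [%s]>\n",
              if (x$is_averaged) "averaged" else "BM-form",
              x$intensity_domain, paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' @export
print.FringeVolume <- function(x, ...) {
  cat(sprintf("<FringeVolume [%s]>\n", paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' @export
print.SurfaceMap <- function(x, ...) {
  cat(sprintf("<SurfaceMap %s [%s], depth range %.1f..%.1f>\n", x$label,
              paste(dim(x$z), collapse = " x "), min(x$z), max(x$z)))
  invisible(x)
}

# ---- binary container + YAML sidecar -------------------------------------

DTYPES <- list(
  float64 = list(size = 8L, what = "double"),
  float32 = list(size = 4L, what = "double"),
  int32   = list(size = 4L, what = "integer"),
  int16   = list(size = 2L, what = "integer"),
  uint16  = list(size = 2L, what = "integer")
)

check_dtype <- function(dtype) {
  if (!dtype %in% names(DTYPES)) stop_fmt("unknown dtype tag '%s'", dtype)
  invisible(dtype)
}

meta_to_list <- function(meta) {
  m <- unclass(meta)
  lapply(m, function(v) if (is.integer(v)) as.integer(v) else as.numeric(v))
}

meta_from_list <- function(lst) {
  do.call(acquisition_meta, lst[names(formals(acquisition_meta))[
    names(formals(acquisition_meta)) %in% names(lst)]])
}

#' Write a volume to a flat binary container with a YAML sidecar
#'
#' The binary file is a flat little-endian array in C order (location
#' slowest, last axis fastest); the sidecar records the element type, the
#' shape, the volume kind and all acquisition metadata, so the pair is
#' self-describing and memory-mappable from any language.
#'
#' @param vol A [fringe_volume()] or [oct_volume()].
#' @param path Output path for the binary data (conventionally `.oct.raw`).
#' @param meta_path Output path for the YAML sidecar (`.oct.yaml`).
#' @return Invisibly, `path`.
#' @seealso [read_volume()]
#' @export
write_volume <- function(vol, path, meta_path) {
  if (!inherits(vol, c("FringeVolume", "OCTVolume"))) {
    stop_fmt("vol must be a FringeVolume or OCTVolume")
  }
  dims <- dim(vol$data)
  if (any(dims == 0)) stop_fmt("empty dimensions are not allowed")
  dt <- DTYPES[[vol$dtype]]
  # C order: last axis fastest -> reverse axes then flatten column-major
  flat <- as.vector(aperm(vol$data, rev(seq_along(dims))))
  if (dt$what == "integer") flat <- as.integer(round(flat))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (vol$dtype == "uint16") {
    # writeBin has no unsigned type; re-wrap into signed int16 bit pattern
    wv <- ifelse(flat >= 32768L, flat - 65536L, flat)
    writeBin(as.integer(wv), con, size = 2L, endian = "little")
  } else {
    writeBin(flat, con, size = dt$size, endian = "little")
  }
  side <- list(
    container = "oct.raw.v1",
    kind = if (inherits(vol, "FringeVolume")) "fringe" else "oct",
    dtype = vol$dtype,
    shape = as.integer(dims),
    meta = meta_to_list(vol$meta)
  )
  if (inherits(vol, "OCTVolume")) {
    side$is_averaged <- vol$is_averaged
    side$intensity_domain <- vol$intensity_domain
  }
  yaml::write_yaml(side, meta_path)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' Validates that the declared shape times the element size equals the
#' file size before reading; round-trips [write_volume()] bit-exactly.
#'
#' @param path Binary data path.
#' @param meta_path YAML sidecar path.
#' @return A `FringeVolume` or `OCTVolume`, per the sidecar's `kind`.
#' @export
read_volume <- function(path, meta_path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  if (!file.exists(meta_path)) stop_fmt("no such sidecar: %s", meta_path)
  side <- yaml::read_yaml(meta_path)
  if (is.null(side$dtype) || !side$dtype %in% names(DTYPES)) {
    stop_fmt("format error: unknown or missing dtype tag '%s'",
             if (is.null(side$dtype)) "<none>" else side$dtype)
  }
  dt <- DTYPES[[side$dtype]]
  dims <- as.integer(unlist(side$shape))
  n <- prod(dims)
  expected_bytes <- n * dt$size
  actual_bytes <- file.info(path)$size
  if (actual_bytes != expected_bytes) {
    stop_fmt("format error: declared shape (%s) x %d bytes = %d, file has %d bytes",
             paste(dims, collapse = ","), dt$size, expected_bytes, actual_bytes)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  flat <- if (side$dtype == "uint16") {
    raw16 <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                     endian = "little")
    raw16
  } else if (dt$what == "integer") {
    readBin(con, "integer", n = n, size = dt$size, endian = "little")
  } else {
    readBin(con, "double", n = n, size = dt$size, endian = "little")
  }
  arr <- aperm(array(flat, dim = rev(dims)), rev(seq_along(dims)))
  meta <- meta_from_list(side$meta)
  if (identical(side$kind, "fringe")) {
    fringe_volume(arr, meta, dtype = side$dtype)
  } else if (identical(side$kind, "oct")) {
    oct_volume(arr, meta, is_averaged = isTRUE(side$is_averaged),
               intensity_domain = side$intensity_domain, dtype = side$dtype)
  } else {
    stop_fmt("format error: unknown volume kind '%s'", side$kind)
  }
}

#' Export a 2-D image to TIFF, PNG or CSV
#'
#' `tiff16` maps \[0, 1\] linearly to 0..65535 (round half up), `png8` to
#' 0..255, and `csv` writes raw floating-point values.
#'
#' @param img An [enface_image()] or a plain 2-D numeric matrix (e.g. a
#'   B-scan).
#' @param path Output path.
#' @param format One of `"tiff16"`, `"png8"`, `"csv"`.
#' @return Invisibly, `path`.
#' @export
export_image <- function(img, path, format = c("tiff16", "png8", "csv")) {
  format <- match.arg(format)
  m <- if (inherits(img, "EnFaceImage")) img$data else img
  if (!is.matrix(m)) stop_fmt("img must be a matrix or EnFaceImage")
  if (!all(is.finite(m))) stop_fmt("image contains non-finite values; mask before export")
  if (format == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (format == "tiff16") {
    q <- floor(clamp01(m) * 65535 + 0.5)
    tiff::writeTIFF(q / 65535, path, bits.per.sample = 16L, compression = "none")
  } else {
    q <- floor(clamp01(m) * 255 + 0.5)
    png::writePNG(q / 255, path)
  }
  invisible(path)
}
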