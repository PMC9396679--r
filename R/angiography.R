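#' Interframe speckle variance of a BM stack
#'
#' The flow-contrast statistic: per voxel, the population variance of the
#' intensity over the N registered repeat frames,
#' `sv = (1/N) * sum_i (I_i - Ibar)^2`, computed on the log-grayscale
#' structural frames.
#'
#' @param stack 3-D array `[repeat, depth, ascan]` with N >= 2 registered
#'   repeats.
#' @return 2-D matrix `[depth, ascan]` of nonnegative variances.
#' @export
speckle_variance <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3) stop_fmt("stack must be 3-D [repeat, depth, ascan]")
  if (d[1] < 2) stop_fmt("N < 2 repeats: speckle variance undefined")
  m <- matrix(stack, d[1], d[2] * d[3])
  mu <- colMeans(m)
  sv <- colMeans(sweep(m, 2, mu)^2)
  matrix(sv, d[2], d[3])
}

#' Build a speckle-variance angiography volume
#'
#' Per location: the repeat frames are registered to the first frame
#' (subpixel, via the registration module) and the interframe speckle
#' variance is computed. The output is voxel-aligned with the structural
#' volume, so surfaces segmented on the structural pipeline apply
#' directly; any axial alignment / flattening shifts computed there can be
#' applied to this volume with the same offsets.
#'
#' @param vol BM-form log-grayscale [oct_volume()].
#' @param upsample Subpixel registration precision.
#' @param register Set `FALSE` to skip interframe registration (frames
#'   already aligned).
#' @return An object of class `AngioVolume`: `data` is
#'   `[location, depth, ascan]`, `meta` the acquisition metadata.
#' @export
build_angio_volume <- function(vol, upsample = 10, register = TRUE) {
  stopifnot(inherits(vol, "OCTVolume"), !vol$is_averaged)
  meta <- vol$meta
  if (meta$n_repeats < 2) stop_fmt("N < 2 repeats: speckle variance undefined")
  out <- array(0, dim = c(meta$n_locations, meta$n_depth, meta$n_ascans))
  for (l in seq_len(meta$n_locations)) {
    st <- array(vol$data[l, , , ], dim = dim(vol$data)[2:4])
    if (register) {
      ref <- matrix(st[1, , ], meta$n_depth, meta$n_ascans)
      for (r in 2:meta$n_repeats) {
        fr <- matrix(st[r, , ], meta$n_depth, meta$n_ascans)
        sh <- tryCatch(estimate_shift_subpixel(ref, fr, upsample = upsample),
                       error = function(e) c(0, 0))
        if (any(sh != 0)) st[r, , ] <- apply_shift(fr, -sh[1], -sh[2])
      }
    }
    out[l, , ] <- speckle_variance(st)
  }
  structure(list(data = out, meta = meta), class = "AngioVolume")
}

#' @export
print.AngioVolume <- function(x, ...) {
  cat(sprintf("<AngioVolume [%s]>\n", paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Depth slab specification
#'
#' A slab is bounded by offsets from the segmented surfaces. Offsets can
#' be absolute pixels (`top_offset_px`) and/or fractions of the local
#' ILM-to-RPE distance (`top_frac`), resolved per column at projection
#' time.
#'
#' @param name Slab label.
#' @param top_ref,bottom_ref `"ILM"` or `"RPE"`.
#' @param top_offset_px,bottom_offset_px Absolute pixel offsets.
#' @param top_frac,bottom_frac Fractions of the local retinal thickness
#'   added to the respective reference.
#' @return An object of class `SlabSpec`.
#' @export
slab_spec <- function(name, top_ref = c("ILM", "RPE"), top_offset_px = 0,
                      bottom_ref = c("ILM", "RPE"), bottom_offset_px = 0,
                      top_frac = 0, bottom_frac = 0) {
  structure(list(name = name, top_ref = match.arg(top_ref),
                 top_offset_px = top_offset_px,
                 bottom_ref = match.arg(bottom_ref),
                 bottom_offset_px = bottom_offset_px,
                 top_frac = top_frac, bottom_frac = bottom_frac),
            class = "SlabSpec")
}

#' Anatomical slab presets
#'
#' Percent-of-thickness slabs adapt across species: superficial plexus
#' \[ILM, ILM + 25% thickness), intermediate \[+25%, +55%), deep
#' \[+55%, RPE), choroid \[RPE, RPE + 60 px), full \[ILM, RPE + 60 px).
#' The named plexuses correspond anatomically to the NFL/GCL, IPL
#' borders, and INL-OPL vascular beds; the choroid slab covers the
#' choriocapillaris and larger choroidal vessels below Bruch's membrane.
#'
#' @param name One of `"superficial"`, `"intermediate"`, `"deep"`,
#'   `"choroid"`, `"full"`.
#' @return A [slab_spec()].
#' @export
slab_preset <- function(name = c("superficial", "intermediate", "deep",
                                 "choroid", "full")) {
  name <- match.arg(name)
  switch(name,
    superficial = slab_spec("superficial", "ILM", 0, "ILM", 0, 0, 0.25),
    intermediate = slab_spec("intermediate", "ILM", 0, "ILM", 0, 0.25, 0.55),
    deep = slab_spec("deep", "ILM", 0, "RPE", 0, 0.55, 0),
    choroid = slab_spec("choroid", "RPE", 0, "RPE", 60),
    full = slab_spec("full", "ILM", 0, "RPE", 60))
}

resolve_slab <- function(slab, ilm, rpe) {
  th <- rpe$z - ilm$z
  base_top <- if (slab$top_ref == "ILM") ilm$z else rpe$z
  base_bot <- if (slab$bottom_ref == "ILM") ilm$z else rpe$z
  top <- base_top + slab$top_offset_px + slab$top_frac * th
  bot <- base_bot + slab$bottom_offset_px + slab$bottom_frac * th
  list(top = top, bottom = bot)
}

#' En face projection of a slab
#'
#' Projects each (location, A-scan) column over the half-open depth
#' interval `[top, bottom)` resolved from the surfaces plus the slab's
#' offsets, using the named statistic. The interval is clipped to the
#' depth range with a warning; an empty slab after clipping is an error.
#'
#' @param vol3d An `AngioVolume`, an averaged `OCTVolume`, or a plain 3-D
#'   array `[location, depth, ascan]`.
#' @param ilm,rpe [surface_map()]s covering the grid.
#' @param slab A [slab_spec()].
#' @param mode `"max"`, `"mean"` or `"sum"`.
#' @return An [enface_image()] (`kind` follows `mode`).
#' @export
enface_project <- function(vol3d, ilm, rpe, slab = slab_preset("superficial"),
                           mode = c("max", "mean", "sum")) {
  mode <- match.arg(mode)
  arr <- if (inherits(vol3d, c("AngioVolume", "OCTVolume"))) vol3d$data else vol3d
  d <- dim(arr)
  if (length(d) != 3) stop_fmt("vol3d must be 3-D [location, depth, ascan]")
  nl <- d[1]; nz <- d[2]; nx <- d[3]
  rs <- resolve_slab(slab, ilm, rpe)
  top <- matrix(as.integer(round(rs$top)), nl, nx)
  bot <- matrix(as.integer(round(rs$bottom)), nl, nx)
  clipped <- any(top < 0) || any(bot > nz)
  top <- pmax(top, 0L); bot <- pmin(bot, nz)
  if (clipped) warning("slab clipped to the volume depth range")
  if (all(bot <= top)) stop_fmt("slab '%s' is empty after clipping", slab$name)
  fn <- switch(mode, max = max, mean = mean, sum = sum)
  out <- matrix(0, nl, nx)
  for (l in seq_len(nl)) {
    bs <- matrix(arr[l, , ], nz, nx)
    for (x in seq_len(nx)) {
      t0 <- top[l, x]; b0 <- bot[l, x]
      out[l, x] <- if (b0 > t0) fn(bs[(t0 + 1):b0, x]) else 0
    }
  }
  kind <- switch(mode, max = "angio_max", mean = "angio_mean", sum = "fundus_sum")
  enface_image(out, kind, slab = slab)
}

#' Sum-projection OCT fundus image
#'
#' Full-depth axial sum of an averaged structural volume, min-max
#' normalized to \[0, 1\] (a constant image maps to all zeros).
#'
#' @param vol Averaged [oct_volume()].
#' @return An [enface_image()] of kind `fundus_sum`.
#' @export
oct_fundus <- function(vol) {
  stopifnot(inherits(vol, "OCTVolume"), vol$is_averaged)
  s <- apply(vol$data, c(1, 3), sum)
  rng <- range(s)
  out <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else s * 0
  enface_image(out, "fundus_sum")
}

#' Background subtraction and contrast stretching
#'
#' Subtracts a large-kernel Gaussian background estimate, clips negatives
#' to zero, then linearly maps the `[p_lo, p_hi]` percentile range to
#' \[0, 1\] with clipping. Degenerate ranges map to all zeros.
#'
#' @param img An [enface_image()] or matrix.
#' @param background_sigma_px Gaussian sigma of the background estimate.
#' @param stretch_percentiles `c(p_lo, p_hi)` in (0, 100), `p_lo < p_hi`.
#' @return Same type as the input, values in \[0, 1\].
#' @export
enhance_contrast <- function(img, background_sigma_px = 25,
                             stretch_percentiles = c(1, 99)) {
  p <- stretch_percentiles
  if (p[1] >= p[2]) stop_fmt("p_lo must be < p_hi")
  m <- if (inherits(img, "EnFaceImage")) img$data else img
  if (!all(is.finite(m))) stop_fmt("image contains non-finite values")
  rad <- 2 * ceiling(3 * background_sigma_px) + 1
  mdim <- min(dim(m))
  if (rad > mdim) rad <- mdim - (1 - mdim %% 2)   # largest odd radius that fits
  bg <- EBImage::gblur(m, sigma = background_sigma_px, radius = rad)
  g <- pmax(m - bg, 0)
  q <- stats::quantile(g, p / 100, names = FALSE)
  out <- if (q[2] > q[1]) clamp01((g - q[1]) / (q[2] - q[1])) else g * 0
  if (inherits(img, "EnFaceImage")) {
    enface_image(out, img$kind, img$slab)
  } else out
}
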