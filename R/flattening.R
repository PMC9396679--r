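#' Flattening parameters
#'
#' Controls the per-B-scan surface detection chain (Gaussian blur, 2-D
#' median filter, thresholding, Canny edge detection, first-edge pick,
#' 1-D median smoothing) and the target centre depth for the circular
#' A-line shifts.
#'
#' @param gauss_sigma_px Gaussian blur sigma for speckle reduction.
#' @param median_kernel_px Width (odd) of the 2-D median filter.
#' @param threshold_method `"otsu"` or `"percentile"`: pixels below the
#'   threshold are zeroed (removes noise above the surface).
#' @param percentile_q Percentile (0..100) used when
#'   `threshold_method = "percentile"`.
#' @param canny_sigma Gaussian sigma of the Canny gradient.
#' @param canny_low,canny_high Hysteresis thresholds relative to the
#'   maximum gradient magnitude (`canny_low < canny_high`).
#' @param surface_median_window Width (odd) of the 1-D median filter
#'   applied to the detected edge-row profile.
#' @param center_depth_px Depth every A-line surface is shifted to; `NULL`
#'   selects `n_depth / 3` at flattening time.
#' @return An object of class `FlattenParams`.
#' @export
flatten_params <- function(gauss_sigma_px = 2, median_kernel_px = 3,
                           threshold_method = c("otsu", "percentile"),
                           percentile_q = 75,
                           canny_sigma = 2, canny_low = 0.1, canny_high = 0.3,
                           surface_median_window = 15,
                           center_depth_px = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (median_kernel_px %% 2 != 1) stop_fmt("median_kernel_px must be odd")
  if (surface_median_window %% 2 != 1) stop_fmt("surface_median_window must be odd")
  if (percentile_q <= 0 || percentile_q >= 100) stop_fmt("percentile_q must lie in (0,100)")
  if (canny_low >= canny_high) stop_fmt("canny_low must be < canny_high")
  structure(list(gauss_sigma_px = gauss_sigma_px,
                 median_kernel_px = as.integer(median_kernel_px),
                 threshold_method = threshold_method, percentile_q = percentile_q,
                 canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high,
                 surface_median_window = as.integer(surface_median_window),
                 center_depth_px = center_depth_px),
            class = "FlattenParams")
}

shift_mat <- function(m, dz, dx) {
  # non-circular shift, padding with 0
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  rs <- max(1, 1 + dz):min(n, n + dz)
  cs <- max(1, 1 + dx):min(p, p + dx)
  out[rs, cs] <- m[rs - dz, cs - dx]
  out
}

# Canny edge detector: Gaussian-smoothed central-difference gradient,
# non-maximum suppression along the quantized gradient direction, and
# hysteresis linking via connected components.
canny_edges <- function(img, sigma = 2, low = 0.1, high = 0.3) {
  sm <- if (sigma > 0) {
    EBImage::gblur(img, sigma = sigma, boundary = "replicate")
  } else img
  n <- nrow(sm); p <- ncol(sm)
  gz <- (shift_mat(sm, -1, 0) - shift_mat(sm, 1, 0)) / 2   # d/d(row)
  gx <- (shift_mat(sm, 0, -1) - shift_mat(sm, 0, 1)) / 2   # d/d(col)
  mag <- sqrt(gz^2 + gx^2)
  mag[c(1, n), ] <- 0   # differences at the border see padding, not tissue
  mag[, c(1, p)] <- 0
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, n, p))
  ang <- atan2(gz, gx)             # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:horiz 1:diag 2:vert 3:anti-diag
  nms <- matrix(FALSE, n, p)
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0, 1), "1" = c(1, 1), "2" = c(1, 0), "3" = c(1, -1))
    sel <- sector == s
    fwd <- shift_mat(mag, d[1], d[2])
    bck <- shift_mat(mag, -d[1], -d[2])
    nms[sel] <- mag[sel] >= fwd[sel] & mag[sel] >= bck[sel]
  }
  strong <- nms & mag >= high * mx
  weak <- nms & mag >= low * mx
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, n, p) & weak
}

#' Detect the retinal top surface in one B-scan
#'
#' Gaussian blur, 2-D median filter, thresholding (zeroing sub-threshold
#' pixels, notably the noise above the surface), Canny edge detection,
#' then per A-line the first nonzero edge row scanning from depth 0
#' downward; a 1-D median filter removes outlier columns and columns with
#' no detected edge are filled by linear interpolation between their
#' nearest detected neighbours (constant extension at the ends).
#'
#' @param bscan 2-D matrix `[depth, ascan]`, values in \[0, 1\].
#' @param params A [flatten_params()].
#' @return Numeric vector of 0-based surface depth rows, one per A-scan.
#' @export
detect_surface_bscan <- function(bscan, params = flatten_params()) {
  if (!all(is.finite(bscan))) stop_fmt("B-scan contains non-finite values")
  img <- clamp01(bscan)
  if (params$gauss_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = params$gauss_sigma_px,
                          boundary = "replicate")
  }
  if (params$median_kernel_px > 1) {
    img <- EBImage::medianFilter(clamp01(img),
                                 size = (params$median_kernel_px - 1L) / 2L)
  }
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(clamp01(img)))
  } else {
    stats::quantile(img, params$percentile_q / 100, names = FALSE)
  }
  img[img < thr] <- 0
  edges <- canny_edges(img, sigma = params$canny_sigma,
                       low = params$canny_low, high = params$canny_high)
  if (!any(edges)) stop_fmt("no edges detected in B-scan")
  first_row <- apply(edges, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] - 1L else NA_integer_
  })
  det <- which(!is.na(first_row))
  z <- as.numeric(first_row)
  if (length(det) < length(z)) {
    z <- stats::approx(det, z[det], xout = seq_along(z), rule = 2)$y
  }
  k <- min(params$surface_median_window,
           if (length(z) %% 2 == 1) length(z) else length(z) - 1)
  if (k >= 3) z <- stats::runmed(z, k, endrule = "median")
  as.numeric(z)
}

#' Flatten a volume to a common surface depth
#'
#' Detects the top surface of every B-scan and circularly shifts each
#' A-line by the (rounded) distance between its detected surface and the
#' target centre depth, so the surface lands on `center_depth_px`. The
#' voxel multiset of every A-line is preserved exactly.
#'
#' @param vol Aligned averaged [oct_volume()].
#' @param params A [flatten_params()].
#' @return List with `volume` (flattened `OCTVolume`), `surface` (the
#'   pre-flattening [surface_map()], label `generic_top`) and
#'   `center_depth_px`.
#' @export
flatten_volume <- function(vol, params = flatten_params()) {
  stopifnot(inherits(vol, "OCTVolume"), vol$is_averaged)
  meta <- vol$meta
  center <- params$center_depth_px
  if (is.null(center)) center <- round(meta$n_depth / 3)
  z <- matrix(0, meta$n_locations, meta$n_ascans)
  out <- vol$data
  for (l in seq_len(meta$n_locations)) {
    bs <- matrix(vol$data[l, , ], meta$n_depth, meta$n_ascans)
    zl <- detect_surface_bscan(bs, params)
    z[l, ] <- zl
    sh <- as.integer(round(center - zl))
    for (x in seq_len(meta$n_ascans)) {
      if (sh[x] != 0) out[l, , x] <- roll_vec(bs[, x], sh[x])
    }
  }
  list(volume = oct_volume(out, meta, is_averaged = TRUE,
                           intensity_domain = vol$intensity_domain),
       surface = surface_map(z, "generic_top"),
       center_depth_px = center)
}
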