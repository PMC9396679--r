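# Signed FFT frequency indices 0, 1, ..., n/2, -(n/2-1), ..., -1 (even n)
fft_freq_idx <- function(n) {
  half <- floor(n / 2)
  c(0:half, seq_len(n - half - 1) - (n - half))
}

# Subpixel circular translation via the Fourier shift theorem; positive
# shifts move content toward larger indices. Exact (to rounding) for
# integer shifts.
fourier_shift <- function(img, dz, dx) {
  n <- nrow(img); m <- ncol(img)
  kz <- fft_freq_idx(n) / n
  kx <- fft_freq_idx(m) / m
  G <- stats::fft(img)
  ph <- exp(-2i * pi * (outer(kz * dz, kx * dx, "+")))
  Re(stats::fft(G * ph, inverse = TRUE)) / (n * m)
}

#' Subpixel translation of an image
#'
#' Circular translation by the Fourier shift theorem. Integer shifts
#' reproduce an array roll to within 1e-10.
#'
#' @param img 2-D numeric matrix (finite values).
#' @param dz,dx Shift along rows (depth) and columns; positive moves
#'   content toward larger indices.
#' @return Shifted matrix of the same shape.
#' @export
apply_shift <- function(img, dz, dx) {
  if (!all(is.finite(img))) stop_fmt("image contains non-finite values")
  if (dz == round(dz) && dx == round(dx)) {
    out <- roll_rows(img, as.integer(round(dz)))
    return(t(roll_rows(t(out), as.integer(round(dx)))))
  }
  fourier_shift(img, dz, dx)
}

# Local upsampled inverse DFT of a cross-power spectrum (matrix-multiply
# DFT): evaluates the correlation surface on a grid of spacing 1/usfac
# centred at (roff, coff), size nor x noc.
dftups <- function(CP, nor, noc, usfac, roff, coff) {
  n <- nrow(CP); m <- ncol(CP)
  kz <- fft_freq_idx(n)
  kx <- fft_freq_idx(m)
  rows <- roff + (0:(nor - 1)) / usfac
  cols <- coff + (0:(noc - 1)) / usfac
  Er <- exp(2i * pi * outer(rows, kz) / n)     # [nor, n]
  Ec <- exp(2i * pi * outer(kx, cols) / m)     # [m, noc]
  Re(Er %*% CP %*% Ec)
}

#' Estimate a subpixel translation between two images
#'
#' FFT phase correlation: the integer peak of the inverse-transformed
#' cross-power spectrum gives the coarse shift; a matrix-multiply DFT
#' evaluates the correlation surface on a `1/upsample`-pixel grid around
#' it for the subpixel refinement. `estimate_shift_subpixel(ref, mov)`
#' returns the displacement of `mov` relative to `ref`: if
#' `mov == apply_shift(ref, 3, -2)` the estimate is `(3, -2)`, and
#' `apply_shift(mov, -dz, -dx)` re-aligns `mov` to `ref`.
#'
#' @param ref,mov 2-D numeric matrices of the same shape, non-constant.
#' @param upsample Integer >= 1; precision is `1/upsample` pixel.
#' @return Numeric vector `c(dz, dx)`.
#' @export
estimate_shift_subpixel <- function(ref, mov, upsample = 10) {
  if (!all(dim(ref) == dim(mov))) stop_fmt("images must have the same shape")
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    stop_fmt("constant image: phase correlation undefined")
  }
  upsample <- max(1L, as.integer(upsample))
  n <- nrow(ref); m <- ncol(ref)
  F1 <- stats::fft(ref); F2 <- stats::fft(mov)
  CP <- F1 * Conj(F2)
  CPn <- CP / (Mod(CP) + .Machine$double.eps)
  corr <- Re(stats::fft(CPn, inverse = TRUE))
  pk <- which.max(corr)
  pz <- (pk - 1) %% n
  px <- (pk - 1) %/% n
  if (pz > n / 2) pz <- pz - n
  if (px > m / 2) px <- px - m
  dz <- -pz; dx <- -px
  if (upsample > 1) {
    nb <- ceiling(1.5 * upsample)
    roff <- -dz - (nb %/% 2) / upsample
    coff <- -dx - (nb %/% 2) / upsample
    loc <- dftups(CPn, nb, nb, upsample, roff, coff)
    pk2 <- which.max(loc)
    rz <- (pk2 - 1) %% nb
    rx <- (pk2 - 1) %/% nb
    dz <- -(roff + rz / upsample)
    dx <- -(coff + rx / upsample)
  }
  c(dz = dz, dx = dx)
}

#' Register and average the repeated B-scans of one position
#'
#' Frame 1 is the reference; each later frame is registered to it with
#' [estimate_shift_subpixel()] and re-aligned by the Fourier shift theorem
#' before the arithmetic mean is taken.
#'
#' @param stack 3-D array `[repeat, depth, ascan]` with >= 1 repeat.
#' @param upsample Subpixel registration precision (1/upsample px).
#' @return List with `bscan` (2-D averaged B-scan `[depth, ascan]`) and
#'   `shifts` (matrix `[repeat, 2]` of per-frame `(dz, dx)`; frame 1 is
#'   `(0, 0)`).
#' @export
average_bm_scans <- function(stack, upsample = 10) {
  d <- dim(stack)
  if (length(d) != 3) stop_fmt("stack must be 3-D [repeat, depth, ascan]")
  nrep <- d[1]
  ref <- matrix(stack[1, , ], d[2], d[3])
  shifts <- matrix(0, nrep, 2, dimnames = list(NULL, c("dz", "dx")))
  if (nrep == 1) return(list(bscan = ref, shifts = shifts))
  acc <- ref
  for (r in 2:nrep) {
    fr <- matrix(stack[r, , ], d[2], d[3])
    sh <- estimate_shift_subpixel(ref, fr, upsample = upsample)
    shifts[r, ] <- sh
    acc <- acc + apply_shift(fr, -sh[1], -sh[2])
  }
  list(bscan = acc / nrep, shifts = shifts)
}

#' Average all BM stacks of a volume
#'
#' Applies [average_bm_scans()] at every location of a BM-form volume.
#'
#' @param vol BM-form [oct_volume()].
#' @param upsample Subpixel precision.
#' @return List with `volume` (averaged `OCTVolume`) and `shifts`
#'   (array `[location, repeat, 2]`).
#' @export
average_volume <- function(vol, upsample = 10) {
  stopifnot(inherits(vol, "OCTVolume"), !vol$is_averaged)
  meta <- vol$meta
  out <- array(0, dim = c(meta$n_locations, meta$n_depth, meta$n_ascans))
  shifts <- array(0, dim = c(meta$n_locations, meta$n_repeats, 2))
  for (l in seq_len(meta$n_locations)) {
    st <- array(vol$data[l, , , ], dim = dim(vol$data)[2:4])
    av <- average_bm_scans(st, upsample = upsample)
    out[l, , ] <- av$bscan
    shifts[l, , ] <- av$shifts
  }
  dat <- if (vol$intensity_domain == "log_grayscale") clamp01(out) else out
  list(volume = oct_volume(dat, meta, is_averaged = TRUE,
                           intensity_domain = vol$intensity_domain),
       shifts = shifts)
}

# Best circular NCC lag between profiles a and b within +/- max_lag:
# returns the axial displacement of b relative to a (b == roll(a, j) -> j).
best_ncc_lag <- function(a, b, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(j) {
    suppressWarnings(stats::cor(a, roll_vec(b, -j)))
  }, numeric(1))
  cc[is.na(cc)] <- -Inf
  lags[which.max(cc)]
}

#' Axially align the B-scans of an averaged volume
#'
#' Each B-scan is collapsed to its mean axial profile (mean over A-scans);
#' starting from a reference B-scan, each neighbour is registered to its
#' already-aligned neighbour by the integer lag maximizing circular
#' normalized cross-correlation within `+/- max_lag`, offsets are
#' accumulated outward in both directions, and every B-scan is circularly
#' rolled by minus its offset.
#'
#' @param vol Averaged [oct_volume()].
#' @param ref_index Reference location (1-based), or `"auto"` to use the
#'   location with maximal total intensity.
#' @param max_lag Maximum axial lag searched (< `n_depth / 2`).
#' @return List with `volume` (aligned `OCTVolume`) and `offsets`
#'   (integer per-location axial displacement relative to the reference;
#'   `offsets[ref_index] == 0`).
#' @export
axial_align_volume <- function(vol, ref_index = "auto", max_lag = 50) {
  stopifnot(inherits(vol, "OCTVolume"), vol$is_averaged)
  meta <- vol$meta
  nl <- meta$n_locations
  if (max_lag >= meta$n_depth / 2) {
    stop_fmt("max_lag must be < n_depth/2")
  }
  prof <- sapply(seq_len(nl), function(l) {
    rowMeans(matrix(vol$data[l, , ], meta$n_depth, meta$n_ascans))
  })                                           # [depth, location]
  if (identical(ref_index, "auto")) {
    ref_index <- which.max(colSums(prof))
  }
  if (!is_count(ref_index) || ref_index > nl) stop_fmt("invalid ref_index")
  offsets <- integer(nl)
  if (nl > 1) {
    if (ref_index < nl) {
      for (l in (ref_index + 1):nl) {
        aligned_prev <- roll_vec(prof[, l - 1], -offsets[l - 1])
        offsets[l] <- best_ncc_lag(aligned_prev, prof[, l], max_lag)
      }
    }
    if (ref_index > 1) {
      for (l in (ref_index - 1):1) {
        aligned_next <- roll_vec(prof[, l + 1], -offsets[l + 1])
        offsets[l] <- best_ncc_lag(aligned_next, prof[, l], max_lag)
      }
    }
  }
  out <- vol$data
  for (l in seq_len(nl)) {
    if (offsets[l] != 0) {
      out[l, , ] <- roll_rows(matrix(vol$data[l, , ], meta$n_depth,
                                     meta$n_ascans), -offsets[l])
    }
  }
  list(volume = oct_volume(out, meta, is_averaged = TRUE,
                           intensity_domain = vol$intensity_domain),
       offsets = offsets, ref_index = ref_index)
}
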