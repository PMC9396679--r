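#' Reconstruction parameters
#'
#' @param dispersion_c2,dispersion_c3 Dispersion-compensation phase
#'   polynomial coefficients (radians per normalized-k squared / cubed).
#'   The compensating phase `exp(-i (c2 k^2 + c3 k^3))` is applied to the
#'   analytic fringe signal, with k the centred spectral coordinate
#'   normalized to \[-1, 1\].
#' @param floor_db,ceil_db Grayscale display dynamic range: the dB profile
#'   is mapped affinely from `[floor_db, ceil_db]` to \[0, 1\] and clipped.
#'   Magnitudes are normalized so a unit-amplitude on-bin reflector sits at
#'   0 dB.
#' @param epsilon Log guard added to the magnitude before `20*log10`.
#' @return An object of class `ReconParams`.
#' @export
recon_params <- function(dispersion_c2 = 0, dispersion_c3 = 0,
                         floor_db = -30, ceil_db = 60, epsilon = 1e-9) {
  if (ceil_db <= floor_db) stop_fmt("ceil_db must exceed floor_db")
  if (epsilon <= 0) stop_fmt("epsilon must be > 0")
  structure(list(dispersion_c2 = dispersion_c2, dispersion_c3 = dispersion_c3,
                 floor_db = floor_db, ceil_db = ceil_db, epsilon = epsilon),
            class = "ReconParams")
}

# One-sided-spectrum analytic signal of the columns of a real matrix.
analytic_signal <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  h[1] <- 1
  h[n / 2 + 1] <- 1
  h[2:(n / 2)] <- 2
  Xa <- X * h
  stats::mvfft(Xa, inverse = TRUE) / n
}

# Core of the reconstruction chain for a frame of fringes (columns =
# A-lines, rows = k samples). Returns complex spectrum magnitudes for the
# first n_k/2 bins, normalized by the window sum.
recon_magnitudes <- function(fr, params) {
  n <- nrow(fr)
  a <- analytic_signal(fr)
  if (params$dispersion_c2 != 0 || params$dispersion_c3 != 0) {
    kap <- 2 * (0:(n - 1)) / (n - 1) - 1
    ph <- exp(-1i * (params$dispersion_c2 * kap^2 + params$dispersion_c3 * kap^3))
    a <- a * ph
  }
  w <- hann_window(n)
  X <- stats::mvfft(a * w)
  Mod(X[1:(n / 2), , drop = FALSE]) / sum(w)
}

db_to_gray <- function(db, params) {
  clamp01((db - params$floor_db) / (params$ceil_db - params$floor_db))
}

#' Reconstruct one A-scan from a spectral fringe
#'
#' Fixed processing order: reference-spectrum (DC) subtraction, analytic
#' signal, dispersion compensation, Hann window, FFT keeping the first
#' `n_k/2` magnitude bins, `20*log10(mag + epsilon)`, and an affine map of
#' `[floor_db, ceil_db]` to \[0, 1\] with clipping.
#'
#' @param fringe Real numeric vector of even length `n_k >= 8`.
#' @param params A [recon_params()].
#' @param reference Reference spectrum to subtract; default is the
#'   fringe's own mean (scalar DC removal). Within a volume the per-frame
#'   mean fringe is used instead (see [reconstruct_volume()]).
#' @param output `"grayscale"` (default), `"db"`, or `"linear"` (squared
#'   normalized magnitude, i.e. intensity).
#' @return Numeric vector of length `n_k/2` (depth profile).
#' @export
reconstruct_ascan <- function(fringe, params = recon_params(),
                              reference = NULL,
                              output = c("grayscale", "db", "linear")) {
  output <- match.arg(output)
  n <- length(fringe)
  if (n < 8 || n %% 2 != 0) stop_fmt("fringe length must be even and >= 8")
  if (!all(is.finite(fringe))) stop_fmt("fringe contains non-finite values")
  ref <- if (is.null(reference)) mean(fringe) else reference
  mag <- recon_magnitudes(cbind(fringe - ref), params)[, 1]
  switch(output,
         linear = mag^2,
         db = 20 * log10(mag + params$epsilon),
         grayscale = db_to_gray(20 * log10(mag + params$epsilon), params))
}

#' Reconstruct a full fringe volume
#'
#' Applies the A-scan chain to every fringe in the volume. The reference
#' spectrum subtracted from each frame is that frame's mean fringe over
#' all of its A-scans (per-frame common-mode removal, tolerant of slow
#' source drift).
#'
#' @param fv A [fringe_volume()].
#' @param params A [recon_params()].
#' @return BM-form log-grayscale [oct_volume()] of shape
#'   `[n_locations, n_repeats, n_k/2, n_ascans]`.
#' @export
reconstruct_volume <- function(fv, params = recon_params()) {
  stopifnot(inherits(fv, "FringeVolume"))
  meta <- fv$meta
  if (meta$n_k == 0) {
    stop_fmt("volume is already reconstructed (n_k = 0); skip this stage")
  }
  nl <- meta$n_locations; nr <- meta$n_repeats
  nx <- meta$n_ascans; nk <- meta$n_k
  nz <- nk / 2
  out <- array(0, dim = c(nl, nr, nz, nx))
  for (l in seq_len(nl)) {
    for (r in seq_len(nr)) {
      fr <- t(matrix(fv$data[l, r, , ], nx, nk))   # [k, ascan]
      ref <- rowMeans(fr)
      mag <- recon_magnitudes(fr - ref, params)
      out[l, r, , ] <- db_to_gray(20 * log10(mag + params$epsilon), params)
    }
  }
  oct_volume(out, meta, is_averaged = FALSE, intensity_domain = "log_grayscale")
}

#' Synthesize spectral fringes from a linear-intensity structural volume
#'
#' Each A-line's fringe is a DC term plus
#' `sum_z sqrt(I(z)) * cos(2*pi*z*k/n_k + phi_z)` with per-voxel phases
#' `phi_z` drawn once per volume (seeded, uniform on \[0, 2*pi)), so that
#' reconstruction recovers the depth profile up to windowing blur.
#'
#' @param structural Linear-intensity BM-form [oct_volume()].
#' @param spec The [phantom_spec()] that produced it (provides `n_k` via
#'   its meta and the RNG seed for the phases).
#' @param dc_level Constant DC offset added to every fringe.
#' @return A [fringe_volume()] of shape
#'   `[n_locations, n_repeats, n_ascans, n_k]`.
#' @export
synthesize_fringes <- function(structural, spec, dc_level = 10) {
  stopifnot(inherits(structural, "OCTVolume"))
  if (structural$intensity_domain != "linear") {
    stop_fmt("structural volume must be in the linear intensity domain")
  }
  meta <- structural$meta
  if (meta$n_k != 2 * meta$n_depth) {
    stop_fmt("meta n_k (%d) must equal 2 * n_depth (%d)", meta$n_k, meta$n_depth)
  }
  nl <- meta$n_locations; nr <- meta$n_repeats
  nz <- meta$n_depth; nx <- meta$n_ascans; nk <- meta$n_k
  out <- array(0, dim = c(nl, nr, nx, nk))
  with_seed(spec$seed + 1L, {
    for (l in seq_len(nl)) {
      phi <- matrix(runif(nz * nx, 0, 2 * pi), nz, nx)  # per-voxel, shared by repeats
      for (r in seq_len(nr)) {
        A <- sqrt(pmax(matrix(structural$data[l, r, , ], nz, nx), 0))
        C <- A * exp(1i * phi)
        Cp <- rbind(C, matrix(0, nk - nz, nx))
        # Re{ sum_z c_z e^{+2pi i z k / n_k} } for k = 0..n_k-1
        fr <- Re(stats::mvfft(Cp, inverse = TRUE))
        out[l, r, , ] <- t(fr) + dc_level
      }
    }
  })
  fringe_volume(out, meta)
}
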