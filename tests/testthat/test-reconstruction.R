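test_that("a 2048-sample fringe reconstructs to a 1024-pixel depth profile", {
  f <- cos(2 * pi * 50 * (0:2047) / 2048)
  p <- reconstruct_ascan(f)
  expect_length(p, 1024)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("single-tone fringes peak at the matching depth bin (direct DFT oracle)", {
  n <- 2048
  set.seed(101)
  for (z in c(50, sample(5:900, 5))) {
    f <- cos(2 * pi * z * (0:(n - 1)) / n + runif(1, 0, 2 * pi))
    p <- reconstruct_ascan(f, output = "db")
    expect_equal(which.max(p) - 1L, z)
    # oracle: direct DFT of the same windowed fringe localizes identically
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    X <- direct_dft_bins((f - mean(f)) * w, n / 2)
    expect_equal(which.max(Mod(X)) - 1L, z)
  }
})

test_that("a zero fringe maps to the grayscale floor", {
  p <- reconstruct_ascan(numeric(64))
  expect_true(all(p == 0))
})

test_that("odd length and non-finite fringes are rejected", {
  expect_error(reconstruct_ascan(numeric(63)), "even")
  expect_error(reconstruct_ascan(c(numeric(63), NA)), "non-finite")
})

test_that("amplitude scaling shifts the dB profile uniformly by 20*log10(alpha)", {
  set.seed(7)
  f <- rnorm(256)
  params <- recon_params(epsilon = 1e-15)
  p1 <- reconstruct_ascan(f, params, output = "db")
  p2 <- reconstruct_ascan(3.5 * f, params, output = "db")
  expect_equal(p2 - p1, rep(20 * log10(3.5), 128), tolerance = 1e-6)
})

test_that("profile energy matches a brute-force DFT oracle to 1e-6 relative", {
  set.seed(13)
  n <- 128
  worst <- 0
  for (i in 1:100) {
    f <- rnorm(n)
    p <- reconstruct_ascan(f, output = "linear")
    # independent oracle: direct-DFT analytic signal, windowed, direct DFT
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    a <- direct_analytic(f - mean(f))
    X <- direct_dft_bins(a * w, n / 2)
    e_oracle <- sum(Mod(X)^2) / sum(w)^2
    worst <- max(worst, abs(sum(p) - e_oracle) / e_oracle)
  }
  expect_lt(worst, 1e-6)
})

test_that("matched dispersion compensation restores the undispersed peak width", {
  n <- 1024
  z <- 200
  fwhm_px <- function(p) {
    half <- max(p) / 2
    sum(p >= half)
  }
  f0 <- cos(2 * pi * z * (0:(n - 1)) / n)
  p0 <- reconstruct_ascan(f0, recon_params(), output = "linear")
  # synthesize a dispersed fringe: phase c2*kappa^2 applied to the analytic signal
  c2 <- 40
  kap <- 2 * (0:(n - 1)) / (n - 1) - 1
  X <- stats::fft(f0)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  a <- stats::fft(X * h, inverse = TRUE) / n
  fd <- Re(a * exp(1i * c2 * kap^2))
  p_bad <- reconstruct_ascan(fd, recon_params(), output = "linear")
  p_fix <- reconstruct_ascan(fd, recon_params(dispersion_c2 = c2),
                             output = "linear")
  expect_gt(fwhm_px(p_bad), fwhm_px(p0))          # dispersion blurs
  expect_lte(fwhm_px(p_fix), fwhm_px(p0) + 1)     # compensation restores
})

test_that("volume reconstruction has the documented shape and zeroes common-mode frames", {
  meta <- small_meta(n_locations = 2, n_repeats = 3, n_ascans = 8, n_depth = 64)
  sp <- phantom_spec(meta = meta, ilm_center_depth_px = 15,
                     curvature_sag_px = 2, n_vessels = 0,
                     layers = data.frame(name = c("NFL", "choroid"),
                                         thickness_um = c(30, 45),
                                         reflectivity = c(0.9, 0.3)),
                     seed = 4)
  g <- generate_structural(sp)
  fv <- synthesize_fringes(g$volume, sp)
  expect_equal(dim(fv$data), c(2, 3, 8, 128))
  rec <- reconstruct_volume(fv)
  expect_equal(dim(rec$data), c(2, 3, 64, 8))
  expect_identical(rec$intensity_domain, "log_grayscale")
  # identical A-lines: the per-frame reference spectrum removes everything
  flat <- fringe_volume(array(rep(cos(2 * pi * 7 * (0:127) / 128), each = 2 * 3 * 8),
                              c(2, 3, 8, 128)), meta)
  rec0 <- reconstruct_volume(flat)
  expect_true(all(rec0$data == 0))
  # pre-reconstructed input is refused with guidance
  meta0 <- acquisition_meta(n_locations = 2, n_repeats = 3, n_ascans = 8,
                            n_k = 0, n_depth = 64)
  expect_error(reconstruct_volume(fringe_volume(array(0, c(2, 3, 8, 128)),
                                                meta)),
               NA)   # valid fringes fine
  expect_error({
    fv0 <- fv; fv0$meta <- meta0
    reconstruct_volume(fv0)
  }, "already reconstructed")
})

test_that("fringe synthesis followed by reconstruction recovers the structure", {
  # single-voxel contract: one bright voxel -> cosine at that depth frequency
  meta1 <- acquisition_meta(n_locations = 1, n_repeats = 1, n_ascans = 1,
                            n_k = 256, n_depth = 128)
  one <- array(0, c(1, 1, 128, 1)); one[1, 1, 51, 1] <- 1   # depth index 50
  sv <- oct_volume(one, meta1, intensity_domain = "linear")
  f1 <- synthesize_fringes(sv, phantom_spec(meta = meta1,
                                            ilm_center_depth_px = 30,
                                            curvature_sag_px = 0,
                                            n_vessels = 0,
                                            layers = data.frame(
                                              name = c("NFL", "choroid"),
                                              thickness_um = c(60, 90),
                                              reflectivity = c(0.9, 0.3)),
                                            seed = 1))
  spec_f <- Mod(stats::fft(f1$data[1, 1, 1, ] - mean(f1$data[1, 1, 1, ])))
  expect_equal(which.max(spec_f[1:128]) - 1L, 50L)
  # all-zero structure -> DC-only fringe
  zero <- oct_volume(array(0, c(1, 1, 128, 1)), meta1,
                     intensity_domain = "linear")
  fz <- synthesize_fringes(zero, phantom_spec(meta = meta1,
                                              ilm_center_depth_px = 30,
                                              curvature_sag_px = 0,
                                              n_vessels = 0,
                                              layers = data.frame(
                                                name = c("NFL", "choroid"),
                                                thickness_um = c(60, 90),
                                                reflectivity = c(0.9, 0.3)),
                                              seed = 1), dc_level = 7)
  expect_equal(unique(as.vector(fz$data)), 7)

  # full noiseless phantom: reconstruct and compare against the input
  sp <- small_spec(seed = 21, n_locations = 3, n_ascans = 64,
                   ilm_center_depth_px = 55, curvature_sag_px = 40,
                   n_vessels = 0, speckle_contrast = 0)
  g <- generate_structural(sp)
  fv <- synthesize_fringes(g$volume, sp)
  rec <- reconstruct_volume(fv, recon_params(floor_db = -30, ceil_db = 0))
  # The synthesized A-line is a coherent sum (random per-voxel phases), so
  # the reconstruction carries interference speckle; agreement is assessed
  # at the axial resolution of the windowed reconstruction (~5 px) by
  # comparing locally averaged intensities in the log domain.
  sm5 <- function(m) stats::filter(m, rep(1 / 5, 5), circular = TRUE)
  l <- 2
  recon_bscan <- matrix(rec$data[l, 1, , ], sp$meta$n_depth, sp$meta$n_ascans)
  truth_bscan <- matrix(g$volume$data[l, 1, , ], sp$meta$n_depth,
                        sp$meta$n_ascans)
  recon_lin <- 10^((recon_bscan * 30 - 30) / 10)     # invert the (-30, 0) dB map
  r <- cor(as.vector(log10(sm5(recon_lin) + 1e-12)),
           as.vector(log10(sm5(truth_bscan) + 1e-12)))
  expect_gt(r, 0.9)
  # first bright band (70% of column max) localizes the ILM within +/- 2 px
  errs <- c()
  for (ll in 1:3) {
    b <- matrix(rec$data[ll, 1, , ], sp$meta$n_depth, sp$meta$n_ascans)
    fb <- apply(b, 2, function(v) which(v >= 0.7 * max(v))[1] - 1)
    errs <- c(errs, fb - g$truth$ilm_surface$z[ll, ])
  }
  expect_gte(mean(abs(errs) <= 2), 0.95)
})
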