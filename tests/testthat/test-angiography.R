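test_that("speckle variance follows the population-variance formula", {
  st <- array(0, c(3, 2, 2))
  st[, 1, 1] <- c(0, 0.5, 1)
  sv <- speckle_variance(st)
  expect_equal(sv[1, 1], (0.5^2 * 2) / 3)       # mean 0.5 -> 1/6
  expect_equal(sv[2, 2], 0)
  # identical frames give exactly zero everywhere
  base <- matrix(runif(12), 3, 4)
  same <- array(rep(base, each = 3), c(3, 3, 4))
  expect_true(all(speckle_variance(same) == 0))
  expect_error(speckle_variance(array(1, c(1, 4, 4))), "N < 2")
})

test_that("speckle variance is shift-invariant and scales quadratically", {
  set.seed(61)
  st <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  sv <- speckle_variance(st)
  expect_equal(speckle_variance(st + 5), sv, tolerance = 1e-12)
  expect_equal(speckle_variance(2.5 * st), 2.5^2 * sv, tolerance = 1e-12)
})

test_that("speckle variance separates vessels from static tissue (AUC)", {
  aucs <- sapply(c(0.5, 0.7, 0.9), function(rho) {
    sp <- small_spec(seed = 11, n_locations = 10, n_ascans = 64,
                     n_vessels = 6, static_frame_correlation = rho)
    g <- generate_structural(sp)
    an <- build_angio_volume(as_grayscale(g$volume), register = FALSE)
    band <- array(FALSE, dim = dim(an$data))
    for (l in seq_len(dim(an$data)[1])) {
      for (x in seq_len(dim(an$data)[3])) {
        z0 <- floor(g$truth$ilm_surface$z[l, x])
        z1 <- ceiling(g$truth$rpe_surface$z[l, x]) + 50
        band[l, (z0 + 1):(z1 + 1), x] <- TRUE
      }
    }
    vm <- g$truth$vessel_mask
    rank_auc(an$data[vm & band], an$data[!vm & band])
  })
  expect_gte(aucs[3], 0.90)
  # discrimination improves with frame correlation (tolerance 0.02)
  expect_gte(aucs[2], aucs[1] - 0.02)
  expect_gte(aucs[3], aucs[2] - 0.02)
})

test_that("angio volumes are deterministic and sized one frame per location", {
  sp <- small_spec(seed = 13, n_locations = 4, n_vessels = 2)
  g <- generate_structural(sp)
  gv <- as_grayscale(g$volume)
  a1 <- build_angio_volume(gv)
  a2 <- build_angio_volume(gv)
  expect_identical(a1$data, a2$data)
  expect_equal(dim(a1$data), c(4, 256, 32))
})

test_that("en face projection respects modes, the half-open interval and ordering", {
  nl <- 4; nz <- 30; nx <- 5
  arr <- array(0, c(nl, nz, nx))
  arr[, 11:20, ] <- 0.4                       # constant slab, thickness 10
  arr[, 13, ] <- 0.9                          # one bright plane inside
  ilm <- surface_map(matrix(10, nl, nx), "ILM_NFL")
  rpe <- surface_map(matrix(20, nl, nx), "RPE_BrM")
  full <- slab_spec("band", "ILM", 0, "RPE", 0)
  mx <- enface_project(arr, ilm, rpe, full, "max")
  mn <- enface_project(arr, ilm, rpe, full, "mean")
  sm <- enface_project(arr, ilm, rpe, full, "sum")
  expect_true(all(mx$data == 0.9))
  expect_equal(unique(as.vector(sm$data)), 0.4 * 9 + 0.9)
  expect_true(all(mx$data >= mn$data))        # order statistic
  # single-row slab returns exactly that row (half-open [top, bottom))
  row12 <- enface_project(arr, ilm, rpe, slab_spec("one", "ILM", 2, "ILM", 3),
                          "max")
  expect_true(all(row12$data == 0.9))
  row11 <- enface_project(arr, ilm, rpe, slab_spec("one", "ILM", 1, "ILM", 2),
                          "max")
  expect_true(all(row11$data == 0.4))
  expect_error(suppressWarnings(
    enface_project(arr, ilm, rpe, slab_spec("void", "RPE", 25, "RPE", 40),
                   "max")), "empty")
})

test_that("the sum fundus equals the full-depth sum projection before normalization", {
  sp <- small_spec(seed = 19, n_locations = 4, n_vessels = 0)
  g <- generate_structural(sp)
  av <- average_volume(as_grayscale(g$volume))
  f <- oct_fundus(av$volume)
  expect_equal(dim(f$data), c(4, 32))
  nl <- 4; nz <- 256
  ilm0 <- surface_map(matrix(0, 4, 32), "ILM_NFL")
  bot <- surface_map(matrix(nz - 1, 4, 32), "RPE_BrM")
  raw <- enface_project(av$volume, ilm0, bot,
                        slab_spec("all", "ILM", 0, "RPE", 1), "sum")
  rng <- range(raw$data)
  expect_equal(f$data, (raw$data - rng[1]) / (rng[2] - rng[1]))
  # degenerate range maps to zeros
  const <- oct_volume(array(1, c(2, 8, 3)),
                      acquisition_meta(n_locations = 2, n_repeats = 1,
                                       n_ascans = 3, n_k = 0, n_depth = 8),
                      is_averaged = TRUE, intensity_domain = "log_grayscale")
  expect_true(all(oct_fundus(const)$data == 0))
})

test_that("avascular-retina phantoms show far weaker retinal than choroidal flow", {
  sp <- small_spec(seed = 3, species = "owl", n_locations = 20, n_ascans = 64)
  g <- generate_structural(sp)
  an <- build_angio_volume(as_grayscale(g$volume), register = FALSE)
  ilm <- g$truth$ilm_surface$z; rpe <- g$truth$rpe_surface$z
  r99 <- stats::quantile(slab_voxels(an$data, ilm, rpe, 0, 0), 0.99,
                         names = FALSE)
  c99 <- stats::quantile(slab_voxels(an$data, rpe, rpe, 0, 60), 0.99,
                         names = FALSE)
  expect_lt(r99 / c99, 0.10)
})

test_that("vessel-free phantoms show <10% of the vessel-slab flow tail", {
  sp0 <- small_spec(seed = 4, n_locations = 16, n_ascans = 64, n_vessels = 0)
  spv <- small_spec(seed = 4, n_locations = 16, n_ascans = 64, n_vessels = 8,
                    vessel_slab = "NFL")
  g0 <- generate_structural(sp0)
  gv <- generate_structural(spv)
  a0 <- build_angio_volume(as_grayscale(g0$volume), register = FALSE)
  av <- build_angio_volume(as_grayscale(gv$volume), register = FALSE)
  # compare within the NFL (the hosting slab): a volume-wide percentile
  # cannot see vessels that occupy <1% of all voxels
  s99 <- stats::quantile(slab_voxels(a0$data, g0$truth$ilm_surface$z,
                                     g0$truth$ilm_surface$z, -4, 9), 0.99,
                         names = FALSE)
  v99 <- stats::quantile(slab_voxels(av$data, gv$truth$ilm_surface$z,
                                     gv$truth$ilm_surface$z, -4, 9), 0.99,
                         names = FALSE)
  expect_lt(s99 / v99, 0.10)
})

test_that("en face vessel skeletons overlap the truth centerlines", {
  sp <- small_spec(seed = 33, n_locations = 24, n_ascans = 64, n_vessels = 4,
                   vessel_slab = "NFL")
  g <- generate_structural(sp)
  an <- build_angio_volume(as_grayscale(g$volume), register = FALSE)
  ef <- enface_project(an, g$truth$ilm_surface, g$truth$rpe_surface,
                       slab_preset("superficial"), "max")
  # truth centerline: columns whose NFL contains vessel voxels
  center <- apply(g$truth$vessel_mask, c(1, 3), any)
  thr <- stats::quantile(ef$data, 0.75, names = FALSE)
  expect_gte(mean(ef$data[center] > thr), 0.8)
})

test_that("contrast enhancement flattens smooth backgrounds and clips to [0,1]", {
  set.seed(71)
  clean <- matrix(0, 48, 48)
  clean[, seq(8, 40, by = 8)] <- 1                      # vessel-like stripes
  grad <- outer(seq(0, 0.8, length.out = 48), rep(1, 48))
  img <- clean * 0.5 + grad
  enh <- enhance_contrast(img, background_sigma_px = 10,
                          stretch_percentiles = c(5, 99))
  expect_gte(cor(as.vector(enh), as.vector(clean)),
             cor(as.vector(img), as.vector(clean)))
  expect_true(min(enh) >= 0 && max(enh) <= 1)
  expect_true(all(enhance_contrast(matrix(0.7, 30, 30)) == 0))
  expect_error(enhance_contrast(img, stretch_percentiles = c(90, 10)), "p_lo")
})
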