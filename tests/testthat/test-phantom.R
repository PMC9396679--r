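test_that("phantom generation is deterministic under a fixed seed", {
  sp <- small_spec(seed = 7, n_locations = 4, n_vessels = 2)
  g1 <- generate_structural(sp)
  g2 <- generate_structural(sp)
  expect_identical(g1$volume$data, g2$volume$data)
  expect_identical(g1$truth$vessel_mask, g2$truth$vessel_mask)
  expect_identical(g1$truth$jitter_px, g2$truth$jitter_px)
})

test_that("flat spec yields constant truth surfaces and zero jitter", {
  sp <- small_spec(seed = 2, n_locations = 4, curvature_sag_px = 0,
                   jitter_walk_sigma_px = 0, n_vessels = 0)
  g <- generate_structural(sp)
  expect_equal(diff(range(g$truth$ilm_surface$z)), 0)
  expect_equal(diff(range(g$truth$rpe_surface$z)), 0)
  expect_true(all(g$truth$jitter_px == 0L))
  # thickness invariant: (rpe - ilm) * axial pitch
  expect_equal(g$truth$thickness_um,
               (g$truth$rpe_surface$z - g$truth$ilm_surface$z) *
                 sp$meta$axial_um_per_px)
})

test_that("perfect frame correlation without vessels gives identical repeats", {
  sp <- small_spec(seed = 3, n_locations = 3, static_frame_correlation = 1,
                   n_vessels = 0)
  g <- generate_structural(sp)
  for (l in 1:3) {
    expect_equal(g$volume$data[l, 1, , ], g$volume$data[l, 2, , ])
    expect_equal(g$volume$data[l, 1, , ], g$volume$data[l, 3, , ])
  }
})

test_that("vessel voxels decorrelate across repeats while static voxels stay correlated", {
  # vessels confined to the (constant-reflectivity) NFL so the frame-pair
  # correlation measures temporal decorrelation, not layer structure
  sp <- small_spec(seed = 5, n_locations = 8, n_ascans = 64, n_vessels = 6,
                   vessel_slab = "NFL", static_frame_correlation = 0.9)
  g <- generate_structural(sp)
  vm <- g$truth$vessel_mask
  d <- dim(g$volume$data)
  stat_cor <- c(); ves_cor <- c()
  for (l in seq_len(d[1])) {
    f1 <- matrix(g$volume$data[l, 1, , ], d[3], d[4])
    f2 <- matrix(g$volume$data[l, 2, , ], d[3], d[4])
    m <- vm[l, , ]
    # static comparison within the same NFL band
    nfl <- outer(0:(d[3] - 1), g$truth$ilm_surface$z[l, ],
                 function(z, s) z >= s & z < s + 5)
    if (sum(m) > 50) ves_cor <- c(ves_cor, cor(f1[m], f2[m]))
    stat_cor <- c(stat_cor, cor(f1[nfl & !m], f2[nfl & !m]))
  }
  expect_gt(mean(stat_cor), 0.8)
  expect_lt(mean(ves_cor), 0.2)
})

test_that("layer mean intensities preserve the configured reflectivity ordering", {
  sp <- small_spec(seed = 11, n_locations = 12, n_ascans = 64,
                   curvature_sag_px = 0, n_vessels = 0)
  g <- generate_structural(sp)
  ly <- sp$layers
  cum_px <- c(0, cumsum(ly$thickness_um / sp$meta$axial_um_per_px))
  ilm <- sp$ilm_center_depth_px
  means <- sapply(seq_len(nrow(ly) - 1), function(i) {   # skip attenuated choroid
    rows <- (ilm + ceiling(cum_px[i] + 1)):(ilm + floor(cum_px[i + 1] - 1))
    mean(g$volume$data[, , rows + 1, ])
  })
  expect_equal(order(means), order(ly$reflectivity[seq_len(nrow(ly) - 1)]))
})

test_that("species presets scale retinal thickness to the measured means", {
  configured <- c(mouse = 210, rat = 186, owl = 260, opossum = 138.5,
                  sturgeon = 142)
  for (s in names(configured)) {
    sp <- small_spec(seed = 1, species = s, n_locations = 2)
    g <- generate_structural(sp)
    expect_equal(unname(g$truth$thickness_um[1, 1]), unname(configured[[s]]),
                 tolerance = 1e-12)
  }
  # avascular avian retina: owl hosts vessels only in the choroid
  owl <- small_spec(seed = 1, species = "owl", n_locations = 2)
  expect_identical(owl$vessel_slab, "choroid")
  expect_error(species_preset("axolotl"), "unknown species")
})

test_that("jitter is an integer per-location random walk applied to all repeats", {
  sp <- small_spec(seed = 9, n_locations = 16, jitter_walk_sigma_px = 2,
                   n_vessels = 0, curvature_sag_px = 0)
  g <- generate_structural(sp)
  j <- g$truth$jitter_px
  expect_type(j, "integer")
  expect_gt(stats::sd(j), 0)
  # all repeats of a location share the jitter: brightest-row profile match
  l <- which.max(abs(j))
  f1 <- matrix(g$volume$data[l, 1, , ], 256, 32)
  f2 <- matrix(g$volume$data[l, 3, , ], 256, 32)
  expect_equal(which.max(rowMeans(f1 > 0.1)), which.max(rowMeans(f2 > 0.1)))
})

test_that("vessel slab names are validated", {
  expect_error(small_spec(n_vessels = 2, vessel_slab = "sclera"),
               "not in layers")
})
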