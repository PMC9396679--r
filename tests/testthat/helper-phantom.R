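# Shared fixtures: all phantoms are generated in code at test time.

small_meta <- function(n_locations = 8, n_repeats = 3, n_ascans = 32,
                       n_depth = 256, axial_um_per_px = 3) {
  acquisition_meta(n_locations = n_locations, n_repeats = n_repeats,
                   n_ascans = n_ascans, n_k = 2 * n_depth, n_depth = n_depth,
                   axial_um_per_px = axial_um_per_px)
}

small_spec <- function(seed = 1, species = NULL, ...) {
  extra <- list(...)
  meta_args <- extra[names(extra) %in% names(formals(small_meta))]
  extra <- extra[!names(extra) %in% names(formals(small_meta))]
  args <- list(meta = do.call(small_meta, meta_args), ilm_center_depth_px = 60,
               curvature_sag_px = 5, seed = seed)
  args[names(extra)] <- extra
  if (is.null(species)) do.call(phantom_spec, args)
  else do.call(species_preset, c(list(species), args))
}

# Run the structural chain (grayscale -> BM average -> axial align ->
# flatten -> graph-cut) on a phantom; returns everything for inspection.
run_structural_chain <- function(spec, band = c(50, 220), max_lag = 20) {
  g <- generate_structural(spec)
  gv <- as_grayscale(g$volume)
  av <- average_volume(gv)
  al <- axial_align_volume(av$volume, max_lag = max_lag)
  fl <- flatten_volume(al$volume)
  seg <- segment_surfaces_graphcut(fl$volume,
                                   graphcut_params(search_band = band))
  th <- compute_thickness(seg$ilm, seg$rpe, spec$meta$axial_um_per_px)
  list(gen = g, averaged = av, aligned = al, flat = fl, seg = seg, th = th)
}

# Independent per-B-scan dynamic-programming oracle for the optimal
# surface with hard |dz| <= delta between adjacent columns (Viterbi).
dp_surface_oracle <- function(cost2d, delta) {
  nz <- nrow(cost2d); nx <- ncol(cost2d)
  dp <- matrix(Inf, nz, nx)
  dp[, 1] <- cost2d[, 1]
  for (x in 2:nx) {
    for (z in 1:nz) {
      lo <- max(1, z - delta); hi <- min(nz, z + delta)
      dp[z, x] <- cost2d[z, x] + min(dp[lo:hi, x - 1])
    }
  }
  path <- integer(nx)
  path[nx] <- which.min(dp[, nx])
  for (x in (nx - 1):1) {
    lo <- max(1, path[x + 1] - delta); hi <- min(nz, path[x + 1] + delta)
    cand <- lo:hi
    path[x] <- cand[which.min(dp[cand, x])]
  }
  path - 1L
}

# Rank-based (Mann-Whitney) AUC of scores for positives vs negatives.
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Brute-force direct DFT (matrix form) of the first `nbins` bins.
direct_dft_bins <- function(x, nbins) {
  n <- length(x)
  k <- 0:(nbins - 1)
  E <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  as.vector(E %*% x)
}

# Independent analytic-signal oracle by direct DFT synthesis.
direct_analytic <- function(x) {
  n <- length(x)
  X <- direct_dft_bins(x, n)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  Xh <- X * h
  E <- exp(2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(E %*% Xh) / n
}

# Voxels of the angio volume inside a per-column depth band
# [s1 + top_off, s2 + bot_off] (0-based, inclusive).
slab_voxels <- function(arr3d, s1, s2, top_off, bot_off) {
  d <- dim(arr3d)
  out <- vector("list", d[1] * d[3])
  i <- 0
  for (l in seq_len(d[1])) {
    for (x in seq_len(d[3])) {
      t0 <- max(0, floor(s1[l, x] + top_off))
      b0 <- min(d[2] - 1, ceiling(s2[l, x] + bot_off))
      i <- i + 1
      out[[i]] <- arr3d[l, (t0 + 1):(b0 + 1), x]
    }
  }
  unlist(out)
}
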