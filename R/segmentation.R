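#' Graph-cut segmentation parameters
#'
#' The two retinal boundaries are found as exact minimizers of a
#' column-wise cost subject to hard smoothness constraints, via a minimum
#' s-t cut on the standard optimal-surface graph.
#'
#' @param smooth_dx_px Maximum surface-height change between laterally
#'   adjacent columns (along A-scans).
#' @param smooth_dy_px Maximum change between azimuthally adjacent columns
#'   (along B-scan locations); set `>= n_depth` to decouple B-scans.
#' @param min_separation_px Minimum ILM-to-RPE distance.
#' @param cost_sigma_px Gaussian scale of the axial smoothing applied
#'   before the gradient costs; 0 disables smoothing.
#' @param search_band Optional `c(zmin, zmax)` (0-based, inclusive) depth
#'   restriction applied to both surfaces.
#' @param refine `"none"` (default; integer surfaces, exact minimizers)
#'   or `"parabolic"` (fractional refinement by a parabola through the
#'   cost at the cut position and its axial neighbours).
#' @return An object of class `GraphCutParams`.
#' @export
graphcut_params <- function(smooth_dx_px = 2, smooth_dy_px = 2,
                            min_separation_px = 20, cost_sigma_px = 2,
                            search_band = NULL,
                            refine = c("none", "parabolic")) {
  refine <- match.arg(refine)
  if (smooth_dx_px < 0 || smooth_dy_px < 0) stop_fmt("smoothness must be >= 0")
  if (min_separation_px < 1) stop_fmt("min_separation_px must be >= 1")
  if (cost_sigma_px < 0) stop_fmt("cost_sigma_px must be >= 0")
  structure(list(smooth_dx_px = as.integer(smooth_dx_px),
                 smooth_dy_px = as.integer(smooth_dy_px),
                 min_separation_px = as.integer(min_separation_px),
                 cost_sigma_px = cost_sigma_px, search_band = search_band,
                 refine = refine),
            class = "GraphCutParams")
}

# Gaussian smoothing along the first (depth) axis of a [depth x columns]
# matrix, reflective boundaries.
smooth_axial <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(m)
  pad <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
  out <- stats::filter(pad, k, sides = 2)
  matrix(out[(r + 1):(r + n), ], n, ncol(m))
}

#' Exact minimum-cut optimal surface on a column grid
#'
#' Finds the surface `z(c)` (one depth per column) minimizing the total
#' cost subject to hard smoothness bounds between 4-adjacent columns, as
#' the minimum closed set of the standard optimal-surface graph solved
#' with a maximum-flow / minimum s-t cut. The result is the exact global
#' minimizer.
#'
#' @param cost 3-D array `[location, depth, ascan]` of column costs.
#' @param smooth_dx,smooth_dy Hard bounds on `|dz|` between adjacent
#'   columns along the ascan / location axes; values `>= n_depth` drop the
#'   corresponding constraint.
#' @return Integer matrix `[location, ascan]` of 0-based depth indices.
#' @export
solve_optimal_surface <- function(cost, smooth_dx = 2, smooth_dy = 2) {
  d <- dim(cost)
  if (length(d) != 3) stop_fmt("cost must be [location, depth, ascan]")
  nl <- d[1]; nz <- d[2]; nx <- d[3]
  ncols <- nl * nx
  # cost matrix [depth, column], column id = (ascan-1)*nl + location
  cm <- matrix(aperm(cost, c(2, 1, 3)), nz, ncols)
  big <- (sum(abs(cm)) + 1)
  w <- rbind(cm[1, , drop = FALSE] - big, diff(cm))
  wv <- as.vector(w)                       # node weights, z fastest
  INF <- sum(abs(wv)) + 1

  node <- function(z, col) (col - 1L) * nz + z        # z in 1..nz
  intra_from <- as.vector(outer(2:nz, (0:(ncols - 1)) * nz, "+"))
  intra_to <- intra_from - 1L

  col_grid <- matrix(seq_len(ncols), nl, nx)
  sm_from <- integer(0); sm_to <- integer(0)
  add_pairs <- function(p1, p2, delta) {
    if (delta >= nz) return(NULL)
    pairs <- rbind(cbind(p1, p2), cbind(p2, p1))
    zs <- (delta + 1):nz
    list(from = as.vector(outer(zs, (pairs[, 1] - 1L) * nz, "+")),
         to = as.vector(outer(zs - delta, (pairs[, 2] - 1L) * nz, "+")))
  }
  if (nl > 1) {
    a <- add_pairs(as.vector(col_grid[-nl, ]), as.vector(col_grid[-1, ]),
                   as.integer(smooth_dy))
    if (!is.null(a)) { sm_from <- c(sm_from, a$from); sm_to <- c(sm_to, a$to) }
  }
  if (nx > 1) {
    a <- add_pairs(as.vector(col_grid[, -nx]), as.vector(col_grid[, -1]),
                   as.integer(smooth_dx))
    if (!is.null(a)) { sm_from <- c(sm_from, a$from); sm_to <- c(sm_to, a$to) }
  }

  N <- ncols * nz
  S <- N + 1L; Tn <- N + 2L
  pos <- which(wv >= 0); neg <- which(wv < 0)
  ef <- c(intra_from, sm_from, rep.int(S, length(neg)), pos)
  et <- c(intra_to, sm_to, neg, rep.int(Tn, length(pos)))
  cap <- c(rep.int(INF, length(intra_from) + length(sm_from)), -wv[neg], wv[pos])
  g <- igraph::make_graph(rbind(ef, et), n = N + 2L, directed = TRUE)
  fl <- igraph::max_flow(g, S, Tn, capacity = cap)
  src <- as.integer(fl$partition1)
  src <- src[src <= N]
  # surface = highest z in the closed (source) set of each column
  colid <- (src - 1L) %/% nz + 1L
  zid <- (src - 1L) %% nz + 1L
  zbest <- rep.int(0L, ncols)
  o <- order(colid, zid)
  zmax <- tapply(zid[o], colid[o], max)
  zbest[as.integer(names(zmax))] <- as.integer(zmax)
  if (any(zbest == 0L)) stop_fmt("infeasible cut: empty column closed set")
  matrix(zbest - 1L, nl, nx)       # back to [location, ascan], 0-based
}

parabolic_refine <- function(zint, cm3) {
  # cm3: [location, depth, ascan]; refine each z by the vertex of the
  # parabola through cost at z-1, z, z+1 (clamped to +/- 0.5 px)
  d <- dim(cm3)
  out <- matrix(0, d[1], d[3])
  for (l in seq_len(d[1])) {
    for (x in seq_len(d[3])) {
      z <- zint[l, x]
      if (z >= 1 && z <= d[2] - 2) {
        c0 <- cm3[l, z, x]; c1 <- cm3[l, z + 1, x]; c2 <- cm3[l, z + 2, x]
        denom <- c0 - 2 * c1 + c2
        frac <- if (denom > 0) 0.5 * (c0 - c2) / denom else 0
        out[l, x] <- z + max(-0.5, min(0.5, frac))
      } else {
        out[l, x] <- z
      }
    }
  }
  out
}

#' Segment the ILM/NFL and RPE/BrM surfaces by graph cut
#'
#' After Gaussian axial smoothing at `cost_sigma_px`, the ILM/NFL surface
#' minimizes the negative dark-to-bright axial gradient (backward
#' difference, so the surface sits on the first bright row) and the
#' RPE/BrM surface minimizes the negative bright-to-dark gradient (forward
#' difference, surface on the last bright row) restricted to depths at
#' least `min_separation_px` below the found ILM (sequential two-pass).
#' Each pass is an exact minimum s-t cut (see [solve_optimal_surface()]).
#'
#' @param vol Flattened averaged [oct_volume()].
#' @param params A [graphcut_params()].
#' @return List with `ilm` and `rpe` ([surface_map()]s satisfying
#'   `ilm$z + min_separation_px <= rpe$z` everywhere).
#' @export
segment_surfaces_graphcut <- function(vol, params = graphcut_params()) {
  stopifnot(inherits(vol, "OCTVolume"), vol$is_averaged)
  meta <- vol$meta
  nl <- meta$n_locations; nz <- meta$n_depth; nx <- meta$n_ascans
  band <- params$search_band
  z0 <- 0L; z1 <- nz - 1L
  if (!is.null(band)) {
    z0 <- max(0L, as.integer(band[1])); z1 <- min(nz - 1L, as.integer(band[2]))
    if (z1 - z0 + 1 < params$min_separation_px + 1) {
      stop_fmt("search band excludes all feasible depths")
    }
  }
  nb <- z1 - z0 + 1L
  # [depth, loc*ascan] view of the banded volume
  sub <- vol$data[, (z0 + 1):(z1 + 1), , drop = FALSE]
  cm <- matrix(aperm(sub, c(2, 1, 3)), nb, nl * nx)
  cm <- smooth_axial(cm, params$cost_sigma_px)
  grad_bwd <- rbind(0, diff(cm))                    # I[z] - I[z-1]
  grad_fwd <- rbind(diff(cm), 0)                    # I[z+1] - I[z]
  to3 <- function(m) aperm(array(m, dim = c(nb, nl, nx)), c(2, 1, 3))
  cost_ilm <- to3(-grad_bwd)
  zi <- solve_optimal_surface(cost_ilm, params$smooth_dx_px, params$smooth_dy_px)

  cost_rpe <- to3(grad_fwd)
  forbid_big <- (nl * nx + 1) * (max(abs(cost_rpe)) + 1)
  lower <- zi + params$min_separation_px            # 0-based within band
  for (l in seq_len(nl)) {
    for (x in seq_len(nx)) {
      lb <- min(lower[l, x], nb - 1L)
      if (lb > 0) cost_rpe[l, 1:lb, x] <- forbid_big
    }
  }
  zr <- solve_optimal_surface(cost_rpe, params$smooth_dx_px, params$smooth_dy_px)
  zr <- pmax(zr, zi + params$min_separation_px)

  if (params$refine == "parabolic") {
    zi_f <- parabolic_refine(zi, to3(-grad_bwd)) + z0
    zr_f <- parabolic_refine(zr, to3(grad_fwd)) + z0
  } else {
    zi_f <- zi + z0
    zr_f <- zr + z0
  }
  list(ilm = surface_map(zi_f, "ILM_NFL"),
       rpe = surface_map(zr_f, "RPE_BrM"))
}

#' Retinal thickness statistics from two surfaces
#'
#' Thickness is the axial separation of the RPE/BrM and ILM/NFL surfaces
#' converted to micrometres; mean and population standard deviation are
#' computed over unmasked columns.
#'
#' @param ilm,rpe [surface_map()]s of the same shape.
#' @param axial_um_per_px Axial pixel pitch in micrometres.
#' @param mask Optional logical matrix; `TRUE` columns are excluded.
#' @return An object of class `ThicknessResult`: `thickness_um` (matrix),
#'   `mean_um`, `sd_um`, `n_columns`, `mask`.
#' @export
compute_thickness <- function(ilm, rpe, axial_um_per_px, mask = NULL) {
  stopifnot(inherits(ilm, "SurfaceMap"), inherits(rpe, "SurfaceMap"))
  if (!all(dim(ilm$z) == dim(rpe$z))) stop_fmt("surfaces must have the same shape")
  if (!is_scalar_num(axial_um_per_px) || axial_um_per_px <= 0) {
    stop_fmt("axial_um_per_px must be > 0")
  }
  keep <- if (is.null(mask)) {
    matrix(TRUE, nrow(ilm$z), ncol(ilm$z))
  } else !mask
  dz <- rpe$z - ilm$z
  if (any(dz[keep] <= 0)) stop_fmt("surfaces cross on unmasked columns")
  th <- dz * axial_um_per_px
  v <- th[keep]
  structure(list(thickness_um = th,
                 mean_um = mean(v),
                 sd_um = sqrt(mean((v - mean(v))^2)),
                 n_columns = length(v),
                 mask = mask),
            class = "ThicknessResult")
}

#' @export
print.ThicknessResult <- function(x, ...) {
  cat(sprintf("Retinal thickness: %.1f +/- %.1f um (n = %d columns)\n",
              x$mean_um, x$sd_um, x$n_columns))
  invisible(x)
}
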