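#' Specification for a synthetic retinal phantom
#'
#' Defines a layered retinal phantom with fully developed speckle, flow
#' decorrelation inside vessels, parabolic curvature, and inter-B-scan axial
#' motion, together with the acquisition geometry it is "imaged" under.
#' Every stochastic element is driven by `seed`, so the same spec always
#' produces bit-identical volumes and ground truth.
#'
#' Layers are listed from the inner retina (NFL) to the choroid as
#' `(name, thickness_um, mean_reflectivity)`. The retinal thickness ground
#' truth is the ILM-to-RPE distance, i.e. the sum of all layer thicknesses
#' above the `"choroid"` layer.
#'
#' @param meta [acquisition_meta()]; geometry of the simulated acquisition.
#' @param layers data.frame with columns `name`, `thickness_um`,
#'   `reflectivity` (ordered NFL to choroid).
#' @param ilm_center_depth_px Depth (0-based px) of the ILM at the field
#'   centre.
#' @param curvature_sag_px Peak-to-edge parabolic sag applied to all
#'   surfaces.
#' @param speckle_contrast In \[0, 1\]: 0 = deterministic intensity, 1 =
#'   fully developed (exponential-intensity) speckle.
#' @param static_frame_correlation In \[0, 1\]: weight of the shared
#'   speckle realization across BM frames for static tissue.
#' @param n_vessels Number of vessels.
#' @param vessel_radius_px Vessel radius in pixels.
#' @param vessel_slab Character vector of layer names hosting vessels;
#'   vessels are assigned to these slabs cyclically.
#' @param jitter_walk_sigma_px Standard deviation of the per-B-scan axial
#'   random-walk step (integer jitter after rounding).
#' @param intra_frame_shift_px Half-range of an optional uniform subpixel
#'   axial shift applied independently to repeat frames 2..M (exercises
#'   subpixel registration); 0 disables it.
#' @param noise_floor Background reflectivity outside the layer stack.
#' @param choroid_decay_tau_px Exponential depth-attenuation constant of
#'   the choroid signal (models light extinction below the RPE, so the
#'   choroid fades into the floor rather than ending in a sharp edge).
#' @param seed RNG seed.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(meta = acquisition_meta(),
                         layers = default_layers(),
                         ilm_center_depth_px = round(meta$n_depth / 3),
                         curvature_sag_px = 30,
                         speckle_contrast = 0.6,
                         static_frame_correlation = 0.9,
                         n_vessels = 8,
                         vessel_radius_px = 3,
                         vessel_slab = c("NFL", "choroid"),
                         jitter_walk_sigma_px = 0,
                         intra_frame_shift_px = 0,
                         noise_floor = 0.005,
                         choroid_decay_tau_px = 10,
                         seed = 1) {
  spec <- structure(list(
    meta = meta, layers = layers, ilm_center_depth_px = ilm_center_depth_px,
    curvature_sag_px = curvature_sag_px, speckle_contrast = speckle_contrast,
    static_frame_correlation = static_frame_correlation,
    n_vessels = as.integer(n_vessels), vessel_radius_px = vessel_radius_px,
    vessel_slab = vessel_slab, jitter_walk_sigma_px = jitter_walk_sigma_px,
    intra_frame_shift_px = intra_frame_shift_px,
    noise_floor = noise_floor,
    choroid_decay_tau_px = choroid_decay_tau_px, seed = as.integer(seed)
  ), class = "PhantomSpec")
  validate_phantom_spec(spec)
  spec
}

#' Default retinal layer stack
#'
#' A generic rodent-like banding pattern: bright NFL, moderate GCL/IPL,
#' dark INL, bright OPL, dark ONL, bright IS/OS and RPE, with a moderately
#' reflective choroid below. Reflectivities follow the qualitative
#' bright/dark alternation seen in retinal B-scans; they are not
#' species-calibrated.
#'
#' @return data.frame with columns `name`, `thickness_um`, `reflectivity`.
#' @export
default_layers <- function() {
  data.frame(
    name = c("NFL", "GCL_IPL", "INL", "OPL", "ONL", "IS_OS", "RPE", "choroid"),
    thickness_um = c(15, 40, 25, 15, 50, 20, 25, 150),
    reflectivity = c(0.90, 0.50, 0.25, 0.50, 0.22, 0.70, 0.95, 0.30),
    stringsAsFactors = FALSE
  )
}

validate_phantom_spec <- function(spec) {
  validate_meta(spec$meta)
  ly <- spec$layers
  if (!all(c("name", "thickness_um", "reflectivity") %in% names(ly))) {
    stop_fmt("layers must have columns name, thickness_um, reflectivity")
  }
  if (any(ly$thickness_um <= 0)) stop_fmt("layer thicknesses must be > 0")
  if (any(ly$reflectivity < 0 | ly$reflectivity > 1)) {
    stop_fmt("layer reflectivities must lie in [0,1]")
  }
  stack_px <- sum(ly$thickness_um) / spec$meta$axial_um_per_px
  if (spec$ilm_center_depth_px + stack_px + spec$curvature_sag_px >=
      spec$meta$n_depth) {
    stop_fmt("layer stack (%.0f px) plus sag does not fit below the ILM centre depth",
             stack_px)
  }
  for (f in c("speckle_contrast", "static_frame_correlation")) {
    v <- spec[[f]]
    if (!is_scalar_num(v) || v < 0 || v > 1) stop_fmt("%s must lie in [0,1]", f)
  }
  if (spec$curvature_sag_px < 0) stop_fmt("curvature_sag_px must be >= 0")
  if (spec$jitter_walk_sigma_px < 0) stop_fmt("jitter_walk_sigma_px must be >= 0")
  if (spec$n_vessels > 0 && !all(spec$vessel_slab %in% ly$name)) {
    stop_fmt("vessel slab name(s) not in layers: %s",
             paste(setdiff(spec$vessel_slab, ly$name), collapse = ", "))
  }
  invisible(spec)
}

# Fractional ILM depth per (location, ascan): parabolic bowl, deepest at
# the corners, with peak-to-corner excursion = curvature_sag_px.
phantom_ilm_geometry <- function(spec) {
  nl <- spec$meta$n_locations
  nx <- spec$meta$n_ascans
  u <- if (nx > 1) 2 * (0:(nx - 1)) / (nx - 1) - 1 else 0
  v <- if (nl > 1) 2 * (0:(nl - 1)) / (nl - 1) - 1 else 0
  sag <- spec$curvature_sag_px * (outer(v^2, u^2, "+")) / 2
  spec$ilm_center_depth_px + sag   # [location, ascan]
}

#' Generate a structural phantom volume with ground truth
#'
#' Builds a BM-form linear-intensity [oct_volume()] from the layered
#' geometry, multiplies in speckle (exponential intensity, unit mean,
#' blended toward deterministic intensity by `speckle_contrast`), shares
#' one speckle realization across the repeat frames of each location for
#' static tissue (blended with independent per-frame draws at weight
#' `1 - static_frame_correlation`) while vessel voxels are redrawn
#' independently every frame, and finally applies the per-location integer
#' axial jitter. Ground-truth surfaces, thickness, vessel mask and jitter
#' are returned alongside; surfaces and the vessel mask are expressed in
#' the motion-free (aligned) frame.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (BM-form linear `OCTVolume`) and
#'   `truth` (class `PhantomTruth`: `ilm_surface`, `rpe_surface`,
#'   `thickness_um`, `vessel_mask`, `jitter_px`, `seed`).
#' @export
generate_structural <- function(spec) {
  validate_phantom_spec(spec)
  meta <- spec$meta
  nl <- meta$n_locations; nr <- meta$n_repeats
  nz <- meta$n_depth; nx <- meta$n_ascans
  ly <- spec$layers
  px_per_um <- 1 / meta$axial_um_per_px
  cum_px <- c(0, cumsum(ly$thickness_um * px_per_um))   # boundaries, rel to ILM
  retinal <- ly$name != "choroid"
  retina_px <- sum(ly$thickness_um[retinal]) * px_per_um
  refl <- c(spec$noise_floor, ly$reflectivity, spec$noise_floor)

  ilm_z <- phantom_ilm_geometry(spec)                   # [loc, ascan], fractional

  with_seed(spec$seed, {
    # --- vessels (drawn first: fixed RNG order) ---
    vessels <- NULL
    if (spec$n_vessels > 0) {
      host <- rep(spec$vessel_slab, length.out = spec$n_vessels)
      vessels <- lapply(seq_len(spec$n_vessels), function(k) {
        li <- match(host[k], ly$name)
        # mid-slab, except the choroid where vessels concentrate just below
        # Bruch's membrane (choriocapillaris)
        frac <- if (ly$name[li] == "choroid") 0.2 else 0.5
        depth_rel <- cum_px[li] + frac * (cum_px[li + 1] - cum_px[li])
        x0 <- runif(1, 0.1, 0.9) * (nx - 1)
        slope <- runif(1, -0.5, 0.5)
        list(x0 = x0, slope = slope, depth_rel = depth_rel)
      })
    }
    # --- jitter random walk (integer, per location) ---
    jitter <- if (spec$jitter_walk_sigma_px > 0 && nl > 1) {
      as.integer(round(cumsum(c(0, rnorm(nl - 1, 0, spec$jitter_walk_sigma_px)))))
    } else integer(nl)

    vol <- array(0, dim = c(nl, nr, nz, nx))
    vmask <- array(FALSE, dim = c(nl, nz, nx))
    zidx <- 0:(nz - 1)
    w <- 1 - spec$static_frame_correlation
    cs <- spec$speckle_contrast

    for (l in seq_len(nl)) {
      s <- ilm_z[l, ]                                   # per-ascan ILM depth
      rel <- outer(zidx, s, "-")                        # [depth, ascan]
      lay <- findInterval(rel, cum_px)                  # 0 above, L+1 below
      refl_frame <- matrix(refl[lay + 1L], nz, nx)
      # choroid fades exponentially into the floor (depth attenuation)
      ch <- match("choroid", ly$name)
      if (!is.na(ch) && spec$choroid_decay_tau_px > 0) {
        in_ch <- lay == ch
        if (any(in_ch)) {
          depth_in <- rel[in_ch] - cum_px[ch]
          decay <- exp(-depth_in / spec$choroid_decay_tau_px)
          refl_frame[in_ch] <- pmax(refl_frame[in_ch] * decay, spec$noise_floor)
        }
      }
      # vessel mask for this location
      vm <- matrix(FALSE, nz, nx)
      if (!is.null(vessels)) {
        for (vs in vessels) {
          xc <- vs$x0 + vs$slope * (l - 1)
          if (xc < -spec$vessel_radius_px || xc > nx - 1 + spec$vessel_radius_px) next
          xr <- max(0, floor(xc - spec$vessel_radius_px)):
                min(nx - 1, ceiling(xc + spec$vessel_radius_px))
          for (x in xr) {
            zc <- s[x + 1] + vs$depth_rel
            dz2 <- spec$vessel_radius_px^2 - (x - xc)^2
            if (dz2 < 0) next
            zr <- max(0, ceiling(zc - sqrt(dz2))):min(nz - 1, floor(zc + sqrt(dz2)))
            vm[zr + 1L, x + 1L] <- TRUE
          }
        }
      }
      vmask[l, , ] <- vm
      # speckle: shared field + per-frame blend; vessels fully redrawn
      shared <- matrix(rexp(nz * nx), nz, nx)
      for (r in seq_len(nr)) {
        indep <- matrix(rexp(nz * nx), nz, nx)
        sfield <- (1 - w) * shared + w * indep
        if (any(vm)) {
          sfield[vm] <- rexp(sum(vm))
        }
        mult <- (1 - cs) + cs * sfield
        frame <- refl_frame * mult
        if (spec$intra_frame_shift_px > 0 && r > 1) {
          dz <- runif(1, -spec$intra_frame_shift_px, spec$intra_frame_shift_px)
          frame <- pmax(fourier_shift(frame, dz, 0), 0)
        }
        if (jitter[l] != 0) frame <- roll_rows(frame, jitter[l])
        vol[l, r, , ] <- frame
      }
    }

    truth <- structure(list(
      ilm_surface = surface_map(ilm_z, "ILM_NFL"),
      rpe_surface = surface_map(ilm_z + retina_px, "RPE_BrM"),
      thickness_um = matrix(retina_px * meta$axial_um_per_px, nl, nx),
      vessel_mask = vmask,
      jitter_px = jitter,
      seed = spec$seed
    ), class = "PhantomTruth")

    list(volume = oct_volume(vol, meta, is_averaged = FALSE,
                             intensity_domain = "linear"),
         truth = truth)
  })
}

#' Convert a linear-intensity volume to log grayscale
#'
#' Maps `10*log10(I + eps)` affinely from `[floor_db, ceil_db]` to
#' \[0, 1\] with clipping, matching the grayscale convention of the fringe
#' reconstruction (which computes `20*log10` of magnitude).
#'
#' @param vol Linear-intensity [oct_volume()].
#' @param floor_db,ceil_db Display dynamic range in dB.
#' @param epsilon Log guard.
#' @return A log-grayscale `OCTVolume` of the same form.
#' @export
as_grayscale <- function(vol, floor_db = -35, ceil_db = 5, epsilon = 1e-12) {
  stopifnot(inherits(vol, "OCTVolume"))
  if (vol$intensity_domain != "linear") return(vol)
  db <- 10 * log10(vol$data + epsilon)
  g <- clamp01((db - floor_db) / (ceil_db - floor_db))
  oct_volume(g, vol$meta, is_averaged = vol$is_averaged,
             intensity_domain = "log_grayscale", dtype = vol$dtype)
}

SPECIES_THICKNESS_UM <- c(mouse = 210, rat = 186, owl = 260,
                          opossum = 138.5, sturgeon = 142)

#' Species phantom presets
#'
#' Returns a [phantom_spec()] whose retinal layer thicknesses are scaled so
#' the total ILM-to-RPE distance equals the species' measured mean retinal
#' thickness (mouse 210, rat 186, owl 260, opossum 138.5, sturgeon 142
#' micrometres). The owl preset hosts vessels only in the choroid: the
#' avian retina is avascular, supplied from the choroid (and the pecten,
#' which is not modelled).
#'
#' Per-layer thickness fractions within the retina are not species
#' calibrated; the default stack's proportions are rescaled uniformly.
#'
#' @param name One of `"mouse"`, `"rat"`, `"owl"`, `"opossum"`,
#'   `"sturgeon"`.
#' @param ... Overrides passed to [phantom_spec()] (e.g. `meta`, `seed`).
#' @return A `PhantomSpec`.
#' @export
species_preset <- function(name, ...) {
  if (!name %in% names(SPECIES_THICKNESS_UM)) {
    stop_fmt("unknown species '%s' (known: %s)", name,
             paste(names(SPECIES_THICKNESS_UM), collapse = ", "))
  }
  total <- SPECIES_THICKNESS_UM[[name]]
  ly <- default_layers()
  retinal <- ly$name != "choroid"
  ly$thickness_um[retinal] <- ly$thickness_um[retinal] *
    total / sum(ly$thickness_um[retinal])
  args <- list(...)
  if (is.null(args$layers)) args$layers <- ly
  if (name == "owl") {
    # avascular retina over a densely vascularized choroid
    if (is.null(args$vessel_slab)) args$vessel_slab <- "choroid"
    if (is.null(args$n_vessels)) args$n_vessels <- 16
    if (is.null(args$vessel_radius_px)) args$vessel_radius_px <- 4
  }
  sp <- do.call(phantom_spec, args)
  sp$species <- name
  sp
}
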