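# Configuration schema: section -> key -> default. `NULL` defaults are
# filled at run time.
config_schema <- function() {
  list(
    phantom = list(species = "mouse", seed = 1, n_locations = 64,
                   n_ascans = 64, n_depth = 256, n_repeats = 3,
                   axial_um_per_px = 3.0, curvature_sag_px = 10,
                   speckle_contrast = 0.6, static_frame_correlation = 0.9,
                   n_vessels = 6, vessel_radius_px = 3,
                   jitter_walk_sigma_px = 0),
    recon = list(use_fringes = FALSE, dispersion_c2 = 0, dispersion_c3 = 0,
                 floor_db = -30, ceil_db = 60),
    register = list(ref = "auto", max_lag = 50, upsample = 10),
    flatten = list(gauss_sigma_px = 2, median_kernel_px = 3,
                   threshold_method = "otsu", percentile_q = 75,
                   canny_sigma = 2, canny_low = 0.1, canny_high = 0.3,
                   surface_median_window = 15, center_depth_px = NULL),
    segment = list(smooth_dx_px = 2, smooth_dy_px = 2, min_separation_px = 20,
                   cost_sigma_px = 2, band_halfwidth_px = 60),
    angio = list(enabled = TRUE, slabs = c("superficial", "choroid"),
                 bg_sigma = 25, stretch = c(1, 99))
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults section by section, rejects unknown sections or keys,
#' and checks parameter invariants before any stage executes. The
#' configuration may be a YAML file path or a nested list.
#'
#' @param config Path to a YAML document or a nested list.
#' @return The fully defaulted configuration (nested list).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_fmt("config must be a list or a YAML file path")
  schema <- config_schema()
  errs <- character(0)
  unknown_sec <- setdiff(names(config), names(schema))
  if (length(unknown_sec)) {
    errs <- c(errs, sprintf("unknown section(s): %s",
                            paste(unknown_sec, collapse = ", ")))
  }
  out <- schema
  for (sec in intersect(names(config), names(schema))) {
    unknown <- setdiff(names(config[[sec]]), names(schema[[sec]]))
    if (length(unknown)) {
      errs <- c(errs, sprintf("unknown key(s) in '%s': %s", sec,
                              paste(unknown, collapse = ", ")))
    }
    for (k in intersect(names(config[[sec]]), names(schema[[sec]]))) {
      out[[sec]][[k]] <- config[[sec]][[k]]
    }
  }
  ph <- out$phantom
  if (!ph$species %in% names(SPECIES_THICKNESS_UM)) {
    errs <- c(errs, sprintf("unknown species '%s'", ph$species))
  }
  if (ph$curvature_sag_px < 0) errs <- c(errs, "phantom: negative curvature_sag_px")
  if (ph$jitter_walk_sigma_px < 0) errs <- c(errs, "phantom: negative jitter_walk_sigma_px")
  fl <- out$flatten
  if (fl$canny_low >= fl$canny_high) {
    errs <- c(errs, "flatten: canny_low must be < canny_high")
  }
  if (fl$median_kernel_px %% 2 != 1) errs <- c(errs, "flatten: median_kernel_px must be odd")
  if (out$recon$ceil_db <= out$recon$floor_db) {
    errs <- c(errs, "recon: ceil_db must exceed floor_db")
  }
  if (out$segment$min_separation_px < 1) {
    errs <- c(errs, "segment: min_separation_px must be >= 1")
  }
  if (out$angio$enabled && ph$n_repeats < 2) {
    errs <- c(errs, "angio: N < 2 repeats, speckle variance undefined")
  }
  if (length(errs)) {
    stop(paste(c("invalid configuration:", paste(" -", errs)), collapse = "\n"),
         call. = FALSE)
  }
  out
}

log_stage <- function(msg, ...) {
  message(sprintf("[octapipe %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(msg, ...)))
}

#' Run the full phantom-to-angiography pipeline
#'
#' Executes the stages in fixed order: phantom generation, reconstruction
#' (either through synthesized spectral fringes and the FFT chain, or a
#' direct log-grayscale conversion of the structural volume), BM-scan
#' registration and averaging, axial volume alignment, flattening,
#' graph-cut segmentation with a thickness summary, and (optionally)
#' speckle-variance angiography with en face projections. Every stage's
#' parameters, output files and their MD5 hashes are written to a
#' provenance manifest, so re-running with the same configuration and
#' seed reproduces all numeric outputs.
#'
#' @param config Configuration (list or YAML path); see
#'   [validate_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest (nested list).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("octapipe")),
                   seed = cfg$phantom$seed, config = cfg, stages = list())
  emit <- function(stage, params, files) {
    files <- files[file.exists(files)]
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      stage = stage, parameters = params,
      outputs = as.list(tools::md5sum(files)))
    log_stage("stage %-10s done (%d artifact%s)", stage, length(files),
              if (length(files) == 1) "" else "s")
  }
  ph <- cfg$phantom

  # 1. phantom
  spec <- species_preset(ph$species,
                         meta = acquisition_meta(
                           n_locations = ph$n_locations, n_repeats = ph$n_repeats,
                           n_ascans = ph$n_ascans, n_k = 2 * ph$n_depth,
                           n_depth = ph$n_depth,
                           axial_um_per_px = ph$axial_um_per_px),
                         curvature_sag_px = ph$curvature_sag_px,
                         speckle_contrast = ph$speckle_contrast,
                         static_frame_correlation = ph$static_frame_correlation,
                         n_vessels = ph$n_vessels,
                         vessel_radius_px = ph$vessel_radius_px,
                         jitter_walk_sigma_px = ph$jitter_walk_sigma_px,
                         seed = ph$seed)
  gen <- generate_structural(spec)
  truth_csv <- file.path(out_dir, "truth_surfaces.csv")
  utils::write.csv(data.frame(
    location = rep(seq_len(nrow(gen$truth$ilm_surface$z)),
                   ncol(gen$truth$ilm_surface$z)),
    ascan = rep(seq_len(ncol(gen$truth$ilm_surface$z)),
                each = nrow(gen$truth$ilm_surface$z)),
    ilm_z = as.vector(gen$truth$ilm_surface$z),
    rpe_z = as.vector(gen$truth$rpe_surface$z)), truth_csv, row.names = FALSE)
  jitter_csv <- file.path(out_dir, "truth_jitter.csv")
  utils::write.csv(data.frame(location = seq_along(gen$truth$jitter_px),
                              jitter_px = gen$truth$jitter_px),
                   jitter_csv, row.names = FALSE)
  emit("phantom", spec[c("ilm_center_depth_px", "curvature_sag_px",
                         "speckle_contrast", "static_frame_correlation",
                         "n_vessels", "seed")],
       c(truth_csv, jitter_csv))

  # 2. reconstruction
  rc <- cfg$recon
  if (isTRUE(rc$use_fringes)) {
    fv <- synthesize_fringes(gen$volume, spec)
    params <- recon_params(rc$dispersion_c2, rc$dispersion_c3,
                           rc$floor_db, rc$ceil_db)
    bm <- reconstruct_volume(fv, params)
    emit("reconstruct", c(mode = "fringe_fft", rc), character(0))
  } else {
    bm <- as_grayscale(gen$volume)
    emit("reconstruct", list(mode = "direct_grayscale"), character(0))
  }

  # 3. registration: BM averaging + axial alignment
  rg <- cfg$register
  av <- average_volume(bm, upsample = rg$upsample)
  ref <- if (identical(rg$ref, "auto")) "auto" else as.integer(rg$ref)
  al <- axial_align_volume(av$volume, ref_index = ref, max_lag = rg$max_lag)
  off_csv <- file.path(out_dir, "axial_offsets.csv")
  utils::write.csv(data.frame(location = seq_along(al$offsets),
                              offset_px = al$offsets), off_csv, row.names = FALSE)
  emit("register", rg, off_csv)

  # 4. flattening
  fl <- cfg$flatten
  fparams <- flatten_params(fl$gauss_sigma_px, fl$median_kernel_px,
                            fl$threshold_method, fl$percentile_q,
                            fl$canny_sigma, fl$canny_low, fl$canny_high,
                            fl$surface_median_window, fl$center_depth_px)
  flat <- flatten_volume(al$volume, fparams)
  surf_csv <- file.path(out_dir, "flatten_surface.csv")
  utils::write.csv(as.data.frame(flat$surface$z), surf_csv, row.names = FALSE)
  emit("flatten", fl, surf_csv)

  # 5. segmentation + thickness
  sg <- cfg$segment
  center <- flat$center_depth_px
  band <- c(max(0, center - 20),
            min(ph$n_depth - 1, center + sg$band_halfwidth_px +
                  ceiling(SPECIES_THICKNESS_UM[[ph$species]] / ph$axial_um_per_px)))
  gparams <- graphcut_params(sg$smooth_dx_px, sg$smooth_dy_px,
                             sg$min_separation_px, sg$cost_sigma_px,
                             search_band = band)
  seg <- segment_surfaces_graphcut(flat$volume, gparams)
  th <- compute_thickness(seg$ilm, seg$rpe, ph$axial_um_per_px)
  th_csv <- file.path(out_dir, "thickness_summary.csv")
  utils::write.csv(data.frame(label = ph$species, n_columns = th$n_columns,
                              mean_um = th$mean_um, sd_um = th$sd_um),
                   th_csv, row.names = FALSE)
  th_tif <- file.path(out_dir, "thickness_map.tif")
  export_image(th$thickness_um / max(th$thickness_um), th_tif, "tiff16")
  fundus_png <- file.path(out_dir, "fundus.png")
  export_image(oct_fundus(al$volume), fundus_png, "png8")
  emit("segment", sg, c(th_csv, th_tif, fundus_png))

  # 6. angiography
  if (isTRUE(cfg$angio$enabled)) {
    an <- cfg$angio
    # apply the same axial offsets + flattening shifts to the BM volume
    bmdat <- bm$data
    shift_tot <- -matrix(al$offsets, ph$n_locations, ph$n_ascans) +
      round(center - flat$surface$z)
    for (l in seq_len(ph$n_locations)) {
      for (r in seq_len(ph$n_repeats)) {
        fr <- matrix(bmdat[l, r, , ], ph$n_depth, ph$n_ascans)
        for (x in seq_len(ph$n_ascans)) {
          s <- shift_tot[l, x]
          if (s != 0) fr[, x] <- roll_vec(fr[, x], s)
        }
        bmdat[l, r, , ] <- fr
      }
    }
    bm_flat <- oct_volume(bmdat, bm$meta, is_averaged = FALSE,
                          intensity_domain = bm$intensity_domain)
    angio <- build_angio_volume(bm_flat, upsample = rg$upsample)
    files <- character(0)
    for (sl in an$slabs) {
      mode <- if (sl == "choroid") "mean" else "max"
      ef <- enface_project(angio, seg$ilm, seg$rpe, slab_preset(sl), mode)
      ef <- enhance_contrast(ef, an$bg_sigma, an$stretch)
      f <- file.path(out_dir, sprintf("angio_%s.png", sl))
      export_image(ef, f, "png8")
      files <- c(files, f)
    }
    emit("angio", an, files)
  } else {
    emit("angio", list(enabled = FALSE), character(0))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
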