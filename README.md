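# octapipe

Post-processing for swept-source OCT (SS-OCT) retinal imaging and OCT
angiography, in R. The package takes raw k-linear spectral fringes (or an
already-reconstructed intensity volume) through the full chain used by
high-speed retinal SS-OCT systems:

1. **Reconstruction** — DC subtraction, dispersion compensation, Hann
   windowing, FFT, log grayscale: fringe → depth profile (A-scan).
2. **Registration** — FFT-based subpixel registration and averaging of the
   repeated B-scans (BM scans) at each position, then axial alignment of
   neighbouring B-scans by normalized cross-correlation.
3. **Flattening** — per-B-scan surface detection (blur, median, threshold,
   Canny, first-edge) and circular A-line shifts to a common centre depth.
4. **Segmentation** — ILM/NFL and RPE/BrM surfaces as exact minimum s-t
   cuts on the optimal-surface graph; retinal thickness as mean ± SD of
   `(RPE − ILM) ×` axial pitch.
5. **Angiography** — speckle-variance flow contrast over the BM repeats,
   depth-resolved en face slab projections (superficial / intermediate /
   deep plexus, choroid), background subtraction and contrast stretching.

It is aimed at researchers building or validating OCT/OCTA processing
chains who need a tested, scriptable reference implementation with known
ground truth. Since raw retinal datasets are rarely shareable, the package
includes a synthetic retinal phantom — layered reflectivity, speckle, flow
decorrelation, axial motion — whose exact surfaces, thickness, vessel mask
and motion are returned alongside the volume.

The modelled acquisition is a 100 kHz swept source scanning 360 B-scan
positions × 3 repeats × 360 A-scans at 1024 depth pixels (≈ 4 s per
volume).

## The core statistic

For the N registered repeat frames at one position, flow contrast at voxel
`(z, x)` is the interframe population variance of the displayed
(log-grayscale) intensity

    sv(z, x) = (1/N) * sum_i ( I_i(z, x) − mean_i I_i(z, x) )²,

which is near zero where tissue is static (frames share their speckle
realization) and large where moving blood decorrelates the speckle between
repeats. Layer surfaces are global minimizers of signed axial-gradient
costs under hard smoothness bounds, solved exactly by min-cut/max-flow.

## Worked example

```r
library(octapipe)

meta <- acquisition_meta(n_locations = 16, n_repeats = 3, n_ascans = 48,
                         n_k = 512, n_depth = 256, axial_um_per_px = 3)
spec <- species_preset("mouse", meta = meta, curvature_sag_px = 10,
                       n_vessels = 2, seed = 1)
ph   <- generate_structural(spec)          # volume + ground truth

vol  <- as_grayscale(ph$volume)
avg  <- average_volume(vol)                # BM registration + averaging
ali  <- axial_align_volume(avg$volume, max_lag = 20)
flat <- flatten_volume(ali$volume)
seg  <- segment_surfaces_graphcut(flat$volume,
                                  graphcut_params(search_band = c(50, 220)))
compute_thickness(seg$ilm, seg$rpe, meta$axial_um_per_px)
#> Retinal thickness: 208.3 +/- 2.2 um (n = 768 columns)

mean(ph$truth$thickness_um)                # ground truth for this preset
#> [1] 210
```

The recovered 208.3 µm agrees with the phantom's 210 µm ground truth to
within the sub-2 µm bias expected from integer-pixel surfaces at 3 µm
axial pitch. An angiogram of the superficial plexus:

```r
angio <- build_angio_volume(vol)           # speckle variance per location
ef <- enface_project(angio, seg$ilm, seg$rpe,
                     slab_preset("superficial"), mode = "max")
export_image(enhance_contrast(ef), "superficial.png", "png8")
```

A command-line front end over the same functions lives in
`inst/cli/octapipe.R` (subcommands `phantom`, `recon`, `register`,
`flatten`, `segment`, `angio`, `enface`, `pipeline`), and
`run_pipeline()` orchestrates all stages from one YAML configuration with
a provenance manifest.

## Method vignette

`vignettes/oct-pipeline-methods.Rmd` documents the models, parameter
defaults with their units and rationale, the phantom's scope and
limitations, and the numerical choices (tie-breaks, boundary handling,
tolerances) in detail.
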