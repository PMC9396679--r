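Package: octapipe
Title: Swept-Source OCT and OCT Angiography Post-Processing Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-processing toolchain for swept-source optical coherence
    tomography (SS-OCT) retinal volumes: reconstruction of depth profiles from
    k-linear spectral fringes (DC subtraction, dispersion compensation, Hann
    windowing, FFT, log grayscale), FFT-based subpixel registration and
    averaging of repeated B-scans, axial inter-B-scan alignment by normalized
    cross-correlation, B-scan flattening by circular A-line shifts, graph-cut
    (minimum s-t cut) segmentation of the ILM/NFL and RPE/BrM surfaces with
    retinal thickness statistics, and speckle-variance OCT angiography with
    depth-resolved en face slab projections. Includes a synthetic retinal
    phantom generator with layered reflectivity, speckle, flow decorrelation,
    and axial motion, providing full ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    yaml,
    jsonlite,
    tiff,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
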