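Package: optofret
Title: Ratiometric FRET Imaging Analysis for Optogenetically Stimulated Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of dual-camera ratiometric FRET biosensor
    imaging in optogenetically stimulated cells. Provides camera and
    illumination corrections (dark frame, half-chip sensitivity step, dust
    spot, systematic ratio gradient), polynomial dual-camera channel
    registration by correlation maximization, cell segmentation and
    reciprocal nearest-neighbor tracking, stimulus-response kinetics
    (population time series, single-cell fold changes, two-pulse peak
    ratios), a diffusion model of the photobleached sensor pool with ratio
    correction, spatial signal-spread profiling (geodesic distance from the
    leading edge and concentric radial bins around a stimulation site),
    migration persistence statistics, and a synthetic dual-camera microscopy
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
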