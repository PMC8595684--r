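# optofret

Quantitative analysis of dual-camera ratiometric FRET biosensor imaging in
optogenetically stimulated cells.

Neutrophil-like cells expressing a membrane-anchored Cdc42 FRET biosensor
(a red/far-red donor/acceptor pair imaged simultaneously on two cameras)
respond to optogenetic receptor stimulation with fast, spatially confined
GTPase activation. Extracting that signal quantitatively requires a chain
of image-processing steps whose systematic errors are each larger than the
~11% dynamic range of the sensor: camera dark offsets, a chip-half
sensitivity step, dust in the light path, illumination gradients,
sub-pixel inter-camera misalignment, photobleaching by the stimulating
laser, and dead-cell autofluorescence. `optofret` implements that chain as
composable, tested R functions, together with a synthetic dual-camera
microscopy generator with known ground truth so that every stage — and the
pipeline end to end — can be validated by parameter recovery.

## What the package computes

For a per-pixel total sensor emission *S* and activity *A* ∈ [0, 1], the
image model is the standard FRET redistribution form

    R = R0 (1 + a A),   donor = S L_d / (1 + R),   acceptor = S L_a R / (1 + R)

with `a` the sensor dynamic range (default 0.11) and `L` each camera's
multiplicative illumination/sensitivity field. The analysis inverts this
chain:

* **Camera corrections** — dark-frame median subtraction; a half-chip
  multiplicative step estimated from the two rows either side of the chip
  middle of a uniform-dye image; a dust correction restoring a dim spot to
  the smooth (sigma 30) illumination field; and a mean-one ratio-correction
  image built from 24 px block medians of unstimulated-cell ratio images
  (`build_dark_correction()`, `build_half_chip_correction()`,
  `build_dust_correction()`, `build_ratio_correction()`,
  `apply_corrections()`).
* **Channel registration** — a 12-coefficient polynomial map (translation,
  axis stretch, second-order terms) from acceptor to donor camera
  coordinates, fitted by maximizing the Pearson correlation of
  gradient-feature images in three stages plus a Gauss–Newton polish;
  typical recovery error is < 0.1 px RMS (`fit_alignment()`,
  `apply_alignment()`).
* **Segmentation and tracking** — summed-channel segmentation (Gaussian
  smooth, sigma-25 unsharp mask, Otsu threshold, 8-connected components,
  area limits) and reciprocal nearest-neighbor linking with conservative
  tie-breaking (`segment_cells()`, `track_cells()`).
* **Ratio kinetics** — per-pixel ratios with dim / near-saturation /
  low-ratio (< 0.8, dead cell) filters; well-level series as the ratio of
  channel means normalized to the pre-stimulus window; single-cell
  response fold changes P/C2 and C1/C2 over five-frame windows
  (C1 = −13.5..−7.5 s, C2 = −6..0 s, P = 4.5..10.5 s relative to the last
  pre-stimulus frame); two-pulse second-peak amplitude ratios
  (`compute_ratio_image()`, `population_timeseries()`,
  `single_cell_fold_change()`, `second_peak_ratio()`).
* **Photobleach correction** — the stimulating laser bleaches a Gaussian
  pool of sensor that spreads by free 2-D diffusion,
  σ²(t) = σ0² + 2Dt with D = 0.5 µm²/s; the bleached fraction *b* biases
  the observed ratio by (1 − α·b), which is divided out per frame
  (`fit_bleach_profile()`, `fit_bleach_series()`, `propagate_bleach()`,
  `correct_ratio_series()`).
* **Spatial profiling** — geodesic (within-mask, quasi-Euclidean)
  distance from the detected leading-edge protrusion, with profiles
  normalized to 1 at the edge; concentric 1 µm annuli around a focal
  stimulation site with per-bin ratio-of-means fold changes; automated
  screening of center-stimulated cells (`detect_protrusion()`,
  `geodesic_distance()`, `edge_distance_profile()`, `radial_profile()`,
  `screen_center_stim_cell()`, `select_edge_target()`).
* **Migration statistics** — mean-squared displacement from the track
  start, directional persistence cosines against the first 30 s step
  (5 µm inclusion screens), and a Welch unequal-variance t test on
  per-experiment phenotype fractions (`mean_squared_displacement()`,
  `persistence_cosine()`, `phenotype_fraction_test()`).
* **Synthetic scenes** — deformable moving cells with a feedback-kinetics
  activity model (fast and slow negative-feedback pools driven by a
  bistable-receptor input), rendered through a configurable optics model
  (misalignment, vignette, half-chip step, dust, Poisson + read noise)
  (`make_scene()`, `render_frames()`, `render_bleach()`, `run_assay()`).

## Worked example

Simulate a global-stimulation well (9 cells, single light pulse at
t = 15.75 s, programmed 6% response), render it through a realistic
camera model, and recover the population response:

```r
library(optofret)
sp <- scene_params(field_shape = c(160, 160), n_cells = 9, cell_radius = 3,
                   n_frames = 24, speed = 0.02,
                   programmed_amplitude = 0.06,
                   stimuli = list(stimulus_event(15.75, "global")))
scene <- make_scene(sp, seed = 7)
optics <- optics_model(c(160, 160), vignette_strength = 0.01,
                       half_chip_factor = 0.99, dust = NULL, bg_level = 400)
stack <- render_frames(scene, optics)
series <- population_timeseries(stack,
  corrections = correction_set(matrix(100, 160, 160), matrix(100, 160, 160)),
  background = list(donor = 400, acceptor = 400))
head(round(series, 4), 8)
#>    time  ratio ratio_norm n_valid
#> 1 -15.0 1.0413     0.9992    2731
#> 2 -13.5 1.0421     0.9999    2730
#> 3 -12.0 1.0428     1.0007    2719
#> ...
```

`time` is seconds relative to the last frame before stimulation, `ratio`
is the acceptor/donor ratio of means over valid pixels, and `ratio_norm`
is that series normalized to its pre-stimulus mean — flat at 1.000 before
the pulse, rising to ~1.06 in the peak window for this scene.

The same experiment through the whole assay runner, at two doses:

```r
cfg <- list(assay = "global", out_dir = tempdir(), seed = 7,
            field_shape = c(160, 160), n_frames = 24, n_cells = 9,
            cell_radius = 3, doses = c(0, 6), stim_time = 15.75)
res <- run_assay(cfg)
fc <- res$fold_changes[res$fold_changes$included, ]
round(tapply(fc$p_c2, fc$dose, mean), 4)
#>      0      6
#> 1.0000 1.0598
```

The mean single-cell peak fold change (P/C2) recovers the programmed
amplitudes — 1.000 for the unstimulated wells and 1.060 for the 6% dose —
and the QC log reconciles detected, included, and excluded cells per well
(here 9 detected, 8 included, 1 excluded by the tracking screen).

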