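---
title: "Models and methods behind optofret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optofret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`optofret` quantifies ratiometric FRET biosensor imaging of
optogenetically stimulated cells acquired on a dual-camera microscope.
This vignette documents the models the package implements, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the numerical and design choices a maintainer should
know about.

## Image formation model

Per pixel, with total sensor emission $S$, activity $A \in [0,1]$, and
baseline ratio $R_0$:

$$R = R_0\,(1 + a\,A), \qquad
  \mathrm{donor} = \frac{S\,L_d}{1+R}, \qquad
  \mathrm{acceptor} = \frac{S\,L_a\,R}{1+R}.$$

FRET redistributes emission between the channels without creating it:
donor + acceptor equals $S L$ regardless of $A$ (asserted to $10^{-9}$
relative in the tests). The modulation depth $a$ defaults to 0.11, the
dynamic-range scale of red/far-red sensor pairs; $L_c$ is camera $c$'s
multiplicative illumination/sensitivity field (vignette × half-chip step
× dust spot). Counts are
$g\cdot\mathrm{Pois}(\mu) + \mathrm{dark} + \mathcal N(0, \sigma_r^2)$,
clipped (never rescaled) at the 16-bit ceiling; the pixel variance
$g^2\mu + \sigma_r^2$ is verified by Monte Carlo. The donor camera sees
the sample through its own coordinate system: the ideal donor image is
resampled through the numerically inverted acceptor→donor polynomial map
before camera effects and noise, so that registration recovery tests are
meaningful round trips.

## Activity kinetics in the generator

No kinetic rate constants are available for the signaling circuit being
emulated, only qualitative response features. The generator therefore
uses a deliberately phenomenological model — receptor drive plus two
negative-feedback pools:

$$\frac{dA}{dt} = k_{in}\,u(t)\,g(x) - (k_{off} + k_1 F_1 + k_2 F_2)\,A,
  \qquad \frac{dF_i}{dt} = a_i A - d_i F_i,$$

with $g(x) = \exp(-d(x,\mathrm{target})^2 / 2\ell^2)$ for focal stimuli
($\ell$ = `spread_length`, default 2.5 µm) and $g \equiv 1$ for global
stimuli. Each light pulse contributes a difference-of-exponentials
receptor drive (activation time `receptor_tau_on` = 2 s; inactivation
under the imaging light `receptor_tau` = 6 s, normalized to peak at the
pulse power); a constant basal drive gives a nonzero resting activity so
that post-stimulus undershoot is expressible. The defaults
(`kinetics_params()`) were tuned once, on the ODE alone, to the
qualitative features of the emulated assay class: single-pulse peak
within a few seconds, undershoot minimum near 30 s, recovery within
about two minutes. Known limitation: with linear feedback pools the
undershoot depth is bounded well below what strongly adaptive circuits
show; the undershoot is present but shallow (a few percent of the peak).
Integration is fixed-step RK4 at 30 substeps per frame, vectorized over
pixels, and is checked against a stiff-solver reference to $10^{-3}$
relative.

### Programmed response amplitudes

Recovery tests need ground truth stated in the units the analysis
measures. When `programmed_amplitude` is set, the ratio modulation is
rescaled so that the *peak-window* (4.5–10.5 s after the last
pre-stimulus frame) mean fold change over the pre-stimulus level equals
the programmed value exactly. A programmed 6% scene therefore has a true
mean P/C2 of 1.060 by construction, and the dose–response recovery test
compares measured means against that definition.

## Camera and illumination corrections

* **Dark**: per-pixel median of ≥ 2 unilluminated frames, subtracted
  with clipping at zero (79 frames in the emulated calibration
  protocol).
* **Half-chip**: ratio of the mean of the two rows above the chip middle
  to the two rows below, from a median uniform-dye image; applied as a
  multiplicative field equal to 1 on the top half.
* **Dust**: pixels ≥ 2% dimmer (default `dim_threshold` 0.98; the source
  protocol states a dim-pixel mask without a number) than the sigma-30
  smoothing of the dye image are flagged; the smooth reference is then
  re-estimated with the flagged region inpainted (a single-pass smooth
  is itself depressed by the spot and would leave a ~1.5% residual); a
  sigma-10 feathered mask blends the correction in, with flagged pixels
  fully restored and the far field exactly 1. Flagged area above 10% of
  the chip is rejected as a bad calibration image.
* **Ratio correction**: per-pixel median of in-mask ratio images →
  24 px block medians (partial edge blocks included; empty blocks filled
  from neighbors) → sigma-5 smoothing *after removing the best-fit
  plane* (reflective smoothing of the raw block image flattens, near the
  borders, exactly the large-scale gradient this correction exists to
  capture; the plane is restored after smoothing) → bilinear upsampling
  with one linearly extrapolated ring so border pixels are corrected →
  rescaled to mean 1 so absolute ratio levels are preserved. Applied by
  dividing ratio images.

Gaussian filters use reflective boundaries throughout (avoiding edge
darkening on correction fields), with the single plane-removal exception
above. Whether the dust correction multiplies or divides is ambiguous in
prose descriptions of such protocols; here it is a multiplicative field
restoring flagged pixels to the smooth-field value, which the
flat-field recovery tests validate end to end (corrected uniform-dye CV
< 0.5% against > 3% uncorrected). Note the dye-derived corrections
target *chip* artifacts; smooth illumination vignetting is deliberately
not corrected in single channels (it cancels to first order in the
ratio, and what survives is captured by the ratio correction), so the
flat-field validation scenes model a half-chip step and dust without
vignetting.

## Channel registration

The acceptor→donor map is polynomial per output axis — constant, $x$,
$y$, $x^2$, $y^2$, $xy$ — over coordinates normalized to $[-1,1]$
(conditioning for the quadratic terms). Features are
background-subtracted (1.5-percentile floor), normalized, sigma-2
smoothed gradient magnitudes. Fitting maximizes Pearson correlation in
stages: translation only on 4×4-binned images, all 12 coefficients on
binned images, then all 12 at full size. A border margin (14 px full
size) is excluded from the correlation: boundary padding of the feature
transform is not warp-invariant and measurably biases the optimum (~0.4
px at desk scale) if included. Because the Nelder–Mead simplex stalls in
the long flat valley of the 12-parameter surface (leaving ~0.3 px RMS
errors), a Gauss–Newton polish of the linearized objective follows the
simplex stages; recovery error on random warps (≤ 10 px shift, ≤ 1%
stretch, ≤ $10^{-5}$/px second-order) is then < 0.1 px RMS typical,
< 0.2 px in all tested cases. One model is intended per imaging session.
Resampling is bilinear; out-of-field samples are marked invalid, never
extrapolated; an exactly-identity model returns the input bit-exactly.

## Segmentation, tracking, background

Segmentation runs on summed donor+acceptor images: sigma-2 smooth,
unsharp masking (subtract a sigma-25 blur), Otsu threshold, 8-connected
components, area limits (defaults 80–2000 px² at 20×; the source
protocol states limits without values). A guard returns an empty
labeling when the Otsu split puts more than 45% of the frame in the
foreground, which only happens on structureless input. The procedure is
invariant to positive intensity rescaling. Both the dense-well
("automatic thresholding") and TIRF use cases use Otsu.

Background has two modes: dense wells use the dimmest 1.5-percentile
pixels to scale an empty-well profile image; sparse/TIRF fields build a
local-neighborhood (65 px radius disk, evaluated on a coarse grid and
interpolated) median background from conservative background pixels.
The dim-pixel selection is slightly low-biased under noise (it selects
the lower tail); the bias cancels when the empty-well profile is
processed identically, and is bounded in the tests.

Tracking links mutual nearest neighbors within `max_link` (default
10 µm/frame, unstated in the emulated protocol); exact distance ties
break reciprocity conservatively (no link). Tracks spanning every frame
are flagged complete; only complete tracks enter single-cell analyses.

## Ratio computation and kinetics

Pixel filters: dim (< 2% of the bit range on the background-subtracted
donor), near-saturating (> 98% of the range), and low ratio (< 0.8,
dead/unhealthy cells with high donor autofluorescence); thresholds for
dim/saturation are package defaults, the 0.8 cutoff is the emulated
protocol's. A zero or negative donor invalidates the pixel as dim rather
than producing an infinity. Well series are the *ratio of channel
means* over valid pixels (robust to brightness heterogeneity, matched
exactly against a ratio-of-means oracle), normalized by the pre-stimulus
mean, on a time axis relative to the last pre-stimulus frame. The
ratio correction enters the well series as the mean correction over the
same valid pixels.

Single-cell responses average the per-cell ratio over three five-frame
windows — C1 = [−13.5, −7.5] s, C2 = [−6, 0] s, P = [4.5, 10.5] s
(closed intervals; the five-frame definition at 1.5 s spacing is taken
as authoritative where window-length statements conflict) — and report
P/C2 and C1/C2. Cells are excluded with explicit reasons: incomplete
track, any saturated pixel in either channel, baseline (first ten
frames) ratio below 0.95, or missing window frames.

Two-pulse experiments report the ratio of second to first peak
amplitude, each amplitude being max(series − 1) within 15 s after its
pulse (the peak-search window is a package default; reported peaks are
well inside it). The second peak counts as resolved only when the series
dips between the two peak positions; closely spaced pulses (7 s) merge
into one rise and return a not-resolvable flag. Amplitudes are
baseline-subtracted (series − 1); an alternative raw-maxima definition
would differ only by the baseline normalization.

## Photobleach correction

A focal stimulus bleaches a Gaussian pool of sensor:
$b(r, 0) = b_0 e^{-r^2/2\sigma_0^2}$, spreading by free 2-D diffusion,
$\sigma^2(t) = \sigma_0^2 + 2Dt$ with amplitude scaled by
$\sigma_0^2/\sigma^2(t)$ (total bleached amount conserved; checked
against a finite-difference PDE oracle to < 0.5%). The printed diffusion
coefficient for membrane sensors of this class, 0.5 (in per-second
units), is dimensionally a diffusion coefficient and is used as
0.5 µm²/s. Because the donor and acceptor constructs bleach
asymmetrically, a bleached fraction $b$ biases the ratio by
$(1 - \alpha b)$; $\alpha$ is fit from a high-power calibration and the
correction divides each post-stimulus ratio frame by that factor, with
multiple pulses summed and clipped at $b \le 1$. Amplitudes scale
linearly with stimulus power relative to the calibration power (37 µW
calibration vs 0.8–4.3 µW experiments in the emulated assays). The
free-space closed form (rather than a bounded-domain solver) is
justified because corrections are small and local relative to the cell.
The assumed Gaussian initial profile matches how such calibration dips
are typically summarized. Note the sigma-1 ratio smoothing of the
standard pipeline slightly widens the sharp bleach dip; round-trip
validation therefore computes ratio frames unsmoothed.

## Spatial profiling

Protrusions are the largest 8-connected component of mask(t+1) \
mask(t), retained only if within one pixel of the protrusions from the
neighboring frame pairs. This temporal-consistency rule is implemented
as an overlap test against the 1-px dilation of each neighbor (requiring
full containment would reject every cell advancing more than one pixel
per frame). Geodesic distances use 8-connected steps with costs 1 and
√2 inside the mask (repeated chamfer sweeps to convergence — exact on
this graph, verified against Dijkstra), and edge profiles are normalized
to 1 at distance 0.

Radial profiles bin in-mask pixels into half-open 1 µm annuli
[k−1, k) by pixel-center Euclidean distance from the stimulation pixel;
per bin, ratio = mean acceptor / mean donor with the ratio correction
applied to the acceptor first; fold change divides by the same bin in
the frame immediately preceding stimulation. Bins with fewer than 5
valid pixels are reported missing; partial annuli at the cell border are
included with a per-bin coverage fraction so downstream analyses can
weight or drop them. Cell screening rejects stimuli outside the mask,
within 4 px of the cell edge (Euclidean distance transform), or cells
whose centroid moves > 4 µm from the stimulation-frame centroid at any
later frame. The manual "consistently moving" track curation of the
emulated workflow is replaced by the automatic screens and by explicit
protrusion-consistency rules — a documented deviation. Edge-target
selection uses mathematical angle convention (counter-clockwise from +x,
physical y up), ties broken by larger centroid distance.

## Migration statistics

MSD uses displacement from the track start (single origin) rather than
time-averaged overlapping windows — matching per-cell
displacement-from-start trajectories; cells must move ≥ 5 µm from their
start to be included. The persistence cosine references the first 30 s
step (≥ 5 µm required) and skips zero-length steps rather than emitting
NaN. Means are per lag over cells; SEMs are across experiments, the
independent unit of such assays. Ballistic tracks give
MSD = (v·lag)² and cosine ≡ 1 exactly; Brownian tracks match 4D·lag
within sampling error. The phenotype comparison consumes per-experiment
(positives, totals) counts — tether counting from images is out of
scope — and uses Welch's unequal-variance two-sided t test via
`stats::t.test`, cross-checked in the tests against a direct formula
evaluation.

## Pipeline and reproducibility

`validate_config()` fills defaults, checks ranges, and reports *all*
problems at once; normalization is idempotent. `run_assay()` executes
the stages in a fixed order, writes canonicalized CSVs (12 significant
digits) plus a QC log in which included + excluded = detected per well,
and stages outputs through a temporary directory so partial results are
never left behind. All randomness derives from one seed through a
splittable stream (`derive_seed()`), making scenes, renders, and whole
assay runs bitwise reproducible; per-cell streams are independent of
generation order. Stacks persist as multi-page 16-bit TIFF per channel
plus a JSON sidecar carrying times, stimulus log, ground truth, and the
configuration echo (quantization to 16 bits is the only loss). A thin
command-line wrapper (`inst/exec/optofret`) exposes `simulate` and `run`
over YAML configurations; the exported functions are the primary
interface.

## Problem sizes used in validation

The test suite runs at desk scale: fields of 48–160 px (0.325 µm/px),
4–20 cells, 2–26 frames; 20 random 144² warps for registration
recovery; 79-frame calibration stacks at 128²; 20 random 30×30 masks
against the Dijkstra oracle; 20-cell/50-frame tracking scenes;
4000-track Brownian ensembles; 20 seeded focal-bleach recovery series of
21 frames at 64². These sizes were chosen so each recovery check is
decided by its systematic error rather than sampling noise.

## What the generator does and does not emulate

It emulates: membrane-localized sensor emission in moving, deformable
cells; FRET redistribution with stimulus-driven kinetics and undershoot;
dual-camera misalignment up to second order; vignetting, half-chip step,
dust; dark offset, shot and read noise; a diffusing photobleached pool;
dead cells with low constant ratio and no response. It does not emulate:
real cell morphology (shapes are Fourier-perturbed disks), 3-D optics or
a PSF (TIRF vs epi differ only by background level), mechanistic GTPase
biochemistry, stage drift or autofocus, or cell division/death
dynamics. Passing recovery tests therefore demonstrates correctness of
the analysis chain under the stated image model, not robustness to every
property of real microscopy data.
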