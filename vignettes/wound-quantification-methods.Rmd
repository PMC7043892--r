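---
title: "Quantifying epidermal wound healing from time-lapse fluorescence movies"
author: "wormwound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epidermal wound healing from time-lapse fluorescence movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormwound)
```

# The measurement problem

Laser wounding of the adult *C. elegans* epidermis (the hyp7 syncytium)
triggers a stereotyped repair programme: microtubule plus-end (EB1) comets
reorient and accumulate at the wound within minutes, an actin ring forms and
contracts in two kinetic phases, microtubule bundles adopt an orthoradial
arrangement around the wound, and slower cargo — SNF-12 clusters, RAB-11
recycling endosomes — is recruited over tens of minutes. Each of those
observations rests on a quantification of single-channel spinning-disk or
confocal time-lapse stacks. `wormwound` implements that whole measurement
chain as a reusable, tested pipeline, together with a synthetic-movie
generator that produces the same classes of signal with known ground truth,
so every stage can be validated by parameter recovery rather than by eye.

Conventions: movies are `[y, x, t]` arrays with pixel size (um) and frame
interval (s); pixel coordinates are 1-based with continuous coordinates at
pixel centres; the image x axis is the worm's anterior-posterior (AP) axis;
all physical quantities are um and seconds, converted once at measurement
time.

# The synthetic generator and its presets

The generator emulates the acquisition regimes the pipeline targets, not the
biology underneath them: diffraction-limited moving spots (comets,
vesicles), persistent clusters with run-and-pause motion, a contracting
annulus, and curvilinear filament textures, all rendered on a constant
background with optional low-frequency texture, then degraded by Poisson
photon noise, Gaussian read noise, exponential bleaching and linear stage
drift. Spots are pixel-integrated Gaussians (`sigma` 1 px by default, so the
full spot width is about 3 px, matching the detector's blob diameter);
rendering integrates the Gaussian over each pixel, so the energy of a
rendered object equals its analytic integral to well under 1%.

The named presets encode the reporter dynamics the pipeline is expected to
recover, at the 0.08 um/px calibration of a 100x spinning-disk
configuration:

| preset | regime | speed (um/s) | frame interval |
|---|---|---|---|
| `eb1_unwounded` | EB1 comets, AP-biased | 0.26 (CV 0.38) | 0.3 s |
| `eb1_near_wound` | EB1 comets toward the wound | 0.16 (CV 0.38) | 0.3 s |
| `rab11` | directed vesicle runs | 1.31 (CV 0.25) | 0.4 s |
| `snf12_unwounded` | mostly static clusters, moving minority | 0.017 (CV 0.29) | 0.2 s |
| `snf12_wounded` | clusters converging on the wound | 0.007 (CV 0.57) | 0.2 s |
| `ring_eb1` | two-phase ring closure | v2 = 0.008, v1 = 10 v2 | 1 s |

Speeds are drawn per object from a normal distribution truncated at zero
(the between-object coefficient of variation reproduces the reported
mean +/- SD); each object then moves at its constant speed in a straight
line. Within-track speed variability is not modelled — the source
statistics report only between-track dispersion. The default noise level
(amplitude 52 over a background of 100 counts of Poisson noise plus 3
counts of read noise) gives a spot signal-to-noise ratio close to 5, which
is what a good spinning-disk acquisition of these reporters looks like.
Determinism is strict: (parameters, seed) reproduce a movie bit-exactly,
with child seeds for the noise stage derived from the main seed.

What the generator does *not* emulate: 3-D point-spread functions, cuticle
autofluorescence, the scar texture of a real wound, spatially varying
background, or motion that curves or reverses. Passing the recovery tests
therefore demonstrates that the measurement chain is unbiased under
realistic noise, sampling and crowding — not that it is robust to every
pathology of real data.

## Choices of study conditions

Where the protocols fix numbers, the presets use them: 300/400/200 ms frame
intervals for EB1/RAB-11/SNF-12; the 20 s substack convention and the
5 px / 120 s (pre-wound) or 420 s (post-wound) minimum-displacement filter
for clusters; blob diameter 3 px, linking gate 2 px, gap closing 2 px over
at most 1 missing frame for EB1 tracking; temporal-median window 31 frames;
the 256 um^2 (thresholded) and 18 um^2 (mean) recruitment ROIs with the
mean + 3 SD pre-wound threshold; the 80x80 px actin-ring ROI with Huang
thresholding. Movie geometries (200x200 px, 300 frames for comet presets;
128x128 px, 301 frames for the ring; 140x140 px and 5-8 min for clusters)
are chosen so that a few hundred analysable tracks, or a complete closure
trace, fit in one movie. Two cluster-specific choices matter: the
wound-directed preset spawns movers on an annulus 48-60 px from the wound
so that none reaches the centre within the movie, and the pre-wound movie
is kept to 5 min with a track-length floor equal to the 120 s displacement
window — in a bounded field, any longer visibility requirement selects
against fast movers (they exit sooner) and biases the recovered mean speed
low, a selection effect verified against the generator's ground truth.

# Preprocessing

**Drift correction** estimates pure translation per frame by Fourier
cross-correlation with upsampled-DFT refinement (default grid 1/20 px)
around the integer peak, then resamples bilinearly, filling exposed borders
with the frame median. The raw (not phase-normalized) cross power is used
for the subpixel stage: on movies that were themselves resampled with an
interpolating filter, phase normalization weights the distorted high
frequencies equally and shows biases up to 0.15 px, while the raw
cross-correlation recovers programmed 0.3 px/frame drifts exactly at the
grid resolution. Rotation and scaling are out of scope, as in the
translation stabilizers this step replaces.

**Temporal-median background subtraction** removes, per pixel, the median
over a centred window (default 31 frames) of that pixel's time series. At
the movie ends the window shrinks symmetrically (odd widths 1, 3, 5, ...),
keeping early wound frames usable. The interior uses `stats::runmed`; the
edges use a vectorized sorted-window median, and the whole operation is
checked against an independent per-pixel sort-based oracle. Negative
residuals are clamped to zero by default; the tracking pipeline runs
detection on *unclamped* residuals, because clamping halves the noise
distribution and deflates the robust response threshold (measured: ~25x
more false maxima on clamped residuals).

**Crop/substack** is an exact sub-array copy; a frame stride multiplies the
frame interval (stride 100 on a 0.2 s movie gives the 20 s cluster
substack). The order register -> median-subtract is the default; the
protocols do not fix it.

# Comet detection, linking and speeds

Detection is Laplacian-of-Gaussian filtering at `sigma = d / (2 sqrt 2)`
for blob diameter `d` (default 3 px), followed by 8-neighbour local maxima
above a threshold. Because absolute detector thresholds are
instrument-specific, the default threshold is auto-calibrated as
`median + k * MAD` of the frame's LoG response. `k = 4` is the package
default: the LoG response of a matched-scale spot at SNR 5 peaks near 6.4
response-MADs, so thresholds much above 4-5 MAD cannot detect such spots at
all, while k = 4 costs about one false maximum per frame — harmless
downstream, because false maxima do not survive as multi-frame tracks.
Subpixel positions come from parabolic interpolation of a Gaussian
matched-filter response, which reaches the information-limited localization
precision at these photon counts (about 0.19 px RMS per coordinate at
SNR 5).

Linking solves, per frame pair, an optimal assignment in which candidate
links cost their distance and declining a link costs the gate distance per
spot — the optimum therefore maximizes the number of links and then
minimizes total distance, deterministically and order-independently
(ties broken by spot order). The assignment solver is a shortest
augmenting-path (Jonker-Volgenant style) implementation validated against
brute-force enumeration. Track ends are then joined to later starts across
gaps of at most one missing frame (configurable) within the gap distance,
again by optimal matching on the gated candidate graph, component by
component.

## Speed statistics and the jitter problem

Three per-track speeds are reported. The *mean step speed* (mean over steps
of step length over elapsed time) is the classic particle-tracking
statistic, but under localization noise it is biased upward: each step of
true length `v dt` is measured as `|v dt + noise|`. At the
information-limited 0.19 px jitter this inflation is about +7% for the
unwounded comet regime (0.98 px/frame) and about +20% for the near-wound
regime (0.6 px/frame) — it cannot be removed by averaging. The *net speed*
(net displacement over duration) avoids per-step inflation for directed
motion. The *MSD speed* is the package's recovery estimator: under a
constant-velocity model the lag-1 and lag-2 mean squared displacements are
`v^2 dt^2 + 4 sigma^2` and `4 v^2 dt^2 + 4 sigma^2`, so
`v^2 = (MSD2 - MSD1) / (3 dt^2)` cancels the noise offset exactly. This is
also closer in spirit to how slopes are read off kymograph traces, which is
how the original speed statistics were measured. On synthetic presets the
MSD speed recovers programmed speeds within a few percent where the naive
step mean is off by up to 20%.

Speed summaries use tracks with at least 10 spots: shorter fragments both
carry the largest jitter variance and double-count fast particles, because
gate-induced fragmentation grows with speed. Singletons are excluded
(undefined speed).

The displacement filter keeps tracks whose net displacement between any two
spots separated by at most the window length reaches the threshold — the
"moving particle" definition used for cluster statistics. Wound-referenced
directionality uses the net displacement vector per track, with the axial
angle to the AP axis in [0, 180) (a signed variant is also emitted, since
the original convention is unstated) or the angle to the track-start ->
wound-centre direction in [0, 180].

For the fast regimes the linking gate scales with the expected per-frame
displacement (12 px for 6.6 px/frame vesicles, 6 px for the 4.3 px/substack
clusters); a 2 px gate is geometrically unusable there and belongs to the
EB1 regime it was calibrated for.

# Ring dynamics

The wound centroid is automated as the intensity-weighted centroid of
above-Otsu pixels within a search ROI (manual per-frame centres remain
possible); degenerate frames fall back to the ROI centre. Radial profiles
average intensity in 1 px annular bins; every in-bounds pixel lands in
exactly one bin, so total intensity is conserved, and `r_max` is the bin of
maximum mean intensity with ties taking the smallest radius (flagged as a
plateau). Kymographs average an AP-oriented stripe over its circumferential
extent and normalize each row by its maximum (all-zero rows stay zero).

The two-phase fit is continuous piecewise-linear least squares with one
change point, the breakpoint found by exhaustive search over interior
sample times (excluding the first and last two); closure speeds are the
absolute slopes. Continuity is the minimal assumption consistent with a
radius trace; the fitted SSE never exceeds a single line's. Either the
radial `r_max(t)` trace or kymograph edge positions can be fed to it.

Huang's automatic threshold minimizes the Shannon fuzziness measure over
all 255 boundaries of a 256-bin histogram of the min-max-scaled ROI, with
membership defined by distance to the class mean; ties take the lowest
threshold, and the implementation is checked for exact agreement with a
naive exhaustive oracle. The "area inside the actin ring" is the connected
below-threshold component containing the ROI centre (the ring is bright,
the wound interior dark); the default ROI is an 80x80 px square, reading
the protocol's "ROI of 80 pixels^2" as an 80 px square (configurable).

# Microtubule orientation

The structure tensor is built from Gaussian-derivative gradients
(`sigma_grad` 1 px) averaged under a Gaussian window (`sigma_window` 4 px).
The reported orientation is the axis of least gray-level change — the
eigenvector of the *smaller* eigenvalue. The eigenvector of the largest
eigenvalue points across an intensity ridge, not along it; the convention
here is validated against synthetic filaments of known orientation, and an
`eigen = "large"` flag exists for parity experiments. Coherency is the
normalized eigenvalue contrast; pixels below a coherency cutoff (default
0.2) are excluded from statistics. None of these three defaults is fixed by
the original protocols; they were chosen on synthetic textures and are
fully configurable.

The wound-referenced angle theta folds the axial difference between local
orientation and the pixel->centre direction into [0, 90]: 0 = radial,
90 = orthoradial. Theta is averaged arithmetically over three annuli
R1-R3 — theta is a folded magnitude, not a circular variable, so the
arithmetic mean is the right primary statistic; the axial (doubled-angle)
circular mean of the underlying orientations is reported alongside for
users wanting classical circular statistics. Sector radii default to
1/4/8/12 um and are configurable; the original annuli are not stated
numerically. Before/after comparisons use a two-sample permutation test on
the sector mean (the original toolbox test is unspecified), deterministic
given its seed.

One caveat surfaced by the synthetic tests: sector means of theta on
*random* textures have an effective sample size set by the number of
distinct filaments, not pixels — pixels along one filament share its
angle — so a single field's sector mean scatters by +/-3 degrees even with
10^4 valid pixels. Tests of the uniform-field expectation (mean theta =
45) therefore pool several independently generated fields.

# Recruitment

The thresholded trace sums the raw values of strictly supra-threshold
pixels in the wound ROI, with the threshold set to mean + 3 SD of the ROI
pixels pooled over all pre-wound frames (a flag restricts the baseline to
the last n pre-wound frames; pooling is the default since the original
frame count is unstated). Summing raw supra-threshold values, not
background-subtracted excesses, follows the protocol literally; a constant
offset added to the movie shifts the threshold identically and leaves the
selected pixel set unchanged. The mean-intensity trace is the per-frame ROI
mean. Temporal colour-code projections tint each frame with a hue from a
red-to-blue LUT and take the per-pixel, per-channel maximum; a static
object therefore takes, per channel, the LUT colour maximizing that
channel (documented convention).

# Numerical choices and degenerate inputs

Degenerate cases are handled explicitly: constant frames register with zero
shift and a warning; a constant pre-wound baseline makes the recruitment
threshold equal the mean (flagged), and the strict inequality keeps the
trace at zero; a constant ROI is a degenerate-histogram error for Huang;
all-zero kymograph rows stay zero (0/0 := 0); zero-displacement tracks are
excluded from angle histograms with a reported count; the centre pixel of a
theta map is undefined and masked. Radial `r_max` ties take the smallest
radius, and the argmax considers complete annuli only — bins extending past
the frame edge hold few pixels, and their noisy means otherwise produce
spurious maxima once the ring has nearly closed. Detector thresholds carry a numerical floor so that flat frames
yield no spots. 32-bit TIFF pages are stored as fixed-point values with a
power-of-two scale in a JSON sidecar (exact to one part in 2^32 of full
scale); 8/16-bit integer movies round-trip bit-exactly.

# Problem sizes used in the shipped checks

The test suite runs the recovery experiments at reduced scale — one seed
per preset, 150x150 px comet movies of 150 frames, 400-460 s cluster
movies — and the reproduction script (`scripts/acceptance.R`) at the full
preset scale (200x200 px, 300 frames, 3 seeds for comet/vesicle presets;
5 seeds for the ring; full-length cluster movies). Tolerances are identical
in both; only the statistical width differs.

# Known limitations

Tracking assumes mostly straight, constant-speed motion between frames; the
MSD speed estimator shares that assumption and will underestimate strongly
curved or stop-and-go motion within its lag window. The pipeline is 2-D
throughout: axial drift and out-of-focus loss are not modelled or
corrected. The wound centroid automation assumes the wound region dominates
its search ROI. Orientation mapping degrades on textures near or below the
pixel scale (a 1 px filament downsampled 2x is no longer resolvable), and
sector statistics on sparse textures inherit per-filament correlation as
described above. The generator's noise model is stationary; bleaching is
global, not fluorophore-specific.
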