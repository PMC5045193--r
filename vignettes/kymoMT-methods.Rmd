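---
title: "Quantifying centrosome signal and microtubule dynamics with kymoMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centrosome signal and microtubule dynamics with kymoMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoMT)
```

## The measurement problem

In one-cell *C. elegans* embryos, centrosome size (the amount of
pericentriolar material, PCM) sets the microtubule-nucleating capacity of
the centrosome, and changes in that capacity propagate to the dynamics of
astral microtubules: how many microtubules are born per unit time, how fast
they grow, and how many reach the cell cortex. The standard live-imaging
assay expresses an EB-family plus-end protein fused to GFP (EBP-2::GFP in
worms), so each growing microtubule tip appears as a moving fluorescent
"comet". kymoMT implements the complete quantification toolchain for such
recordings:

* disc-region intensity quantification of centrosomal, centriolar and
  cytoplasmic signal, with per-region focal-plane selection and background
  subtraction;
* kymographs along near-full (355°) or semicircular arcs around the
  centrosome, and along straight lines following single comet tracks;
* comet-event counting at a proximal arc (25 px), a midpoint arc (60 px)
  and a ring offset 1.5 µm inside the cortex;
* polymerization velocity from the slope of a line kymograph;
* thresholded pixel-overlap (Manders-style directional) colocalization;
* group summaries, fold changes, and the pooled-variance two-tailed t-test.

Because real recordings of this kind are rarely deposited, the package
ships a synthetic-embryo generator whose ground truth (every comet's birth
time, direction, velocity and death) is known exactly, so every stage of
the pipeline can be validated by parameter recovery.

## Imaging model and conventions

All geometry uses 1-based (row, col) pixel coordinates with pixel
$(i, j)$ occupying the unit square centered on the integer point $(i, j)$;
fractional region centers are allowed and every distance is computed
between pixel centers. Disc membership is decided by center distance: a
pixel belongs to a disc of diameter $d$ iff its center is within $d/2$ of
the region center. This makes the canonical 25-, 5- and 1-px discs contain
489, 21 and 1 pixels when integer-centered — the region sizes used for
centrosomal, centriolar, and single-pixel measurements.

The default calibration is 0.151 µm/pixel, 500 ms/frame and 61 frames
(a 30-s recording), with intensities on a floating 0–255 working scale.
The 0–255 scale matters only because the comet count threshold (40) is
defined on it; intensity *ratios* are scale-free, and experiments that
need headroom (e.g. three-fold amplitude contrasts) use a 16-bit scale
instead, as EMCCD cameras acquire natively.

Arc sampling uses bilinear interpolation between pixel centers. Nearest-
pixel sampling aliases visibly at the radii used here (25–60 px), which is
why the nearest-pixel sampler exists only as a test oracle. Samples are
placed at uniform angular spacing equivalent to a fixed arc-length step,
starting adjacent to the excluded wedge and proceeding in the direction of
increasing angle; a 355° arc of radius 35 px at a 1-px step yields
$\lfloor 2\pi\,r\,355/360\rfloor = 216$ samples. The 5° excluded wedge
defaults to pointing along $+x$ (toward the right image edge) and is
configurable — published protocols never state its orientation, and none
of the statistics here depend on it.

Two sampling-width conventions coexist deliberately:

* **Linescan profiles** (average signal along the arc, nucleation
  intensity) use a 5-px radial width, matching the wide linescan used for
  intensity profiles.
* **Counting kymographs** use a 3-px band at a 0.5-px arc step. The band
  must be wide enough that a comet moving up to ~3 px/frame cannot jump
  across it between consecutive frames (at 0.88 µm/s and 500 ms the
  per-frame displacement is 2.91 px), and as narrow as that constraint
  allows so that each crossing occupies the fewest possible kymograph
  cells. Counting on wide bands inflates each event's footprint in time
  and merges neighbouring events.

## The synthetic embryo

`simulateComets()` nucleates comets at each centrosome as a homogeneous
Poisson process (rate λ per second per centrosome), draws directions
uniformly in a configurable angular sector, and moves each comet radially
outward at constant speed $v$. A comet dies by per-frame Bernoulli
catastrophe (probability $p_{cat}$ at each frame boundary), on reaching
the elliptical cortex, or at the end of the recording. The per-frame
catastrophe model matches the frame-quantized analysis and keeps survival
probabilities in closed form ($(1-p_{cat})^k$ after $k$ frames).

`renderMovie()` draws each frame as constant background + Gaussian PCM
blobs + one isotropic Gaussian spot per live comet, optionally applies
Poisson resampling (shot noise) and additive Gaussian read noise, clips to
the working scale and rounds to integer counts. Comets are rendered
without tails: the analyses consume point-like plus-end signal only.
`renderIFScene()` renders fixed-cell-like multi-channel z-stacks in which
each blob is brightest at its designated focal plane and attenuated
axially by a Gaussian factor, which is what the focal-plane-selection
logic of `measureRegion()` needs for validation.

Key defaults and their rationale:

| parameter | default | why |
|---|---|---|
| embryo | 50 × 30 µm ellipse | one-cell embryo dimensions |
| pixel size | 0.151 µm | spinning-disk confocal at 60×/1.4 NA |
| frame interval | 500 ms, 61 frames | standard plus-end imaging protocol |
| comet amplitude | 120 | safely above the count threshold 40 |
| comet σ | 0.7 px (~0.11 µm) | diffraction-limited spot (~0.21 λ/NA at 510 nm / 1.4 NA), slightly widened for finite camera sampling |
| PCM blob | amplitude 60, σ 2 px | a resolvable centrosome focus |
| background, read noise | 20, σ 5 | noise floor below threshold 40 |
| wild-type velocity | 0.88 µm/s | astral MT growth rate in one-cell embryos |
| nucleation rate | 1.26 /s | places ~6.3 crossings in a 5-s window at the proximal arc, the wild-type reference count |

Nucleation rates and catastrophe frequencies are not directly observable
in the reference measurements, so the simulator treats them as calibration
choices: λ is set so that the expected number of arc crossings per window
(λ·w for a sector-matched arc with $p_{cat}=0$) equals the reference
count. Seeds are explicit arguments everywhere; no function touches global
random state without restoring it (`withr::with_seed`).

What the generator does **not** emulate: photobleaching, z-drift, comet
tails and shape anisotropy, spatially varying cytoplasmic
autofluorescence, spindle and chromosome signal, and motion other than
straight radial growth. Passing recovery tests on these movies therefore
validates the measurement geometry, the estimators and their calibration
— not robustness to every artifact of real embryos.

## Intensity quantification

`measureRegion()` evaluates the disc mean on every z-plane and reports the
plane with the highest mean, breaking ties toward the lowest plane index.
The plane search is per-region, not per-stack: two centrosomes in the same
embryo may (and often do) sit in different focal planes. Background discs
are placed outside the embryo and, because the protocol leaves the
background plane unstated, default to pairing with the foreground's chosen
plane (overridable). Fold changes divide background-subtracted group means
and are therefore invariant to global additive offsets and to rescaling of
all stacks; per-sample ratios to the control mean provide the dispersion
(reported as their SD, matching how error bars on relative-intensity plots
are conventionally drawn). Per-group aggregation is mean-of-means: each
embryo or centrosome contributes one value.

## Kymograph analyses

`timeProjection()` is a pixel-wise maximum over the frames of a window
(10 frames for the conventional 5-s window). `buildKymograph()` stacks the
per-frame arc (or line) profiles into a time × position image.
`linescanProfile()` averages it over time.

**Nucleation intensity** is the mean of a 5-px-wide semicircular linescan
(radius 25 px) on the 5-s maximum projection, minus the same statistic for
an identically shaped semicircle in the cytoplasm. Because the projection
is a maximum, the statistic is linear in the nucleation rate only while
comet tracks rarely overlap; at the default rates the occupancy of the
projection near the arc is below ~10 % and a two-fold rate contrast is
recovered as a 1.8–2.1-fold intensity contrast.

**Comet counting.** `countCometEvents()` reports three statistics of the
suprathreshold (> 40) kymograph mask: the raw pixel count, the number of
8-connected components, and the number of *events* — local intensity
maxima above threshold with a minimum separation (1 kymograph cell by
default). At wild-type densities (~6 crossings per 5-s semicircular
kymograph) components and events agree. At several-fold higher densities,
crossings land within one frame and ~2 px of each other often enough that
connected components systematically merge: with ~29 crossings on a
5 s × 78 px kymograph and ~0.8 s × 2 px event footprints, component
counting loses 25–30 % of events, an undercount that is geometric and
cannot be removed by resolution alone. Peak-resolved events lose only the
pairs closer than the peak-separation limit (~5–10 % at that density) and
are also invariant to the rendering scale, which the pixel count is not.
The event count is therefore the headline "number of growing
microtubules"; components and pixels remain available for comparison with
component-based or pixel-based conventions.

**Counting windows.** For simulations the proximal count uses a
steady-state window: counting starts one frame after $r/v$ (the time the
first comets need to reach the arc), so that the crossing flux has reached
its stationary rate λ per second. For real recordings the convention is
the first 5 s of the recording, which assumes comets are already
streaming when acquisition starts.

**Cortex crossings.** `countCortexCrossings()` samples a kymograph along
the contour offset 10 px (1.5 µm) inside the cortex polygon and counts
events as local maxima with a 2-cell minimum separation — an automated
stand-in for the manual dot counting used at the cortex, and the same
estimator the proximal count uses.

**Velocity.** `polymerizationRate()` builds the kymograph of a 4.5-µm
line drawn along a single comet track, estimates the comet position in
each time row as the intensity-weighted centroid of suprathreshold
samples (sub-pixel accuracy; a peak-pixel estimator is biased toward the
grid), and fits position against time by least squares. Two guards keep
the fit on the comet: rows whose suprathreshold run touches either end of
the line are dropped (the spot is partially outside the line, which
biases the centroid), and the track is taken as the longest consecutive
run of comet-present rows, which rejects isolated noise-triggered rows
before or after the transit. On noise-free renders the estimator is
accurate to well under 1 %; across a 0.3–1.2 µm/s sweep under default
noise it recovers velocities within 5 %.

## Colocalization

`coincidenceFraction()` implements thresholded pixel-overlap
colocalization in cytoplasmic discs (60 px diameter by convention):
within each disc, the suprathreshold masks $M_1, M_2$ give the
directional overlaps $100\,|M_1 \cap M_2|/|M_i|$. The per-wavelength
denominator follows the convention of reporting "percentage of
overlapping pixels from each wavelength"; both directions are always
returned, along with values pooled over the union of regions (reported
alongside per-region values because published figures do not always say
which was used). Thresholds are explicit; when unstated they default to
the 0.95 within-region quantile and the choice is logged.

## Statistics

`twoSampleT()` is the two-sample, two-tailed, equal-variance Student
t-test (pooled SD, $n_1+n_2-2$ df), delegated to `stats::t.test()` and
cross-checked in the test suite against the pooled-variance formula to
$10^{-10}$. No multiple-testing correction is applied, matching the
reporting conventions of the assays. `summarizeGroups()` reports n, mean,
SD, SEM and fold versus a named control with deterministic ordering.

## Numerical choices and degenerate inputs

* Bilinear samples outside the frame are NA and flagged (`oob`); region
  means use in-frame pixels only and set a `clipped` flag.
* Focal-plane ties break toward the lowest z index (deterministic).
* A disc entirely outside the image is an empty mask with a warning; a
  measurement on it is an error.
* Zero pooled variance, missing control groups, empty regions, degenerate
  polygons and sub-3-row velocity tracks are errors, not NaNs.
* TIFF round trips are bit-exact for integer stacks on the 0–255 scale
  (8-bit storage) and float32-accurate otherwise; stack metadata travels
  in a JSON sidecar because baseline TIFF tags cannot carry it portably.
* Connected-component labelling is 8-connected (implemented in the
  package; the common 4-connected labelling merges nothing across
  diagonals and is not what crossing blobs need).

## Problem sizes used by the packaged benchmarks

The packaged experiments (`proximalCountExperiment()`,
`velocityBenchmark()`, `amplitudeFoldExperiment()`,
`nucleationFoldExperiment()`) use 17–21 movies for count recovery and 20
paired movies per fold-change contrast, each movie 61 frames of a
199 × 331-px field — enough for the stochastic means to sit well inside
their tolerance bands while a full run stays in the minutes range on a
single core. The property-style tests run on 128 × 128 fields where the
full embryo is not needed.

## Known limitations

* Event counting resolves crossings down to the peak-separation limit
  (~1 px along the arc, one frame in time); genuinely coincident
  crossings are counted once. The component count is reported so the
  merging regime is visible in the output.
* The nucleation-intensity statistic saturates with rate (maximum
  projection); fold changes above ~3 under-recover noticeably.
* No particle linking across frames is attempted: velocities come from a
  user-drawn line along one track, as in the manual protocol.
* Automatic centrosome detection is out of scope; centrosome and region
  placement are inputs.
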