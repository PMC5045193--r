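# kymoMT

Quantification of centrosome-associated fluorescence and microtubule (MT)
plus-end dynamics in one-cell embryo time-lapse recordings, with a
synthetic-embryo movie generator that provides exact ground truth for
every measurement stage.

## The problem

Centrosome size — the amount of pericentriolar material (PCM: SPD-5,
SPD-2, γ-tubulin and friends) — sets how many microtubules a centrosome
nucleates, and that in turn shapes MT growth and cortical contact in the
early *C. elegans* embryo. The standard live assay images an EB-family
plus-end protein fused to GFP, so each growing MT tip is a moving
fluorescent "comet". Quantifying such recordings requires a small zoo of
bespoke measurements that are usually done by hand in imaging software;
kymoMT implements them as tested, scriptable functions:

* **Disc-region intensity quantification** — the mean intensity of a
  25-px-diameter disc centered on the centrosome (5 px for centrioles),
  evaluated on every focal plane and reported at the plane where it is
  maximal, minus a same-size background disc outside the embryo. Group
  contrasts are reported as fold changes of background-subtracted means.
* **Arc kymographs** — the movie resampled along a 355° circle (or a
  semicircle) around the centrosome, one row per frame: position × time
  images in which each crossing MT appears as a bright blob.
* **Comet counting** — suprathreshold (> 40 on a 0–255 scale) structure
  of the kymograph at a proximal arc (25 px), a midpoint arc (60 px) and
  a ring 1.5 µm (10 px) inside the cortex, reported as pixels, 8-connected
  components, and peak-resolved crossing events.
* **Polymerization velocity** — a 4.5-µm line drawn along one comet
  track; the velocity is the least-squares slope of the per-frame
  intensity-weighted centroid position, in µm/s.
* **Thresholded colocalization** — Manders-style directional overlap of
  suprathreshold pixels between two channels inside 60-px cytoplasmic
  discs.
* **Statistics** — per-group n/mean/SD/SEM, fold versus control, and the
  two-tailed equal-variance Student t-test.

Because recordings of this kind are rarely deposited, the package also
simulates them: comets nucleate at centrosomes as a Poisson process (rate
λ per second), travel radially at constant speed v (0.88 µm/s wild-type
reference), and die by per-frame catastrophe or at the elliptical cortex;
movies are rendered as Gaussian spots over background with Poisson and
Gaussian noise at the standard calibration (0.151 µm/px, 500 ms/frame,
61 frames). Every simulated movie carries its ground truth, so the
pipeline's accuracy is measured by parameter recovery.

## Worked example

Simulate a wild-type-like movie, build the proximal-arc kymograph over a
steady-state 5-s window, and count growing MTs:

```r
library(kymoMT)

cfg  <- imagingConfig()                       # 0.151 um/px, 500 ms, 61 frames
geom <- embryoGeometry(config = cfg)          # 50 x 30 um ellipse, 1 centrosome
par  <- cometSimParams(nucleationRatePerS = 1.26, velocityUmPerS = 0.88,
                       angularSectorDeg = 180, sectorCenterDeg = 90)
tr   <- simulateComets(par, geom, durationS = 30, config = cfg, seed = 7)
tr
#> CometTrackSet: 51 comets over 30.0 s (seed 7)
#>   velocity 0.88 um/s, nucleation 1.26 /s, catastrophe 0 /frame

mov <- renderMovie(tr, renderModel(), cfg, geom, seed = 7)
ctr <- centrosomes(geom)[1, ]
arc <- semicircleRegion(ctr, radiusPx = 25, facingDeg = 90, widthPx = 3)
kym <- buildKymograph(mov$stack, arc, window = c(5, 10), step = 0.5)
countCometEvents(kym, threshold = 40)
#> proximal comet count over [5.0, 10.0) s: 11 events (9 components, 45 px > 40)

expectedArcCrossings(tr, ctr, 25, c(5, 10), cfg, spanDeg = 180,
                     gapCenterDeg = 270)      # ground truth
#> [1] 10
```

Eleven detected events against ten true crossings: at this density the
peak-resolved event count tracks the ground truth closely (components
already merge two crossings here — see the methods vignette for why both
are reported). Velocity recovery from a noise-free comet advancing
2.914 px/frame:

```r
est <- velocityBenchmark(2.914)
est$velocityUmPerS
#> [1] 0.8756756
```

i.e. 0.876 µm/s against a true 0.880 µm/s. The vignette
(`vignettes/kymoMT-methods.Rmd`) documents the measurement model, the
simulator's assumptions, and every numerical convention.

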