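#' Packaged synthetic benchmark experiments
#'
#' These functions reproduce the package's reference experiments on
#' synthetic embryos: comet-count recovery at the proximal arc, velocity
#' recovery from single-comet renders, and fold-change recovery for
#' amplitude and nucleation-rate contrasts. They are what
#' \code{scripts/acceptance.R} and the acceptance test suite run.
#'
#' @name benchmarks
NULL

#' @describeIn benchmarks Mean comet-event count per 5-s kymograph at the
#'   proximal semicircular arc (radius 25 px) over `nMovies` synthetic
#'   movies with Poisson nucleation `ratePerS` into the semicircle facing
#'   the arc, velocity 0.88 um/s, no catastrophe, default render, counted
#'   over a steady-state 5-s window at threshold 40. Returns a list with
#'   the per-movie event counts, their mean, and the ground-truth crossing
#'   counts.
#' @param ratePerS Poisson nucleation rate per second.
#' @param nMovies number of movies (one seed each).
#' @param baseSeed integer; movie i uses seed \code{baseSeed * 1000 + i}.
#' @param radiusPx counting arc radius.
#' @param windowS counting window length, seconds.
#' @export
proximalCountExperiment <- function(ratePerS, nMovies, baseSeed = 1L,
                                    radiusPx = 25, windowS = 5) {
  cfg <- imagingConfig()
  geom <- embryoGeometry(config = cfg)
  ctr <- centrosomes(geom)[1, ]
  facing <- 90
  par <- cometSimParams(ratePerS, 0.88, angularSectorDeg = 180,
                        sectorCenterDeg = facing)
  arc <- semicircleRegion(ctr, radiusPx, facing, widthPx = 3)
  vpx <- 0.88 / pixelSize(cfg)
  w0 <- ceiling((radiusPx / vpx) / frameInterval(cfg) + 1) * frameInterval(cfg)
  window <- c(w0, w0 + windowS)
  counts <- numeric(nMovies)
  truth <- numeric(nMovies)
  for (i in seq_len(nMovies)) {
    seed <- baseSeed * 1000L + i
    tr <- simulateComets(par, geom, nFrames(cfg) * frameInterval(cfg), cfg,
                         seed = seed)
    mov <- renderMovie(tr, renderModel(), cfg, geom, seed = seed)
    k <- buildKymograph(mov$stack, arc, window = window, step = 0.5)
    counts[i] <- countCometEvents(k, threshold = 40)$nEvents
    truth[i] <- expectedArcCrossings(tr, ctr, radiusPx, window, cfg,
                                     spanDeg = 180, gapCenterDeg = facing + 180)
  }
  list(counts = counts, mean = mean(counts), truth = truth,
       truthMean = mean(truth), window = window, n = nMovies)
}

#' @describeIn benchmarks Velocity recovered by the 4.5-um kymograph-slope
#'   procedure on a noise-free single comet advancing `pxPerFrame` pixels
#'   per frame radially outward. Returns the velocity estimate list of
#'   [polymerizationRate()] plus the true velocity in um/s.
#' @param pxPerFrame radial displacement per frame, pixels.
#' @export
velocityBenchmark <- function(pxPerFrame) {
  cfg <- imagingConfig()
  v <- pxPerFrame * pixelSize(cfg) / frameInterval(cfg)
  ctr <- (as.numeric(imageShape(cfg)) + 1) / 2
  tr <- new("CometTrackSet",
            tracks = data.frame(id = 1L, centrosome = 1L, birthS = 0,
                                originRow = ctr[1], originCol = ctr[2] + 5,
                                directionDeg = 0, velocityUmPerS = v,
                                deathS = nFrames(cfg) * frameInterval(cfg)),
            params = cometSimParams(velocityUmPerS = v), seed = 1L,
            durationS = nFrames(cfg) * frameInterval(cfg))
  mdl <- renderModel(gaussianNoiseSigma = 0, poissonNoise = FALSE,
                     quantize = FALSE, pcmAmplitude = 0)
  mov <- renderMovie(tr, mdl, cfg, seed = 1L)
  L <- umToPx(4.5, cfg)
  line <- lineRegion(c(ctr[1], ctr[2] + 8), c(ctr[1], ctr[2] + 8 + L),
                     widthPx = 1)
  est <- polymerizationRate(mov$stack, line)
  est$trueUmPerS <- v
  est
}

#' @describeIn benchmarks Fold change of background-subtracted 25-px disc
#'   means between paired movie sets rendered with `amplitudeRatio`-times
#'   the comet and PCM amplitudes: each pair shares its simulated comet
#'   tracks and differs only in the generative amplitudes and in the
#'   (independent) acquisition noise. Run on a 16-bit working scale so the
#'   raised amplitudes stay within range. Returns a \code{"foldChange"}.
#' @param amplitudeRatio generative amplitude ratio (mutant / control).
#' @param nSeeds paired movies per group.
#' @export
amplitudeFoldExperiment <- function(amplitudeRatio = 3, nSeeds = 20,
                                    baseSeed = 1L) {
  cfg <- imagingConfig(bitScale = 65535)
  geom <- embryoGeometry(config = cfg)
  ctr <- centrosomes(geom)[1, ]
  bgc <- c(12, 12)
  one <- function(simSeed, noiseSeed, mult) {
    par <- cometSimParams(1.26, 0.88)
    tr <- simulateComets(par, geom, 30, cfg, seed = simSeed)
    mdl <- renderModel(cometAmplitude = 120 * mult, pcmAmplitude = 60 * mult)
    mov <- renderMovie(tr, mdl, cfg, geom, seed = noiseSeed)
    sig <- measureRegion(mov$stack, discRegion(ctr, 25))$mean
    bg <- measureRegion(mov$stack, discRegion(bgc, 25),
                        compartment = "background")$mean
    sig - bg
  }
  seeds <- baseSeed * 1000L + seq_len(nSeeds)
  ctrl <- vapply(seeds, function(s) one(s, s + 500L, 1), numeric(1))
  mut <- vapply(seeds, function(s) one(s, s + 700L, amplitudeRatio),
                numeric(1))
  foldChange(mut, ctrl)
}

## merge two track sets (Poisson superposition: the union of independent
## Poisson processes at rates a and b is a Poisson process at a + b)
.mergeTracks <- function(a, b) {
  tr <- rbind(tracks(a), tracks(b))
  if (nrow(tr)) tr$id <- seq_len(nrow(tr))
  new("CometTrackSet", tracks = tr, params = a@params, seed = a@seed,
      durationS = a@durationS)
}

#' @describeIn benchmarks Fold change of the semicircular nucleation-
#'   intensity statistic between paired movie sets simulated at
#'   `rateRatio`-times the base nucleation rate. Pairing uses Poisson
#'   superposition: the higher-rate member of each pair reuses the
#'   control's comets and adds an independent set at rate
#'   \code{(rateRatio - 1) * baseRatePerS}, which is distributionally a
#'   Poisson process at the full mutant rate while sharing the pair's
#'   birth-history noise. Returns a \code{"foldChange"}.
#' @param rateRatio nucleation-rate ratio (mutant / control; >= 1).
#' @param baseRatePerS control nucleation rate.
#' @export
nucleationFoldExperiment <- function(rateRatio = 2, baseRatePerS = 1.26,
                                     nSeeds = 20, baseSeed = 1L) {
  if (rateRatio < 1) stop("rateRatio must be >= 1 (swap the groups instead)")
  cfg <- imagingConfig()
  geom <- embryoGeometry(config = cfg)
  ctr <- centrosomes(geom)[1, ]
  measure <- function(tr, noiseSeed) {
    mov <- renderMovie(tr, renderModel(), cfg, geom, seed = noiseSeed)
    nucleationIntensity(mov$stack, ctr, c(ctr[1], ctr[2] - 65),
                        window = c(5, 10))$net
  }
  seeds <- baseSeed * 1000L + seq_len(nSeeds)
  ctrl <- numeric(nSeeds)
  mut <- numeric(nSeeds)
  for (i in seq_len(nSeeds)) {
    trBase <- simulateComets(cometSimParams(baseRatePerS, 0.88), geom, 30,
                             cfg, seed = seeds[i])
    ctrl[i] <- measure(trBase, seeds[i] + 900L)
    trMut <- if (rateRatio > 1) {
      extra <- simulateComets(
        cometSimParams(baseRatePerS * (rateRatio - 1), 0.88), geom, 30,
        cfg, seed = seeds[i] + 300L)
      .mergeTracks(trBase, extra)
    } else trBase
    mut[i] <- measure(trMut, seeds[i] + 1100L)
  }
  foldChange(mut, ctrl)
}
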