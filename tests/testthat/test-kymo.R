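# one comet launched straight at the proximal arc, small field
oneCometMovie <- function(v = 0.88, dirDeg = 0, birth = 0, model = cleanModel(),
                          cfg = smallConfig(), seed = 1) {
  ctr <- c(64.5, 64.5)
  tr <- manualTracks(data.frame(originRow = ctr[1] + 2 * sin(dirDeg * pi / 180),
                                originCol = ctr[2] + 2 * cos(dirDeg * pi / 180),
                                directionDeg = dirDeg, birthS = birth),
                     v = v)
  list(mov = renderMovie(tr, model, cfg, seed = seed), ctr = ctr, tr = tr)
}

test_that("time projections are pixel-wise maxima over the window", {
  cfg <- smallConfig(nFrames = 12L)
  arr <- array(0, dim = c(12, 1, 1, 128, 128))
  for (t in 1:12) arr[t, 1, 1, , ] <- t
  s <- new("ImageStack", data = arr, config = cfg, channelNames = "ch1")
  proj <- timeProjection(s, window = c(0, 5))   # frames 1..10
  expect_true(all(proj == 10))
  # static image repeated -> projection equals that image
  withr::local_seed(3)
  img <- matrix(sample(0:255, 128 * 128, TRUE), 128, 128)
  for (t in 1:12) arr[t, 1, 1, , ] <- img
  s2 <- new("ImageStack", data = arr, config = cfg, channelNames = "ch1")
  expect_equal(timeProjection(s2, c(0, 5)), img)
  # projection dominates every frame
  o <- oneCometMovie(model = renderModel())
  proj3 <- timeProjection(o$mov$stack, c(0, 5))
  for (t in 1:10)
    expect_true(all(proj3 >= getFrame(o$mov$stack, t = t)))
})

test_that("a moving comet leaves a line of suprathreshold loci in the projection", {
  o <- oneCometMovie()
  proj <- timeProjection(o$mov$stack, c(0, 5))
  # one locus per frame at ~2.9 px/frame spacing along the trajectory row
  hits <- which(proj[65, ] > 40 | proj[64, ] > 40)
  expect_gte(diff(range(hits)), 9 * 2.9)
})

test_that("kymographs have the closed-form column count and are constant on uniform movies", {
  cfg <- smallConfig(nFrames = 12L)
  arr <- array(33, dim = c(12, 1, 1, 128, 128))
  s <- new("ImageStack", data = arr, config = cfg, channelNames = "ch1")
  reg <- arcRegion(c(64, 64), 35, spanDeg = 355, widthPx = 5)
  k <- buildKymograph(s, reg, window = c(0, 5), step = 1)
  expect_equal(dim(kymoData(k)), c(10L, 216L))
  expect_true(all(abs(kymoData(k) - 33) < 1e-9))
  prof <- linescanProfile(k)
  expect_true(all(abs(prof$mean - 33) < 1e-9))
})

test_that("a comet crossing the arc appears in the expected kymograph row", {
  v <- 0.88
  o <- oneCometMovie(v = v, dirDeg = 90)
  reg <- semicircleRegion(o$ctr, 25, facingDeg = 90, widthPx = 3)
  k <- buildKymograph(o$mov$stack, reg, window = c(0, 5), step = 0.5)
  # crossing time = (radius - birth radius) / v_px, quantized to frames
  vpx <- v / 0.151
  tCross <- (25 - 2) / vpx
  rowExp <- floor(tCross / 0.5) + 1
  hot <- which(kymoData(k) > 40, arr.ind = TRUE)
  expect_true(all(abs(hot[, 1] - rowExp) <= 1))
  expect_gt(nrow(hot), 0)
})

test_that("kymograph construction commutes with time cropping", {
  par <- cometSimParams(2, 0.88)
  cfg <- smallConfig(nFrames = 20L)
  tr <- simulateComets(par, NULL, 10, cfg, seed = 21)
  mov <- renderMovie(tr, renderModel(), cfg, seed = 21)
  reg <- semicircleRegion(c(64.5, 64.5), 25, 90, widthPx = 3)
  whole <- buildKymograph(mov$stack, reg, window = c(2, 7), step = 1)
  # crop the stack to frames 5..14 (times 2..6.5) and rebuild from t' = 0
  cropped <- stackData(mov$stack)[5:14, , , , , drop = FALSE]
  cfg2 <- smallConfig(nFrames = 10L)
  s2 <- new("ImageStack", data = cropped, config = cfg2, channelNames = "ch1")
  part <- buildKymograph(s2, reg, window = c(0, 5), step = 1)
  expect_equal(kymoData(part), kymoData(whole))
})

test_that("linescan profiles localize single crossings and scale with comet rate", {
  o <- oneCometMovie(dirDeg = 90)
  reg <- semicircleRegion(o$ctr, 25, 90, widthPx = 5)
  k <- buildKymograph(o$mov$stack, reg, window = c(0, 5), step = 1)
  prof <- linescanProfile(k)
  above <- which(prof$mean > 20 + 3)
  expect_gt(length(above), 0)
  expect_lt(diff(range(above)), 12)  # one localized bump
  # doubling the rate doubles the mean net profile level (superposition)
  cfg <- smallConfig()
  runLevel <- function(lam, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulateComets(cometSimParams(lam, 0.88), NULL, 30, cfg, seed = s)
      mov <- renderMovie(tr, cleanModel(cometAmplitude = 60), cfg, seed = s)
      kk <- buildKymograph(mov$stack, reg, window = c(10, 15), step = 1)
      mean(linescanProfile(kk)$mean) - 20
    }, numeric(1)))
  }
  l1 <- runLevel(2, 1:30)
  l2 <- runLevel(4, 31:60)
  expect_lt(abs(l2 / l1 - 2), 0.25)
})

test_that("comet event counting matches constructed fixtures and the labeling oracle", {
  # all-background kymograph: nothing above threshold
  cfg <- smallConfig(nFrames = 12L)
  arr <- array(20, dim = c(12, 1, 1, 128, 128))
  s <- new("ImageStack", data = arr, config = cfg, channelNames = "ch1")
  reg <- semicircleRegion(c(64, 64), 25, 90, widthPx = 3)
  k0 <- buildKymograph(s, reg, window = c(0, 5), step = 0.5)
  c0 <- countCometEvents(k0)
  expect_equal(c0$nPixels, 0)
  expect_equal(c0$nComponents, 0)
  expect_equal(c0$nEvents, 0)
  # one clean crossing -> exactly one event and one component
  o <- oneCometMovie(dirDeg = 90)
  k1 <- buildKymograph(o$mov$stack, reg, window = c(0, 5), step = 0.5)
  c1 <- countCometEvents(k1)
  expect_equal(c1$nEvents, 1)
  expect_equal(c1$nComponents, 1)
  expect_gte(c1$nPixels, c1$nEvents)
  # k well-separated crossings -> k events; components equal the oracle
  ctr <- c(64.5, 64.5)
  angs <- c(20, 65, 110, 155)
  tr <- manualTracks(data.frame(
    originRow = ctr[1] + 2 * sin(angs * pi / 180),
    originCol = ctr[2] + 2 * cos(angs * pi / 180),
    directionDeg = angs, birthS = c(0, 1, 2, 3)), v = 0.88)
  mov <- renderMovie(tr, cleanModel(), smallConfig(), seed = 2)
  kk <- buildKymograph(mov$stack, reg, window = c(0, 8), step = 0.5)
  ck <- countCometEvents(kk)
  expect_equal(ck$nEvents, 4)
  expect_equal(ck$nComponents, bruteLabel8(kymoData(kk) > 40))
})

test_that("crossing counts are conserved at steady state (50 seeds, full circle)", {
  cfg <- smallConfig()
  lam <- 1.26
  reg <- arcRegion(c(64.5, 64.5), 25, spanDeg = 360, widthPx = 3)
  counts <- vapply(1:50, function(s) {
    tr <- simulateComets(cometSimParams(lam, 0.88), NULL, 30, cfg, seed = s)
    mov <- renderMovie(tr, renderModel(), cfg, seed = s)
    k <- buildKymograph(mov$stack, reg, window = c(10, 15), step = 0.5)
    countCometEvents(k)$nEvents
  }, numeric(1))
  expected <- lam * 5
  se <- sqrt(expected / 50)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("counts fall with radius under catastrophe (arc-length normalized)", {
  cfg <- imagingConfig()
  geom <- embryoGeometry(config = cfg)
  ctr <- centrosomes(geom)[1, ]
  par <- cometSimParams(2.5, 0.88, catastrophePerFrame = 0.08,
                        angularSectorDeg = 180, sectorCenterDeg = 90)
  prox <- semicircleRegion(ctr, 25, 90, widthPx = 3)
  mid <- semicircleRegion(ctr, 60, 90, widthPx = 3)
  res <- vapply(1:15, function(s) {
    tr <- simulateComets(par, geom, 30, cfg, seed = s)
    mov <- renderMovie(tr, renderModel(), cfg, geom, seed = s)
    kP <- buildKymograph(mov$stack, prox, window = c(10, 15), step = 0.5)
    kM <- buildKymograph(mov$stack, mid, window = c(10, 15), step = 0.5)
    cx <- countCortexCrossings(mov$stack, geom, window = c(10, 15))
    c(countCometEvents(kP)$nEvents / (pi * 25),
      countCometEvents(kM)$nEvents / (pi * 60),
      cx$nEvents / (2 * pi * sqrt((25 / 0.151) * (15 / 0.151))))
  }, numeric(3))
  m <- rowMeans(res)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})

test_that("cortex crossing counts see radial comets exactly once and drop with catastrophe", {
  cfg <- imagingConfig()
  geom <- embryoGeometry(config = cfg)
  ctr <- centrosomes(geom)[1, ]
  # a single comet aimed at the cortex with no catastrophe crosses once
  tr1 <- manualTracks(data.frame(originRow = ctr[1], originCol = ctr[2] + 2,
                                 directionDeg = 0), v = 0.88)
  mov1 <- renderMovie(tr1, cleanModel(), cfg, geom, seed = 1)
  c1 <- countCortexCrossings(mov1$stack, geom, window = c(0, 30))
  expect_equal(c1$nEvents, 1)
  # heavy catastrophe: nothing reaches the cortex
  parHi <- cometSimParams(2, 0.88, catastrophePerFrame = 0.5)
  trHi <- simulateComets(parHi, geom, 15, imagingConfig(nFrames = 31L),
                         seed = 2)
  movHi <- renderMovie(trHi, renderModel(), imagingConfig(nFrames = 31L),
                       geom, seed = 2)
  cHi <- countCortexCrossings(movHi$stack, geom, window = c(5, 10))
  expect_equal(cHi$nEvents, 0)
  # mean counts are monotone nonincreasing in the catastrophe rate
  meanCount <- function(pcat, seeds) {
    mean(vapply(seeds, function(s) {
      par <- cometSimParams(2, 0.88, catastrophePerFrame = pcat)
      tr <- simulateComets(par, geom, 20, imagingConfig(nFrames = 41L), seed = s)
      mov <- renderMovie(tr, renderModel(), imagingConfig(nFrames = 41L),
                         geom, seed = s)
      countCortexCrossings(mov$stack, geom, window = c(12, 17))$nEvents
    }, numeric(1)))
  }
  m0 <- meanCount(0, 1:8)
  m1 <- meanCount(0.05, 1:8)
  m2 <- meanCount(0.15, 1:8)
  expect_gte(m0, m1)
  expect_gte(m1, m2)
})

test_that("nucleation intensity vanishes without comets and respects isotropy", {
  cfg <- smallConfig()
  empty <- manualTracks(data.frame(originRow = numeric(), originCol = numeric(),
                                   directionDeg = numeric()))
  mov <- renderMovie(empty, cleanModel(), cfg, seed = 1)
  nuc <- nucleationIntensity(mov$stack, c(64.5, 64.5), c(30, 30),
                             window = c(0, 5))
  expect_equal(nuc$net, 0, tolerance = 1e-9)
  expect_error(nucleationIntensity(mov$stack, c(64.5, 64.5), NULL),
               "background")
  # reversing the semicircle on an isotropic simulation moves the statistic
  # by less than 2 SE of the seed-to-seed spread
  run <- function(facing, seeds) {
    vapply(seeds, function(s) {
      tr <- simulateComets(cometSimParams(1.26, 0.88), NULL, 30, cfg, seed = s)
      m <- renderMovie(tr, renderModel(), cfg, seed = s)
      nucleationIntensity(m$stack, c(64.5, 64.5), c(20, 20),
                          facingDeg = facing, window = c(10, 15))$net
    }, numeric(1))
  }
  up <- run(90, 1:15)
  down <- run(270, 1:15)
  seDiff <- sqrt(var(up) / 15 + var(down) / 15)
  expect_lt(abs(mean(up) - mean(down)), 2.5 * seDiff)
})

test_that("nucleation intensity doubles when the nucleation rate doubles", {
  cfg <- smallConfig()
  run <- function(lam, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulateComets(cometSimParams(lam, 0.88), NULL, 30, cfg, seed = s)
      m <- renderMovie(tr, renderModel(), cfg, seed = s)
      nucleationIntensity(m$stack, c(64.5, 64.5), c(20, 20),
                          window = c(10, 15))$net
    }, numeric(1)))
  }
  lo <- run(0.63, 1:30)
  hi <- run(1.26, 31:60)
  expect_lt(abs(hi / lo - 2), 0.3)
})

test_that("polymerization rate recovers known velocities and rejects short tracks", {
  cfg <- smallConfig()
  ctr <- c(64.5, 64.5)
  L <- 4.5 / 0.151
  line <- lineRegion(c(ctr[1], ctr[2] + 8), c(ctr[1], ctr[2] + 8 + L),
                     widthPx = 1)
  mk <- function(v, model = cleanModel(), seed = 1) {
    tr <- manualTracks(data.frame(originRow = ctr[1], originCol = ctr[2] + 5,
                                  directionDeg = 0), v = v)
    renderMovie(tr, model, cfg, seed = seed)$stack
  }
  # stated per-frame displacements map to 0.88 and 0.70 um/s
  for (ppf in c(2.914, 2.318)) {
    v <- ppf * 0.151 / 0.5
    est <- polymerizationRate(mk(v), line)
    expect_lt(abs(est$velocityUmPerS - v), 0.02)
    expect_gte(est$nTimePoints, 3)
  }
  # stationary bright spot -> ~0 um/s
  stat <- mk(1e-4)
  lineS <- lineRegion(c(ctr[1], ctr[2]), c(ctr[1], ctr[2] + L), widthPx = 1)
  expect_lt(polymerizationRate(stat, lineS)$velocityUmPerS, 0.01)
  # velocity sweep 0.3-1.2 um/s with default noise: within 5% everywhere
  for (v in c(0.3, 0.6, 0.88, 1.2)) {
    est <- polymerizationRate(mk(v, renderModel(pcmAmplitude = 0), seed = 7),
                              line)
    expect_lt(abs(est$velocityUmPerS - v) / v, 0.05)
  }
  # unbiased across sub-pixel phase offsets (noise-free)
  for (phase in c(0, 0.25, 0.5, 0.75)) {
    tr <- manualTracks(data.frame(originRow = ctr[1],
                                  originCol = ctr[2] + 5 + phase,
                                  directionDeg = 0), v = 0.88)
    st <- renderMovie(tr, cleanModel(), cfg, seed = 1)$stack
    est <- polymerizationRate(st, line)
    expect_lt(abs(est$velocityUmPerS - 0.88) / 0.88, 0.02)
  }
  # a comet visible in under 3 rows is refused
  short <- manualTracks(data.frame(originRow = ctr[1], originCol = ctr[2] + 5,
                                   directionDeg = 0, deathS = 0.6), v = 0.88)
  stShort <- renderMovie(short, cleanModel(), cfg, seed = 1)$stack
  expect_error(polymerizationRate(stShort, line), "fewer than 3")
  expect_warning(
    polymerizationRate(mk(0.88),
                       lineRegion(c(ctr[1], ctr[2] + 8), c(ctr[1], ctr[2] + 48))),
    "4.5")
})
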