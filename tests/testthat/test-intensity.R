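test_that("disc means match the brute-force mask average and pick the right plane", {
  cfg <- smallConfig(nFrames = 1L, shape = c(96L, 96L))
  scene <- data.frame(row = 48.3, col = 47.6, channel = 1, amplitude = 150,
                      sigmaPx = 3, focalPlane = 3)
  out <- renderIFScene(scene, cleanModel(), cfg, nZ = 5, seed = 1)
  disc <- discRegion(c(48.3, 47.6), 25)
  m <- measureRegion(out$stack, disc)
  expect_equal(m$plane, 3)
  # brute-force oracle over the 489-pixel mask
  mask <- maskPixels(c(96L, 96L), disc)
  expect_equal(sum(mask), bruteDiscCount(c(96L, 96L), c(48.3, 47.6), 25))
  expect_equal(m$mean, mean(getFrame(out$stack, z = 3)[mask]),
               tolerance = 1e-9)
})

test_that("uniform stacks tie-break to the lowest plane", {
  arr <- array(37, dim = c(1, 4, 1, 32, 32))
  s <- new("ImageStack", data = arr,
           config = smallConfig(nFrames = 1L, shape = c(32L, 32L)),
           channelNames = "ch1")
  m <- measureRegion(s, discRegion(c(16, 16), 25))
  expect_equal(m$plane, 1)
  expect_equal(m$mean, 37)
})

test_that("background measurement is exact on noise-free renders and bounded under noise", {
  cfg <- smallConfig(nFrames = 1L, shape = c(96L, 96L))
  empty <- manualTracks(data.frame(originRow = numeric(), originCol = numeric(),
                                   directionDeg = numeric()))
  clean <- renderMovie(empty, cleanModel(backgroundLevel = 20), cfg, seed = 1)
  bg <- measureBackground(clean$stack, discRegion(c(48, 48), 25))
  expect_identical(bg$mean, 20)
  # gaussian noise sigma 5 over ~489 pixels: mean within 20 +- 3*5/sqrt(489)
  noisyMdl <- renderModel(pcmAmplitude = 0, cometAmplitude = 0,
                          poissonNoise = FALSE, quantize = FALSE)
  devs <- vapply(1:10, function(s) {
    st <- renderMovie(empty, noisyMdl, cfg, seed = s)$stack
    measureBackground(st, discRegion(c(48, 48), 25))$mean - 20
  }, numeric(1))
  expect_true(all(abs(devs) < 3 * 5 / sqrt(489)))
})

test_that("a half-out-of-frame region averages in-frame pixels and flags clipping", {
  arr <- array(50, dim = c(1, 1, 1, 64, 64))
  s <- new("ImageStack", data = arr, config = smallConfig(nFrames = 1L, shape = c(64L, 64L)),
           channelNames = "ch1")
  m <- measureRegion(s, discRegion(c(3, 32), 25))
  expect_true(m$clipped)
  expect_equal(m$mean, 50)
  expect_lt(m$nPixels, 489)
  expect_error(suppressWarnings(measureRegion(s, discRegion(c(-40, -40), 25))))
})

test_that("background placement inside the embryo is warned about but measured", {
  cfg <- smallConfig(nFrames = 1L, shape = c(128L, 128L))
  geom <- embryoGeometry(centerPx = c(64, 64), semiAxesUm = c(8, 6),
                         config = cfg)
  arr <- array(20, dim = c(1, 1, 1, 128, 128))
  s <- new("ImageStack", data = arr, config = cfg, channelNames = "ch1")
  expect_warning(m <- measureBackground(s, discRegion(c(64, 64), 25),
                                        geometry = geom), "embryo")
  expect_true(m$overlapsEmbryo)
  expect_equal(m$mean, 20)
  m2 <- measureBackground(s, discRegion(c(15, 15), 25), geometry = geom)
  expect_false(m2$overlapsEmbryo)
})

test_that("fold change is 1 for identical groups, tracks amplitude ratios, and errors on nonpositive controls", {
  same <- data.frame(signal = c(30, 32, 31), background = c(20, 20, 20))
  expect_equal(foldChange(same, same)$ratio, 1)
  # rendered scenes at 2:1 amplitude, no noise
  cfg <- smallConfig(nFrames = 1L, shape = c(96L, 96L))
  mk <- function(amp) {
    scene <- data.frame(row = 48, col = 48, channel = 1, amplitude = amp,
                        sigmaPx = 2, focalPlane = 1)
    st <- renderIFScene(scene, cleanModel(), cfg, nZ = 1, seed = 1)$stack
    data.frame(signal = measureRegion(st, discRegion(c(48, 48), 25))$mean,
               background = measureRegion(st, discRegion(c(15, 15), 25))$mean)
  }
  fc <- foldChange(mk(160), mk(80))
  expect_equal(fc$ratio, 2, tolerance = 1e-3)
  expect_error(foldChange(same, data.frame(signal = c(10, 10), background = c(20, 20))),
               "control")
})

test_that("fold change is invariant to additive offsets and equivariant to scale", {
  withr::local_seed(8)
  s <- data.frame(signal = runif(6, 60, 80), background = runif(6, 18, 22))
  c0 <- data.frame(signal = runif(6, 35, 45), background = runif(6, 18, 22))
  base <- foldChange(s, c0)$ratio
  shift <- function(df, k) data.frame(signal = df$signal + k,
                                      background = df$background + k)
  expect_equal(foldChange(shift(s, 30), shift(c0, 30))$ratio, base,
               tolerance = 1e-12)
  scale2 <- function(df, k) data.frame(signal = df$signal * k,
                                       background = df$background * k)
  expect_equal(foldChange(scale2(s, 3), scale2(c0, 3))$ratio, base,
               tolerance = 1e-12)
  expect_equal(foldChange(scale2(s, 3), c0)$ratio, 3 * base,
               tolerance = 1e-12)
})

test_that("a 5-px centriolar disc on a narrow blob approaches the peak value", {
  cfg <- smallConfig(nFrames = 1L, shape = c(64L, 64L))
  scene <- data.frame(row = 32, col = 32, channel = 1, amplitude = 100,
                      sigmaPx = 8, focalPlane = 1)
  st <- renderIFScene(scene, cleanModel(backgroundLevel = 0), cfg, nZ = 1,
                      seed = 1)$stack
  m5 <- measureRegion(st, discRegion(c(32, 32), 5))
  expect_gt(m5$mean, 0.95 * 100)   # sigma >> disc radius: mean ~ peak
  m25 <- measureRegion(st, discRegion(c(32, 32), 25))
  expect_lt(m25$mean, m5$mean)
})

test_that("recovered fold change for a true 2x amplitude ratio is unbiased under default noise", {
  cfg <- smallConfig(nFrames = 1L, shape = c(96L, 96L))
  mdl <- renderModel()  # default noise, quantized
  one <- function(seed, amp) {
    scene <- data.frame(row = 48, col = 48, channel = 1, amplitude = amp,
                        sigmaPx = 2, focalPlane = 2)
    st <- renderIFScene(scene, mdl, cfg, nZ = 3, seed = seed)$stack
    data.frame(signal = measureRegion(st, discRegion(c(48, 48), 25))$mean,
               background = measureRegion(st, discRegion(c(15, 15), 25),
                                          plane = 2)$mean)
  }
  lo <- do.call(rbind, lapply(1:50, one, amp = 60))
  hi <- do.call(rbind, lapply(51:100, one, amp = 120))
  fc <- foldChange(hi, lo)
  expect_lt(abs(fc$ratio - 2), 0.15)
})
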