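## validate a config list against the allowed schema; unknown keys error
.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ", paste(extra, collapse = ", "))
}

.runDefaults <- function() {
  list(
    seeds = 1L,
    output_dir = "kymoMT-run",
    imaging = list(pixel_size_um = 0.151, frame_interval_s = 0.5,
                   n_frames = 61L, bit_scale = 255,
                   image_shape = c(199L, 331L)),
    geometry = list(semi_axes_um = c(25, 15)),
    comets = list(nucleation_rate_per_s = 1.26, velocity_um_per_s = 0.88,
                  catastrophe_per_frame = 0, birth_radius_px = 2,
                  angular_sector_deg = 360, sector_center_deg = 90),
    render = list(comet_amplitude = 120, comet_sigma_px = 0.7,
                  pcm_amplitude = 60, pcm_sigma_px = 2,
                  background_level = 20, gaussian_noise_sigma = 5,
                  poisson_noise = TRUE, quantize = TRUE),
    analysis = list(threshold = 40, proximal_radius_px = 25,
                    midpoint_radius_px = 60, cortex_offset_px = 10,
                    window_s = 5, steady_state = TRUE))
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with sections \code{imaging}, \code{geometry},
#' \code{comets}, \code{render}, \code{analysis} plus \code{seeds} and
#' \code{output_dir}; unknown keys are errors (they are usually typos), and
#' every omitted key takes the package default (recorded in the effective
#' config written beside the outputs).
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated config list with all defaults filled in.
#' @export
readRunConfig <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  defs <- .runDefaults()
  .checkKeys(user, names(defs), "top level")
  for (sec in c("imaging", "geometry", "comets", "render", "analysis")) {
    if (!is.null(user[[sec]])) {
      .checkKeys(user[[sec]], names(defs[[sec]]), sec)
      defs[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  for (k in c("seeds", "output_dir"))
    if (!is.null(user[[k]])) defs[[k]] <- user[[k]]
  defs
}

.logLine <- function(conn, fmt, ...) {
  line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(line)
  if (!is.null(conn)) writeLines(line, conn)
}

#' Run the end-to-end synthetic experiment pipeline
#'
#' For each seed: simulate comet tracks, render the movie, write the movie
#' TIFF, ground-truth tracks CSV and default measurement regions JSON, then
#' run the standard measurements (proximal and midpoint comet counts,
#' cortex crossings, nucleation intensity, centrosomal disc intensity) and
#' collect them in \code{measurements.csv}. The effective configuration and
#' a run log are written beside the outputs; identical configurations give
#' byte-identical CSV outputs.
#'
#' @param config path to a YAML configuration, or a config list (see
#'   [readRunConfig()]).
#' @param outputDir overrides the configured output directory.
#' @param writeMovies write movie TIFFs (default TRUE; disable to save
#'   space in large sweeps).
#' @return invisibly, the measurements data.frame.
#' @export
runExperiment <- function(config, outputDir = NULL, writeMovies = TRUE) {
  cfg <- readRunConfig(config)
  outDir <- outputDir %||% cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logConn <- file(file.path(outDir, "run.log"), open = "wt")
  on.exit(close(logConn), add = TRUE)

  img <- imagingConfig(cfg$imaging$pixel_size_um, cfg$imaging$frame_interval_s,
                       cfg$imaging$n_frames, cfg$imaging$bit_scale,
                       unlist(cfg$imaging$image_shape))
  geomArgs <- cfg$geometry
  geom <- embryoGeometry(semiAxesUm = unlist(geomArgs$semi_axes_um),
                         config = img)
  par <- cometSimParams(cfg$comets$nucleation_rate_per_s,
                        cfg$comets$velocity_um_per_s,
                        cfg$comets$catastrophe_per_frame,
                        cfg$comets$birth_radius_px,
                        cfg$comets$angular_sector_deg,
                        cfg$comets$sector_center_deg)
  mdl <- renderModel(cfg$render$comet_amplitude, cfg$render$comet_sigma_px,
                     cfg$render$pcm_amplitude, cfg$render$pcm_sigma_px,
                     cfg$render$background_level,
                     cfg$render$gaussian_noise_sigma,
                     cfg$render$poisson_noise, cfg$render$quantize)
  ana <- cfg$analysis
  yaml::write_yaml(cfg, file.path(outDir, "effective-config.yaml"))

  duration <- img@nFrames * img@frameIntervalS
  center <- geom@centrosomesPx[1, ]
  facing <- par@sectorCenterDeg
  vpx <- par@velocityUmPerS / img@pixelSizeUm
  w0 <- if (isTRUE(ana$steady_state)) {
    ceiling((ana$proximal_radius_px / vpx) / img@frameIntervalS + 1) *
      img@frameIntervalS
  } else 0
  window <- c(w0, w0 + ana$window_s)
  bgCenter <- c(center[1],
                center[2] - 2.4 * max(ana$proximal_radius_px, 25))

  rows <- list()
  for (seed in unlist(cfg$seeds)) {
    t0 <- proc.time()[["elapsed"]]
    tr <- simulateComets(par, geom, durationS = duration, config = img,
                         seed = seed)
    mov <- renderMovie(tr, mdl, img, geom, seed = seed)
    .logLine(logConn, "seed %d: simulated %d comets (rate %.3g/s, v %.2f um/s)",
             seed, nTracks(tr), par@nucleationRatePerS, par@velocityUmPerS)
    prox <- semicircleRegion(center, ana$proximal_radius_px, facing,
                             widthPx = 3)
    mid <- semicircleRegion(center, ana$midpoint_radius_px, facing,
                            widthPx = 3)
    if (writeMovies) {
      writeStack(mov$stack, file.path(outDir, sprintf("movie-seed%03d.tif", seed)))
      utils::write.csv(tracks(tr),
                       file.path(outDir, sprintf("tracks-seed%03d.csv", seed)),
                       row.names = FALSE)
      writeRegions(list(proximal = prox, midpoint = mid,
                        centrosome = discRegion(center, 25),
                        background = discRegion(bgCenter, 25)),
                   file.path(outDir, sprintf("regions-seed%03d.json", seed)))
    }
    kymP <- buildKymograph(mov$stack, prox, window = window, step = 0.5)
    kymM <- buildKymograph(mov$stack, mid, window = window, step = 0.5)
    cntP <- countCometEvents(kymP, ana$threshold, role = "proximal")
    cntM <- countCometEvents(kymM, ana$threshold, role = "midpoint")
    cntC <- countCortexCrossings(mov$stack, geom,
                                 offsetPx = ana$cortex_offset_px,
                                 window = window, threshold = ana$threshold)
    nuc <- nucleationIntensity(mov$stack, center, bgCenter,
                               facingDeg = facing, window = window)
    ce <- measureRegion(mov$stack, discRegion(center, 25),
                        label = sprintf("seed%03d", seed))
    bg <- measureRegion(mov$stack, discRegion(bgCenter, 25),
                        label = sprintf("seed%03d", seed),
                        compartment = "background")
    rows[[length(rows) + 1]] <- data.frame(
      seed = seed, nComets = nTracks(tr),
      proximalEvents = cntP$nEvents, proximalComponents = cntP$nComponents,
      proximalPixels = cntP$nPixels,
      midpointEvents = cntM$nEvents, cortexEvents = cntC$nEvents,
      nucleationNet = nuc$net,
      centrosomeMean = ce$mean, backgroundMean = bg$mean,
      centrosomeNet = ce$mean - bg$mean,
      trueCrossings = expectedArcCrossings(
        tr, center, ana$proximal_radius_px, window, img,
        spanDeg = 180, gapCenterDeg = facing + 180))
    .logLine(logConn, "seed %d: proximal %d events, cortex %d, %.1f s",
             seed, cntP$nEvents, cntC$nEvents,
             proc.time()[["elapsed"]] - t0)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(outDir, "measurements.csv"),
                   row.names = FALSE)
  summary <- list(
    nSeeds = length(unlist(cfg$seeds)),
    proximalEventsMean = mean(out$proximalEvents),
    midpointEventsMean = mean(out$midpointEvents),
    cortexEventsMean = mean(out$cortexEvents),
    nucleationNetMean = mean(out$nucleationNet),
    centrosomeNetMean = mean(out$centrosomeNet),
    packageVersion = as.character(utils::packageVersion("kymoMT")))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
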