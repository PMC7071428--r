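# End-to-end orchestration: each step reads/writes the package's file
# formats so runs are reproducible and auditable from the shell or from R.

#' Simulate a play-session fixture
#'
#' Renders a scripted sequence, writes the .k3dv container, the ground
#' truth (velocity + CARS CSVs, centroid JSON) and a config snapshot.
#'
#' @param outDir output directory
#' @param preset \code{"walk"} (1 m/s in x), \code{"run"} (2.5 m/s in x),
#'   \code{"still"} (stationary), or \code{"mixed"} (speed changes each
#'   two seconds)
#' @param duration_s sequence length in seconds
#' @param noise_sd infrared noise standard deviation
#' @param config pipeline configuration
#' @param seed integer seed
#' @return list with paths and the rendered ground truth
#' @export
runSimulate <- function(outDir, preset = c("walk", "run", "still", "mixed"),
                        duration_s = 10, noise_sd = 0,
                        config = defaultConfig(), seed = config$seed) {
  preset <- match.arg(preset)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cal <- canonicalCalibration()
  script <- switch(preset,
    still = trajectoryScript("child1", shapeWidth = 24, shapeHeight = 120,
      path = data.frame(t_ms = 0, x_px = 320, y_px = 240,
                        depth_mm = 2500)),
    walk = makeConstantVelocityScript(1.0, "x", depth_mm = 3000,
                                      duration_s = duration_s,
                                      objectId = "child1"),
    run = makeConstantVelocityScript(2.5, "x", depth_mm = 3800,
                                     duration_s = duration_s,
                                     objectId = "child1"),
    mixed = {
      # alternating slow/fast out-and-back legs, bounded within the frame
      scl <- scalingAt(cal, 3000)
      secs <- ceiling(duration_s)
      spd <- rep(rep(c(0.2, 1.2), each = 2L),
                 length.out = secs) / scl            # px per second
      leg <- rep(c(1, -1), length.out = secs)
      xs <- 320 + c(0, cumsum(leg * spd * 0.45))
      trajectoryScript("child1", shapeWidth = 24, shapeHeight = 120,
        path = data.frame(t_ms = (0:secs) * 1000, x_px = xs, y_px = 240,
                          depth_mm = 3000))
    })
  ren <- renderSequence(script, duration_s = duration_s,
                        noise_sd = noise_sd, seed = seed,
                        calibration = cal)
  writeFrameSequence(ren$frames, file.path(outDir, "frames.k3dv"))
  writeGroundTruth(ren$truth, outDir)
  writeConfig(config, file.path(outDir, "config.txt"))
  invisible(list(dir = outDir, truth = ren$truth,
                 frames = file.path(outDir, "frames.k3dv")))
}

#' Extract tracks from a recorded sequence
#'
#' @param input .k3dv file, image directory, or a
#'   \linkS4class{FrameSequence}
#' @param outDir optional directory for the tracks JSON-lines file
#' @param config pipeline configuration
#' @return a \linkS4class{TrackSet}
#' @export
runExtract <- function(input, outDir = NULL, config = defaultConfig()) {
  frames <- if (is(input, "FrameSequence")) input else
    readFrameSequence(input)
  tracks <- extractTracks(frames, config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTracks(tracks, file.path(outDir, "tracks.jsonl"))
    writeConfig(config, file.path(outDir, "config.txt"))
  }
  tracks
}

#' Convert a child track to velocities and VM epochs
#'
#' @param tracks a \linkS4class{TrackSet}
#' @param whitelist child track ids (defaults to the longest track)
#' @param calibration a \linkS4class{CalibrationModel}
#' @param outDir optional directory for velocities/epochs CSVs
#' @param config pipeline configuration
#' @param child_id identifier written into the epoch table
#' @return list with \code{velocities} and \code{epochs} data.frames
#' @export
runMotion <- function(tracks, whitelist = NULL,
                      calibration = canonicalCalibration(), outDir = NULL,
                      config = defaultConfig(), child_id = 1L) {
  if (is.null(whitelist)) {
    lens <- vapply(trackData(tracks), nrow, integer(1L))
    if (length(lens) == 0L) stop("no tracks to analyse")
    whitelist <- names(lens)[which.max(lens)]
  }
  child <- selectChildTracks(tracks, whitelist)
  vel <- trackVelocities(child, calibration, vMax = config$v_max,
                         K = config$K, useSmoothed = config$use_smoothed)
  epochs <- epochsFromTrack(child, calibration, config)
  if (nrow(epochs) > 0L) epochs <- cbind(child_id = child_id, epochs)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(vel, file.path(outDir, "velocities.csv"),
                     row.names = FALSE)
    utils::write.csv(epochs, file.path(outDir, "epochs.csv"),
                     row.names = FALSE)
  }
  list(velocities = vel, epochs = epochs)
}

#' Reintegrate a CARS CSV into epoch intensities
#'
#' @param carsCsv path to a CSV with columns child_id, second, code
#' @param outDir optional output directory
#' @param config pipeline configuration
#' @return data.frame of epoch intensities
#' @export
runCars <- function(carsCsv, outDir = NULL, config = defaultConfig()) {
  rec <- readCarsCsv(carsCsv)
  out <- reintegrateCars(rec, epochS = config$epoch_s)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(outDir, "cars_epochs.csv"),
                     row.names = FALSE)
  }
  out
}

#' Train and evaluate intensity classifiers on labelled epochs
#'
#' Trains the one-vs-all and multiclass trees, evaluates both by
#' resubstitution, and runs the equivalence analysis of observed vs
#' estimated time shares.
#'
#' @param epochs data.frame with columns child_id, epoch_index,
#'   vm_value, intensity
#' @param outDir optional output directory for reports
#' @param config pipeline configuration
#' @return list with models, reports, shares and equivalence tables
#' @export
runClassification <- function(epochs, outDir = NULL,
                              config = defaultConfig()) {
  cart <- trainIntensityModel(epochs, "onevsall")
  mcart <- trainIntensityModel(epochs, "multiclass")
  evCart <- evaluateIntensityModel(cart, epochs, nBoot = config$n_boot,
                                   seed = config$seed)
  evMcart <- evaluateIntensityModel(mcart, epochs, nBoot = config$n_boot,
                                    seed = config$seed)
  shares <- list(
    cart = timeShares(epochs, transform(epochs,
      intensity = predictLabels(cart, epochs$vm_value))),
    mcart = timeShares(epochs, transform(epochs,
      intensity = predictLabels(mcart, epochs$vm_value))))
  equiv <- list(
    cart = equivalenceAnalysis(shares$cart, nBoot = config$n_boot,
                               seed = config$seed),
    mcart = equivalenceAnalysis(shares$mcart, nBoot = config$n_boot,
                                seed = config$seed))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(classMetrics(evCart),
                     file.path(outDir, "report_cart.csv"),
                     row.names = FALSE)
    utils::write.csv(classMetrics(evMcart),
                     file.path(outDir, "report_mcart.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(cbind(model = "cart", equiv$cart),
                           cbind(model = "mcart", equiv$mcart)),
                     file.path(outDir, "equivalence.csv"),
                     row.names = FALSE)
    conf <- confusionMatrix(evMcart)
    if (length(conf) > 0L)
      utils::write.csv(conf, file.path(outDir, "confusion_mcart.csv"))
    writeIntensityModel(cart, file.path(outDir, "model_cart.json"))
    writeIntensityModel(mcart, file.path(outDir, "model_mcart.json"))
  }
  list(models = list(cart = cart, mcart = mcart),
       reports = list(cart = evCart, mcart = evMcart),
       shares = shares, equivalence = equiv)
}

#' Run the full pipeline on a rendered fixture
#'
#' simulate -> extract -> motion -> CARS reintegration -> classification.
#' The fixture's own ground-truth CARS stream provides the labels.
#'
#' @param outDir working directory for all artifacts
#' @param preset fixture preset, see \code{\link{runSimulate}}
#' @param duration_s fixture length in seconds
#' @param config pipeline configuration
#' @param seed integer seed
#' @return list of intermediate results
#' @export
runAll <- function(outDir, preset = "mixed", duration_s = 60,
                   config = defaultConfig(), seed = config$seed) {
  sim <- runSimulate(outDir, preset = preset, duration_s = duration_s,
                     config = config, seed = seed)
  tracks <- runExtract(sim$frames, outDir, config)
  motion <- runMotion(tracks, outDir = outDir, config = config)
  truthCars <- utils::read.csv(file.path(outDir, "truth_cars.csv"))
  carsRec <- data.frame(child_id = 1L, second = truthCars$second,
                        code = truthCars$code)
  carsEp <- reintegrateCars(carsRec, epochS = config$epoch_s)
  utils::write.csv(carsEp, file.path(outDir, "cars_epochs.csv"),
                   row.names = FALSE)
  labelled <- merge(motion$epochs, carsEp[, c("epoch_index", "intensity")],
                    by = "epoch_index")
  cls <- if (length(unique(labelled$intensity)) >= 2L)
    runClassification(labelled, outDir, config) else NULL
  list(tracks = tracks, motion = motion, cars = carsEp,
       classification = cls)
}
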