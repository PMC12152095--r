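#' Pipeline configuration
#'
#' Aggregates every setting of the end-to-end analysis. Defaults follow
#' the package's standard protocol: 710--825 nm SID window, six
#' endmembers, SNV pre-treatment, RBF-SVM detection with a stratified
#' 60/40 split and 10-fold cross-validation repeated 50 times, and a
#' synthetic campaign of 168 samples per class.
#'
#' @param simulate generate a synthetic campaign (TRUE) or read cubes
#'   from \code{paths}.
#' @param seed master seed; each stage uses seed + 1000 * stage index.
#' @param window SID window in nm (length 2).
#' @param K number of endmembers.
#' @param nPerClass labeled samples per class in simulate mode.
#' @param classifier detection classifier kind.
#' @param pretreatment spectra pre-treatment for detection ("snv", ...).
#' @param protocol list with splitFrac, folds, iterations.
#' @param scene a [sceneConfig()] for simulate mode.
#' @param paths named list of input paths (cube, white, dark, plantPixels,
#'   backgroundPixels) for non-simulated runs.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(simulate = TRUE, seed = 1L,
                           window = c(710, 825), K = 6L,
                           nPerClass = 168L, classifier = "svm_rbf",
                           pretreatment = "snv",
                           protocol = list(splitFrac = 0.6, folds = 10L,
                                           iterations = 50L),
                           scene = sceneConfig(),
                           paths = list()) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (lo, hi) with lo < hi")
  cfg <- list(simulate = simulate, seed = as.integer(seed), window = window,
              K = as.integer(K), nPerClass = as.integer(nPerClass),
              classifier = classifier, pretreatment = pretreatment,
              protocol = protocol, scene = scene, paths = paths)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipelineConfig()] arguments; scene keys
#' are nested under \code{scene}. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$scene)) raw$scene <- do.call(sceneConfig, raw$scene)
  do.call(pipelineConfig, raw)
}

stageSeed <- function(cfg, k) cfg$seed + 1000L * k

newRunLog <- function(dir) {
  logPath <- file.path(dir, "run.log")
  function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", sep = "", file = logPath, append = TRUE)
    message(line)
  }
}

#' Run the detection pipeline
#'
#' Executes the full detection flow and writes every artifact to a run
#' directory: (simulate or load) reflectance cubes, plant/background
#' segmentation, 5x5 mask erosion, N-FINDR endmember extraction on the
#' infested image, infested reference spectrum, SID map in the
#' configured window with Otsu thresholding, labeled mean-spectra table,
#' random-forest wavelength selection on the pre-treated spectra, the
#' detection protocol for the configured classifier on the selected
#' bands, and a pixel-wise class map. A JSON manifest records the stage
#' order, seeds, threshold and every output file.
#'
#' @param config a [pipelineConfig()] (or path to a YAML config).
#' @param outDir run directory (created; must not exist or be empty).
#' @return invisibly, the manifest list.
#' @export
runDetection <- function(config = pipelineConfig(), outDir = tempfile("run_")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- newRunLog(outDir)
  manifest <- list(pipeline = "detection",
                   package = as.character(utils::packageVersion("aphidSID")),
                   seed = config$seed, stages = list(), outputs = list())
  addStage <- function(name, info = list()) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      c(list(stage = name), info)
    log("stage %s done", name)
  }

  # 1. acquire -------------------------------------------------------------
  if (config$simulate) {
    scHealthy <- config$scene
    scHealthy$aphidCount <- 0L
    healthy <- makeScene(scHealthy, seed = stageSeed(config, 1L))
    infested <- makeScene(config$scene, seed = stageSeed(config, 1L) + 1L)
    writeENVI(healthy$cube, file.path(outDir, "healthy"))
    writeENVI(infested$cube, file.path(outDir, "infested"))
    addStage("simulate", list(seed = stageSeed(config, 1L)))
  } else {
    p <- config$paths
    infestedRaw <- readENVI(p$cube)
    if (!is.null(p$white) && !is.null(p$dark)) {
      infested <- list(cube = calibrateReflectance(
        infestedRaw, readENVI(p$white), readENVI(p$dark)), truth = NULL)
    } else infested <- list(cube = infestedRaw, truth = NULL)
    healthy <- NULL
    addStage("load", list(cube = p$cube))
  }
  addStage("calibrate",
           list(note = if (config$simulate)
             "simulated cubes are generated in reflectance units"
             else "white/dark calibration"))

  # 2. segment + erode ------------------------------------------------------
  segSeed <- stageSeed(config, 2L)
  if (config$simulate) {
    truthLeaf <- leafMask(infested$truth)
    pick <- withSeed(segSeed, list(
      plant = sample(which(truthLeaf), min(300L, sum(truthLeaf))),
      bg = sample(which(!truthLeaf), min(300L, sum(!truthLeaf)))))
    Xall <- pixelMatrix(infested$cube)
    model <- fitBackgroundModel(Xall[pick$plant, , drop = FALSE],
                                Xall[pick$bg, , drop = FALSE],
                                seed = segSeed)
  } else {
    model <- fitBackgroundModel(readSpectraCSV(config$paths$plantPixels),
                                readSpectraCSV(config$paths$backgroundPixels),
                                seed = segSeed)
  }
  mask <- segmentPlant(infested$cube, model)
  addStage("segment", list(seed = segSeed, plantPixels = sum(mask)))
  maskEroded <- erodeMask(mask)
  writeMaskPNG(maskEroded, file.path(outDir, "plant_mask.png"))
  addStage("erode", list(plantPixels = sum(maskEroded)))

  # 3. endmembers -> reference -> SID map -----------------------------------
  emSeed <- stageSeed(config, 3L)
  em <- nfindr(infested$cube, maskEroded, K = config$K, seed = emSeed)
  utils::write.csv(
    data.frame(endmember = seq_len(config$K),
               stats::setNames(as.data.frame(endmemberSpectra(em)),
                               bandColumnNames(wavelengths(em)))),
    file.path(outDir, "endmembers.csv"), row.names = FALSE)
  addStage("endmembers", list(seed = emSeed, K = config$K))
  win <- resolveWindow(wavelengths(infested$cube),
                       config$window[1], config$window[2])
  aphidIdx <- aphidEndmembers(em, infested$cube, maskEroded, win)
  ref <- buildReference(em, subset = aphidIdx)
  addStage("reference", list(aphidEndmembers = as.integer(aphidIdx)))
  smap <- sidMap(infested$cube, maskEroded, ref, win)
  infMask <- thresholdSid(smap, "otsu")
  writeSIDMapPNG(smap, file.path(outDir, "sid_map.png"),
                 threshold = attr(infMask, "threshold"))
  writeMaskPNG(infMask, file.path(outDir, "infestation_mask.png"))
  addStage("sidmap", list(loIdx = win$loIdx, hiIdx = win$hiIdx,
                          threshold = attr(infMask, "threshold")))

  # 4. labeled spectra ------------------------------------------------------
  tabSeed <- stageSeed(config, 4L)
  if (config$simulate) {
    table <- makeLabeledDataset(config$nPerClass, config$scene, seed = tabSeed)
  } else {
    table <- readSpectraCSV(config$paths$labeledSpectra)
  }
  writeSpectraCSV(table, file.path(outDir, "labeled_spectra.csv"))
  addStage("spectra", list(seed = tabSeed, n = nrow(table)))

  # 5. feature selection -----------------------------------------------------
  prepTable <- table
  if (config$pretreatment != "raw") {
    M <- applyPretreatment(spectraMatrix(table), config$pretreatment)
    prepTable[, bandColumns(table)] <- M
  }
  selSeed <- stageSeed(config, 5L)
  ranking <- rfRankFeatures(prepTable, seed = selSeed)
  utils::write.csv(data.frame(wavelength = tableWavelengths(table),
                              importance = as.numeric(ranking$importance),
                              selected = seq_along(ranking$importance) %in%
                                ranking$selectedIdx),
                   file.path(outDir, "feature_ranking.csv"),
                   row.names = FALSE)
  addStage("select", list(seed = selSeed,
                          nSelected = length(ranking$selectedIdx)))

  # 6. detection protocol ----------------------------------------------------
  clsSeed <- stageSeed(config, 6L)
  selTable <- prepTable[, c("sample_id", "label",
                            bandColumns(prepTable)[ranking$selectedIdx])]
  report <- evaluateProtocol(selTable, kind = config$classifier,
                             splitFrac = config$protocol$splitFrac,
                             folds = config$protocol$folds,
                             iterations = config$protocol$iterations,
                             seed = clsSeed)
  jsonlite::write_json(report[c("kind", "cv", "test", "folds", "iterations",
                                "nTrain", "nTest")],
                       file.path(outDir, "classifier_report.json"),
                       auto_unbox = TRUE, digits = NA)
  addStage("classify", list(seed = clsSeed, kind = config$classifier,
                            testBalancedAccuracy =
                              report$test$balancedAccuracy))

  # 7. pixel map --------------------------------------------------------------
  classMap <- predictPixelMap(infested$cube, maskEroded, report$model,
                              pretreatment = config$pretreatment,
                              selectedIdx = ranking$selectedIdx)
  writeClassMapPNG(classMap, file.path(outDir, "class_map.png"))
  addStage("maps", list())

  manifest$outputs <- as.list(list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("detection pipeline complete: %s", outDir)
  invisible(c(manifest, list(report = report, ranking = ranking,
                             sidMask = infMask, classMap = classMap,
                             runDir = outDir,
                             truth = if (config$simulate) infested$truth)))
}

#' Run the aphid-count regression pipeline
#'
#' Builds (or reads) a counted spectra table of infested samples and
#' compares the PLS pre-treatments (raw, SNV, log(1/R), first and second
#' derivatives) on a shared split, writing the report table and a
#' manifest.
#'
#' @param config a [pipelineConfig()] (or YAML path).
#' @param outDir run directory.
#' @return invisibly, the report data.frame.
#' @export
runRegression <- function(config = pipelineConfig(), outDir = tempfile("run_")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- newRunLog(outDir)
  tabSeed <- stageSeed(config, 4L)
  if (config$simulate) {
    table <- makeLabeledDataset(config$nPerClass, config$scene, seed = tabSeed)
    table <- table[table$label == "infested", ]
  } else {
    table <- readSpectraCSV(config$paths$countedSpectra)
  }
  if (!"aphid_count" %in% names(table) || !nrow(table))
    stop("regression requires a spectra table with aphid_count")
  report <- comparePretreatments(table, folds = config$protocol$folds,
                                 seed = stageSeed(config, 7L))
  utils::write.csv(report, file.path(outDir, "pls_report.csv"),
                   row.names = FALSE)
  manifest <- list(pipeline = "regression",
                   package = as.character(utils::packageVersion("aphidSID")),
                   seed = config$seed, n = nrow(table),
                   stages = list(list(stage = "spectra", seed = tabSeed),
                                 list(stage = "regress",
                                      seed = stageSeed(config, 7L))),
                   outputs = as.list(list.files(outDir)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("regression pipeline complete: %s", outDir)
  invisible(report)
}
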