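# Study drivers tying the phases together: a YAML study config selects a
# method block (moat | correlations | vbd | tune), the synthetic cohort
# and the execution settings; every command writes machine-readable
# outputs plus a JSON run log with seeds, run counts and cache statistics.

readStudyConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  methods <- intersect(names(config$method), c("moat", "correlations", "vbd", "tune"))
  if (length(methods) != 1)
    stop("study config must contain exactly one method block", call. = FALSE)
  config$methodName <- methods
  config
}

studySpace <- function(config) {
  sp <- if (is.null(config$space) || identical(config$space, "watershed"))
    watershedSpace(includeDummy = isTRUE(config$include_dummy))
  else readParameterSpace(config$space)
  if (!is.null(config$fixed)) sp <- fixParameters(sp, unlist(config$fixed))
  sp
}

studyCohort <- function(config) {
  cc <- config$cohort %||% list()
  cfg <- sceneConfig(width = cc$width %||% 64, height = cc$height %||% 64,
                     nuclei = cc$nuclei %||% 8,
                     overlapFraction = cc$overlap %||% 0.25,
                     noiseSd = cc$noise_sd %||% 8)
  generateCohort(cc$tiles %||% 6, cfg,
                 masterSeed = cc$master_seed %||% deriveSeed(config$seed %||% 1, 99))
}

studyStore <- function(config) {
  sc <- config$store
  if (is.null(sc)) return(NULL)
  resultStore(capacity = sc$capacity %||% 128,
              policy = toupper(sc$policy %||% "FIFO"),
              l2capacity = sc$l2capacity %||% Inf)
}

# Evaluate every row of a unit-space design on the cohort; the output of
# one run is the XOR pixel count between its mask and the reference mask
# (the default-parameter segmentation), summed over tiles.
evaluateDesign <- function(space, design, cohort, pipeline = watershedPipeline(),
                           mode = "compact", store = NULL) {
  d <- designMatrix(design)
  points <- lapply(seq_len(nrow(d)), function(i) fromUnit(space, d[i, ]))
  refPoint <- defaultPoint(space)
  y <- numeric(nrow(d))
  stats <- list(runs = 0, nodes = 0, replicaRuns = 0)
  for (ti in seq_along(cohort$tiles)) {
    input <- list(tile = cohort$tiles[[ti]])
    ref <- runPipeline(cohort$tiles[[ti]], refPoint)$mask
    res <- runBatch(pipeline, points, input, mode = mode, store = store)
    y <- y + vapply(res$outputs, function(o) xorCount(o$mask, ref), numeric(1))
    stats$runs <- stats$runs + res$stats$runs
    stats$nodes <- stats$nodes + res$stats$nodes
    stats$replicaRuns <- stats$replicaRuns + res$stats$replicaRuns
  }
  stats$savings <- 1 - stats$runs / stats$replicaRuns
  list(y = y, stats = stats, points = points)
}

writeRunLog <- function(outDir, name, log) {
  jsonlite::write_json(log, file.path(outDir, paste0(name, "_runlog.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

prepareOutDir <- function(config) {
  outDir <- config$output_dir %||% "study_output"
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  outDir
}

#' Run a study described by a config file
#'
#' The config (YAML, or an equivalent list) selects the parameter space,
#' the synthetic cohort, the result-store settings, the composition mode
#' and exactly one method block: `moat` (screening), `correlations`,
#' `vbd` or `tune`. Outputs (CSV reports, histories, a JSON run log with
#' seeds, run counts and cache statistics) land in `output_dir`.
#'
#' @param config path to a YAML study config, or a list.
#' @return the method's primary result, invisibly (also written to disk).
#' @export
runStudy <- function(config) {
  config <- readStudyConfig(config)
  switch(config$methodName,
         moat = cmdMoat(config),
         correlations = cmdImportance(config),
         vbd = cmdImportance(config),
         tune = cmdTune(config))
}

#' Study commands
#'
#' `cmdGenerate` writes a synthetic cohort to disk; `cmdMoat` runs the
#' screening phase (design, batched evaluation, elementary effects,
#' three-class report); `cmdImportance` runs the correlation phase and/or
#' variance-based decomposition; `cmdTune` runs an auto-tuning study and
#' writes the default-vs-tuned comparison panel.
#'
#' @param config study config (path or list), see [runStudy()].
#' @return the primary result of the command, invisibly.
#' @export
cmdGenerate <- function(config) {
  config <- if (is.character(config)) yaml::read_yaml(config) else config
  outDir <- prepareOutDir(config)
  cc <- config$cohort %||% list()
  cfg <- sceneConfig(width = cc$width %||% 64, height = cc$height %||% 64,
                     nuclei = cc$nuclei %||% 8,
                     overlapFraction = cc$overlap %||% 0.25,
                     noiseSd = cc$noise_sd %||% 8)
  cohort <- generateCohort(cc$tiles %||% 6, cfg,
                           masterSeed = cc$master_seed %||% 1,
                           dir = file.path(outDir, "cohort"))
  invisible(cohort)
}

#' @rdname cmdGenerate
#' @export
cmdMoat <- function(config) {
  config <- readStudyConfig(config)
  outDir <- prepareOutDir(config)
  mb <- config$method$moat
  space <- studySpace(config)
  cohort <- studyCohort(config)
  store <- studyStore(config)
  seed <- config$seed %||% 1
  design <- moatDesign(space, r = mb$r %||% 10, seed = deriveSeed(seed, 1),
                       p = mb$p %||% space@p)
  ev <- evaluateDesign(space, design, cohort,
                       mode = config$composition %||% "compact", store = store)
  effects <- elementaryEffects(design, ev$y)
  report <- screenParameters(effects, tHi = mb$t_hi, tLo = mb$t_lo)
  writeMOATReport(report, file.path(outDir, "moat_report.csv"))
  writeRunLog(outDir, "moat",
              list(seed = seed, r = design@r, k = ncol(design@design),
                   runs = nRuns(design), execution = ev$stats,
                   store = if (!is.null(store)) storeStats(store)))
  invisible(report)
}

#' @rdname cmdGenerate
#' @export
cmdImportance <- function(config) {
  config <- readStudyConfig(config)
  outDir <- prepareOutDir(config)
  space <- studySpace(config)
  cohort <- studyCohort(config)
  store <- studyStore(config)
  seed <- config$seed %||% 1
  k <- paramCount(space)
  out <- list()

  if (config$methodName == "correlations") {
    cb <- config$method$correlations
    n <- cb$n %||% 400
    design <- switch(cb$sampler %||% "monte-carlo",
      "monte-carlo" = monteCarloDesign(n, k, deriveSeed(seed, 2)),
      "lhs" = lhsDesign(n, k, deriveSeed(seed, 2)),
      "halton" = haltonDesign(n, k),
      "hammersley" = hammersleyDesign(n, k))
    ev <- evaluateDesign(space, design, cohort,
                         mode = config$composition %||% "compact", store = store)
    # correlate on the snapped values actually run (categoricals as levels)
    X <- do.call(rbind, lapply(ev$points, function(pt)
      toUnit(space, pt)))
    rep <- correlationReport(X, ev$y)
    writeImportanceReport(rep, file.path(outDir, "correlation_report.csv"))
    writeRunLog(outDir, "correlations",
                list(seed = seed, n = n, k = k, runs = nRuns(design),
                     execution = ev$stats))
    out$correlations <- rep
  } else {
    vb <- config$method$vbd
    n <- vb$n %||% 200
    design <- saltelliDesign(n, k, sampler = vb$sampler %||% "monte-carlo",
                             seed = deriveSeed(seed, 3))
    ev <- evaluateDesign(space, design, cohort,
                         mode = config$composition %||% "compact", store = store)
    rep <- vbdEstimate(design, ev$y, names = paramNames(space, free = TRUE))
    writeImportanceReport(rep, file.path(outDir, "vbd_report.csv"))
    writeRunLog(outDir, "vbd",
                list(seed = seed, n = n, k = k, runs = nRuns(design),
                     V = rep$V, sumSi = rep$sumSi, execution = ev$stats))
    out$vbd <- rep
  }
  invisible(out)
}

#' @rdname cmdGenerate
#' @export
cmdTune <- function(config) {
  config <- readStudyConfig(config)
  outDir <- prepareOutDir(config)
  tb <- config$method$tune
  space <- studySpace(config)
  cohort <- studyCohort(config)
  store <- studyStore(config)
  seed <- config$seed %||% 1
  metric <- tb$metric %||% "dice"
  nTiles <- length(cohort$tiles)

  idx <- seq_len(nTiles)
  testIdx <- integer(0)
  if (!is.null(tb$train) && tb$train < nTiles) {
    split <- trainTestSplit(nTiles, tb$train, seed = deriveSeed(seed, 4))
    idx <- split$train
    testIdx <- split$test
  }
  obj <- segObjective(space, cohort$tiles[idx], cohort$masks[idx],
                      metric = metric, store = store)
  result <- tune(obj, method = tb$method %||% "nm", budget = tb$budget %||% 100,
                 threshold = tb$threshold %||% 0, seed = deriveSeed(seed, 5))
  writeTuningHistory(result, file.path(outDir, "tuning_history.csv"))

  # per-image default-vs-tuned comparison panel
  mfun <- if (metric == "dice") diceCoef else jaccardCoef
  panelIdx <- if (length(testIdx)) testIdx else seq_len(nTiles)
  defaults <- defaultPoint(space)
  panel <- do.call(rbind, lapply(panelIdx, function(i) {
    ref <- asBinaryMask(cohort$masks[[i]])
    md <- runPipeline(cohort$tiles[[i]], defaults)$mask
    mt <- runPipeline(cohort$tiles[[i]], result@bestPoint)$mask
    data.frame(image = i, default = mfun(md, ref), tuned = mfun(mt, ref))
  }))
  write.csv(panel, file.path(outDir, "tuning_panel.csv"), row.names = FALSE)
  yaml::write_yaml(result@bestPoint, file.path(outDir, "best_params.yaml"))
  writeRunLog(outDir, "tune",
              list(seed = seed, method = tb$method %||% "nm",
                   budget = tb$budget %||% 100, metric = metric,
                   evaluations = result@evaluations,
                   bestScore = result@bestScore,
                   stopReason = result@stopReason,
                   train = if (length(testIdx)) idx,
                   test = if (length(testIdx)) testIdx,
                   panelMeanDefault = mean(panel$default),
                   panelMeanTuned = mean(panel$tuned),
                   store = if (!is.null(store)) storeStats(store)))
  invisible(list(result = result, panel = panel))
}

#' Compact-vs-replica composition statistics for a design batch
#'
#' Builds both composition modes for the given batch on one tile and
#' reports node counts, stage executions and the savings ratio — the
#' simultaneous-parameter-evaluation gain for that batch.
#'
#' @param space a [ParameterSpace-class].
#' @param design a [DesignMatrix-class] (e.g. a MOAT design).
#' @param tile an RGB tile.
#' @param pipeline a [SegPipeline-class].
#' @return list with per-mode stats and the savings ratio.
#' @export
composeStats <- function(space, design, tile, pipeline = watershedPipeline()) {
  d <- designMatrix(design)
  points <- lapply(seq_len(nrow(d)), function(i) fromUnit(space, d[i, ]))
  input <- list(tile = tile)
  rep_ <- runBatch(pipeline, points, input, mode = "replica")
  cmp <- runBatch(pipeline, points, input, mode = "compact")
  identical_ <- all(vapply(seq_along(points), function(i)
    identical(rep_$outputs[[i]], cmp$outputs[[i]]), logical(1)))
  list(replica = rep_$stats, compact = cmp$stats,
       outputsIdentical = identical_,
       savings = 1 - cmp$stats$runs / rep_$stats$runs)
}
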