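# End-to-end experiment orchestration: data -> dictionary -> extraction ->
# (optional quantization) -> IG pre-selection -> SFS -> final classifier ->
# metrics, extractor accounting, compression ratio and energy report, all
# reproducible from one declarative config.

#' Experiment configuration
#'
#' @param application `"arrhythmia"` (binary, single-channel 256-sample
#'   windows), `"har_multiclass"` or `"har_one_vs_all"` (6-channel
#'   128-sample windows).
#' @param dataset optional [WindowedDataset-class]; when `NULL` a synthetic
#'   dataset matching the application is generated under `seed`.
#' @param includeConstant include the constant wavelet in the dictionary
#'   (default `TRUE` for HAR applications, `FALSE` for arrhythmia).
#' @param channels channel indices to generate features from; defaults to
#'   all dataset channels.
#' @param nPreselect IG pre-selection pool size.
#' @param sfsMode `"basic"`, `"adapted"` or `"optimized"`.
#' @param selection a [selectionConfig()].
#' @param finalClassifier optional [classifierSpec()] for the final refit on
#'   the selected features (defaults to the selection classifier).
#' @param quantizationBits optional ADC bit depth applied to the candidate
#'   features after pre-selection (ranges learned on the training split).
#' @param budget optional [powerBudget()] for energy reporting.
#' @param signalDuration duration used for chain-energy reports, s.
#' @param windowPeriod analysis-window cadence, s; defaults to the
#'   application convention (contiguous 0.711 s ECG windows; 1.28 s between
#'   50%-overlapped inertial windows).
#' @param outputDir optional directory for JSON artifacts.
#' @param seed master seed for simulation and selection.
#' @return an `ExperimentConfig` (list).
#' @export
experimentConfig <- function(application = c("arrhythmia", "har_multiclass",
                                             "har_one_vs_all"),
                             dataset = NULL, includeConstant = NULL,
                             channels = NULL, nPreselect = 100L,
                             sfsMode = c("adapted", "basic", "optimized"),
                             selection = selectionConfig(),
                             finalClassifier = NULL,
                             quantizationBits = NULL, budget = NULL,
                             signalDuration = 10, windowPeriod = NULL,
                             outputDir = NULL, seed = 1L) {
  application <- match.arg(application)
  sfsMode <- match.arg(sfsMode)
  if (is.null(includeConstant))
    includeConstant <- application != "arrhythmia"
  structure(list(application = application, dataset = dataset,
                 includeConstant = includeConstant, channels = channels,
                 nPreselect = as.integer(nPreselect), sfsMode = sfsMode,
                 selection = selection, finalClassifier = finalClassifier,
                 quantizationBits = quantizationBits, budget = budget,
                 signalDuration = signalDuration,
                 windowPeriod = windowPeriod, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

runStage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[nuws] stage %-12s %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

sfsRun <- function(mode, candidates, fm, labels, mask, cfg) {
  switch(mode,
         basic = sfsBasic(candidates, fm, labels, mask, cfg),
         adapted = sfsAdapted(candidates, fm, labels, mask, cfg),
         optimized = sfsOptimized(candidates, fm, labels, mask, cfg))
}

#' Run a full A2F experiment
#'
#' Executes every stage in order and assembles the report: selection
#' trajectories, final test-set confusion matrix and metrics, extractor
#' accounting, compression ratio and (when a budget is configured) energy
#' breakdowns. The one-vs-all mode runs six binary searches and reports
#' per-class MCC. A rerun with the same config and seed is reproducible.
#'
#' @param cfg an [experimentConfig()].
#' @return an `ExperimentReport` (list).
#' @export
runExperiment <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  ds <- runStage("data", {
    if (!is.null(cfg$dataset)) cfg$dataset
    else if (cfg$application == "arrhythmia") simulateEcg(seed = cfg$seed)
    else simulateInertial(seed = cfg$seed)
  })
  mask <- trainMask(ds)
  labels <- datasetLabels(ds)
  channels <- cfg$channels %||% seq_len(dim(ds@windows)[2L])
  dict <- runStage("dictionary",
    haarDictionary(windowLen(ds), samplingRate(ds),
                   includeConstant = cfg$includeConstant))
  fm <- runStage("extract", extractMatrix(ds, dictionarySpecs(dict, channels)))
  candidates <- runStage("preselect",
    preselectTopK(fm, labels, k = cfg$nPreselect, rows = mask))
  if (!is.null(cfg$quantizationBits)) {
    fm <- runStage("quantize", {
      sub <- new("FeatureMatrix",
                 values = fm@values[, candidates$index, drop = FALSE],
                 specs = fm@specs[candidates$index], fs = fm@fs)
      q <- quantizeFeatures(sub, cfg$quantizationBits, mask)
      full <- fm
      full@values[, candidates$index] <- q@values
      full@quantized <- TRUE
      full@bits <- q@bits
      full
    })
  }
  selCfg <- cfg$selection
  if (is.null(selCfg$budget)) selCfg$budget <- cfg$budget
  finalSpec <- cfg$finalClassifier %||% selCfg$classifier

  defaultPeriod <- if (cfg$application == "arrhythmia") {
    windowLen(ds) / samplingRate(ds)            # contiguous windows
  } else {
    windowLen(ds) / samplingRate(ds) / 2        # 50% window overlap
  }
  windowPeriod <- cfg$windowPeriod %||% defaultPeriod

  evalFinal <- function(selection, y) {
    std <- standardizeFeatures(fm, mask)
    cols <- match(vapply(selection@specs, specKey, character(1)),
                  vapply(fm@specs, specKey, character(1)))
    model <- trainClassifier(finalSpec,
                             std$values[mask, cols, drop = FALSE], y[mask],
                             seed = selCfg$seed)
    evaluateClassifier(model, std$values[!mask, cols, drop = FALSE],
                       y[!mask])
  }

  if (cfg$application == "har_one_vs_all") {
    perClass <- lapply(levels(labels), function(cl) {
      y <- factor(ifelse(labels == cl, cl, "rest"),
                  levels = c("rest", cl))
      sel <- runStage(paste0("sfs:", cl),
        sfsRun(cfg$sfsMode, candidates, fm, y, mask, selCfg))
      list(selection = sel, metrics = evalFinal(sel, y))
    })
    names(perClass) <- levels(labels)
    selection <- NULL
    metrics <- NULL
    table2 <- reportTable2(perClass)
  } else {
    selection <- runStage("sfs",
      sfsRun(cfg$sfsMode, candidates, fm, labels, mask, selCfg))
    metrics <- runStage("evaluate", evalFinal(selection, labels))
    perClass <- NULL
    table2 <- NULL
  }

  nSamples <- windowLen(ds) * length(channels)
  nFeat <- if (!is.null(selection)) length(selection@specs) else
    sum(vapply(perClass, function(p) length(p$selection@specs), numeric(1)))
  energy <- NULL
  if (!is.null(cfg$budget) && !is.null(selection) &&
      length(selection@specs)) {
    energy <- list(
      nyquist = chainNyquist(cfg$signalDuration, cfg$budget),
      a2i = chainA2i(cfg$signalDuration, cfg$budget),
      a2f = chainA2f(cfg$signalDuration, selection@specs, windowPeriod,
                     cfg$budget),
      a2fInSensor = chainA2f(cfg$signalDuration, selection@specs,
                             windowPeriod, cfg$budget, inSensor = TRUE,
                             resultBits = ceiling(log2(nlevels(labels)))))
  }
  report <- structure(list(
    application = cfg$application, seed = cfg$seed, sfsMode = cfg$sfsMode,
    zeroRule = zeroRule(labels[mask], labels[!mask]),
    selection = selection, metrics = metrics, perClass = perClass,
    table2 = table2,
    compressionRatio = compressionRatio(nFeat, nSamples),
    energy = energy,
    pWavelet = if (!is.null(cfg$budget)) cfg$budget@pWavelet else NA_real_),
    class = "ExperimentReport")
  if (!is.null(cfg$outputDir)) writeExperimentReport(report, cfg$outputDir)
  report
}

specKey <- function(s) paste0(s$channel, "|", waveletKey(s$wavelet))

#' Extractor-accounting table for one-vs-all classification
#'
#' Tabulates, per binary classifier, the number of selected features, the
#' final metric (MCC), and the extractor totals split into wavelet-generator
#' and direct-integration extractors.
#'
#' @param perClass named list (one entry per class) of
#'   `list(selection = SelectionResult, metrics = MetricsReport)`.
#' @return a data.frame, one row per class.
#' @export
reportTable2 <- function(perClass) {
  if (!length(perClass) || is.null(names(perClass)) ||
      any(!nzchar(names(perClass))))
    stop("perClass must be a named list with one entry per class")
  rows <- lapply(names(perClass), function(cl) {
    p <- perClass[[cl]]
    sel <- p$selection
    if (!length(sel@specs)) stop("empty selection for class '", cl, "'")
    last <- nrow(sel@extractors)
    data.frame(class = cl, nFeatures = length(sel@specs),
               metric = if (!is.null(p$metrics)) p$metrics@mcc else
                 sel@metric[length(sel@metric)],
               extractors = sel@extractors[last, "total"],
               withGenerator = sel@extractors[last, "generator"],
               directIntegration = sel@extractors[last, "direct"])
  })
  do.call(rbind, rows)
}

#' Write an experiment report as JSON
#'
#' @param report an `ExperimentReport`.
#' @param dir output directory (created if missing).
#' @return the report path, invisibly.
#' @export
writeExperimentReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  serializeSelection <- function(sel) {
    if (is.null(sel)) return(NULL)
    list(mode = sel@mode,
         specs = lapply(sel@specs, function(s)
           list(channel = s$channel, family = s$wavelet@family,
                period = s$wavelet@period, support = s$wavelet@support,
                shift = s$wavelet@shift)),
         metric = sel@metric, energy = sel@energy,
         extractors = as.data.frame(sel@extractors),
         boundStep = sel@boundStep)
  }
  obj <- list(
    application = report$application, seed = report$seed,
    sfsMode = report$sfsMode, zeroRule = report$zeroRule,
    selection = serializeSelection(report$selection),
    metrics = if (!is.null(report$metrics)) list(
      accuracy = report$metrics@accuracy,
      sensitivity = report$metrics@sensitivity,
      specificity = report$metrics@specificity,
      mcc = report$metrics@mcc,
      confusion = unname(as.matrix(report$metrics@confusion))) else NULL,
    perClass = if (!is.null(report$perClass))
      lapply(report$perClass, function(p) list(
        selection = serializeSelection(p$selection),
        mcc = p$metrics@mcc)) else NULL,
    table2 = report$table2,
    compressionRatio = report$compressionRatio,
    energy = if (!is.null(report$energy)) lapply(report$energy, function(e)
      list(chain = e@chain, acquisition = e@acquisition,
           transmission = e@transmission,
           classification = e@classification, total = e@total)) else NULL,
    pWavelet = report$pWavelet)
  path <- file.path(dir, "report.json")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null", null = "null"), path)
  invisible(path)
}
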