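# Feature selection: information-gain filter ranking, greedy interval
# scheduling of wavelet supports onto parallel extractors, and the three
# sequential forward search (SFS) variants wrapped around the classifier.

shannonEntropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of one feature
#'
#' Discretizes the feature into `nBins` equal-width intervals over its
#' observed range and computes the entropy reduction of the class label,
#' `IG = H(D) - sum_i (|D_i|/|D|) H(D_i)`, in bits. Empty bins contribute
#' nothing; a constant feature has zero gain. Invariant under positive
#' affine transforms of the feature.
#'
#' @param values numeric feature column.
#' @param labels class labels, same length.
#' @param nBins number of equal-width discretization intervals (default 12).
#' @return information gain in bits.
#' @export
informationGain <- function(values, labels, nBins = 12L) {
  if (length(values) != length(labels))
    stop("values (", length(values), ") and labels (", length(labels),
         ") lengths differ")
  stopifnot(all(is.finite(values)), length(values) >= 1)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(0)
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  h <- shannonEntropy(labels)
  cond <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    cond <- cond + sum(sel) / length(values) * shannonEntropy(labels[sel])
  }
  h - cond
}

#' Pre-select the top-k features by information gain
#'
#' Ranks every feature column by IG (descending, ties broken by dictionary
#' order) and keeps the first `min(k, n_features)`. Used to shrink the SFS
#' candidate pool, whose cost is quadratic in the pool size.
#'
#' @param fm a [FeatureMatrix-class].
#' @param labels class labels for the ranked rows.
#' @param k pool size (default 100).
#' @param nBins discretization bins for [informationGain()].
#' @param rows optional logical/integer row subset to rank on (e.g. the
#'   training split); defaults to all rows.
#' @return list with `specs` (ranked feature specs), `index` (column indices
#'   into `fm` in rank order) and `ig` (their gains).
#' @export
preselectTopK <- function(fm, labels, k = 100L, nBins = 12L, rows = NULL) {
  stopifnot(k >= 1)
  vals <- fm@values
  if (!is.null(rows)) {
    vals <- vals[rows, , drop = FALSE]
    labels <- labels[rows]
  }
  ig <- vapply(seq_len(ncol(vals)), function(j)
    informationGain(vals[, j], labels, nBins), numeric(1))
  ord <- order(-ig, seq_along(ig))
  keep <- ord[seq_len(min(k, length(ord)))]
  list(specs = fm@specs[keep], index = keep, ig = ig[keep])
}

#' Schedule features onto parallel extractors
#'
#' Greedy interval partitioning: supports sorted by start time are assigned
#' to the first extractor whose latest interval ends on or before the new
#' start. For interval graphs this greedy is optimal, so the extractor count
#' equals the maximum temporal overlap depth. Extractors are channel-
#' agnostic (an input multiplexer selects the signal); extractors serving a
#' constant wavelet perform direct integration (no wavelet generator) and,
#' because that support spans the whole window, hold that single feature.
#'
#' @param specs list of feature specs sharing one window length.
#' @return an [ExtractorSchedule-class].
#' @export
scheduleExtractors <- function(specs) {
  n <- length(specs)
  if (n == 0L)
    return(new("ExtractorSchedule", assignment = integer(0),
               intervals = list(), nExtractors = 0L, nGenerator = 0L,
               nDirect = 0L))
  start <- vapply(specs, function(s) s$wavelet@shift, integer(1))
  end <- start + vapply(specs, function(s) s$wavelet@support, integer(1))
  isConst <- vapply(specs, function(s) s$wavelet@family == "constant",
                    logical(1))
  ord <- order(start, end)
  assignment <- integer(n)
  extEnd <- numeric(0)          # latest end per extractor
  extConst <- logical(0)        # serves a constant wavelet
  for (i in ord) {
    free <- which(extEnd <= start[i])
    if (length(free)) {
      e <- free[1L]
    } else {
      extEnd <- c(extEnd, -Inf)
      extConst <- c(extConst, FALSE)
      e <- length(extEnd)
    }
    assignment[i] <- e
    extEnd[e] <- end[i]
    extConst[e] <- extConst[e] || isConst[i]
  }
  intervals <- lapply(seq_along(extEnd), function(e) {
    idx <- which(assignment == e)
    cbind(start = start[idx], end = end[idx])
  })
  new("ExtractorSchedule", assignment = assignment, intervals = intervals,
      nExtractors = length(extEnd),
      nGenerator = as.integer(sum(!extConst)),
      nDirect = as.integer(sum(extConst)))
}

#' @describeIn nExtractors schedule size
#' @export
setMethod("nExtractors", "ExtractorSchedule", function(x) x@nExtractors)

setMethod("show", "ExtractorSchedule", function(object) {
  cat(sprintf(
    "ExtractorSchedule: %d extractors (%d with generator, %d direct) for %d features\n",
    object@nExtractors, object@nGenerator, object@nDirect,
    length(object@assignment)))
})

#' Selection configuration
#'
#' @param nfMax maximum number of selected features.
#' @param nExtMax maximum number of parallel extractors (adapted/optimized
#'   variants).
#' @param lambda energy-penalty weight of the optimized variant; the score
#'   is `accuracy - lambda * E(S + F) / eRef`. `lambda = 0` reduces the
#'   optimized search exactly to the adapted one.
#' @param monotoneStop stop as soon as the best candidate no longer improves
#'   the metric (the optional early-exit of the basic search).
#' @param seed base RNG seed; per-(step, candidate) training seeds are
#'   derived from it so selection is bit-reproducible.
#' @param classifier a [classifierSpec()] used as the inner evaluator.
#' @param evalPolicy `"validation"` (default): candidate subsets are scored
#'   on a held-out fraction of the training rows; `"test"`: scored on the
#'   test split (matches the original study protocol but leaks the test
#'   set into selection).
#' @param valFraction held-out fraction for `evalPolicy = "validation"`.
#' @param budget optional [powerBudget()] enabling energy trajectories and
#'   the optimized score.
#' @param eRef energy normalizer of the optimized score; defaults to the
#'   energy of a full-window Haar feature under `budget`.
#' @return a `SelectionConfig` (list).
#' @export
selectionConfig <- function(nfMax = 10L, nExtMax = NA_integer_, lambda = 0,
                            monotoneStop = FALSE, seed = 1L,
                            classifier = classifierSpec(),
                            evalPolicy = c("validation", "test"),
                            valFraction = 0.25, budget = NULL, eRef = NULL) {
  evalPolicy <- match.arg(evalPolicy)
  stopifnot(nfMax >= 0, lambda >= 0, is.na(nExtMax) || nExtMax >= 1,
            valFraction > 0, valFraction < 1)
  structure(list(nfMax = as.integer(nfMax), nExtMax = as.integer(nExtMax),
                 lambda = lambda, monotoneStop = monotoneStop,
                 seed = as.integer(seed), classifier = classifier,
                 evalPolicy = evalPolicy, valFraction = valFraction,
                 budget = budget, eRef = eRef),
            class = "SelectionConfig")
}

# Deterministic per-(step, candidate) training seed, kept within 32 bits.
derivedSeed <- function(base, step, candidate) {
  as.integer((as.numeric(base) * 7919 + step * 104729 + candidate * 131) %%
               2147483629)
}

selectionEnergy <- function(specs, budget) {
  if (is.null(budget)) return(NA_real_)
  sum(vapply(specs, function(s) featureEnergy(s$wavelet, budget),
             numeric(1)))
}

# Shared engine behind the three SFS variants. `candidates` is the ranked
# pool from preselectTopK; fm holds (at least) those columns; trainMask
# selects the training rows of fm/labels.
sfsEngine <- function(candidates, fm, labels, trainMask, cfg, mode) {
  stopifnot(is(fm, "FeatureMatrix"))
  idx <- candidates$index
  if (length(idx) == 0L) stop("empty candidate list")
  labels <- as.factor(labels)
  constrained <- mode %in% c("adapted", "optimized")
  if (constrained && is.na(cfg$nExtMax))
    stop("nExtMax must be set for the ", mode, " search")
  lambda <- if (mode == "optimized") cfg$lambda else 0
  if (mode == "optimized" && lambda > 0 && is.null(cfg$budget))
    stop("a power budget is required when lambda > 0")
  eRef <- cfg$eRef
  if (is.null(eRef) && !is.null(cfg$budget)) {
    wl <- fm@specs[[idx[1L]]]$wavelet
    eRef <- featureEnergy(
      newWavelet("haar", wl@windowLen, wl@windowLen, 0L, wl@windowLen,
                 wl@fs), cfg$budget)
  }

  std <- standardizeFeatures(fm, trainMask)
  X <- std$values

  trainRows <- which(trainMask)
  if (cfg$evalPolicy == "validation") {
    set.seed(cfg$seed)
    # stratified hold-out so every class stays present in the inner split
    valRows <- unlist(lapply(split(trainRows, labels[trainRows]),
                             function(r)
                               sample(r, max(1L, round(length(r) *
                                                         cfg$valFraction)))))
    fitRows <- setdiff(trainRows, valRows)
  } else {
    fitRows <- trainRows
    valRows <- which(!trainMask)
  }
  yFit <- labels[fitRows]
  yVal <- labels[valRows]

  selected <- integer(0)        # positions within the candidate ranking
  stepMetric <- numeric(0)
  stepEnergy <- numeric(0)
  stepExt <- NULL
  boundStep <- NA_integer_
  bestSoFar <- -Inf

  for (step in seq_len(cfg$nfMax)) {
    remaining <- setdiff(seq_along(idx), selected)
    if (!length(remaining)) break
    if (constrained) {
      remaining <- remaining[vapply(remaining, function(r) {
        sch <- scheduleExtractors(fm@specs[idx[c(selected, r)]])
        sch@nExtractors <= cfg$nExtMax
      }, logical(1))]
      if (!length(remaining)) break
    }
    acc <- numeric(length(remaining))
    score <- numeric(length(remaining))
    for (m in seq_along(remaining)) {
      r <- remaining[m]
      cols <- idx[c(selected, r)]
      model <- trainClassifier(cfg$classifier,
                               X[fitRows, cols, drop = FALSE], yFit,
                               seed = derivedSeed(cfg$seed, step, r))
      acc[m] <- mean(predict(model, X[valRows, cols, drop = FALSE]) == yVal)
      score[m] <- acc[m]
      if (lambda > 0)
        score[m] <- acc[m] - lambda *
          selectionEnergy(fm@specs[idx[c(selected, r)]], cfg$budget) / eRef
    }
    best <- which.max(score)    # ties resolve to the lowest candidate rank
    if (cfg$monotoneStop && score[best] <= bestSoFar) break
    bestSoFar <- score[best]
    selected <- c(selected, remaining[best])
    stepMetric <- c(stepMetric, acc[best])
    stepEnergy <- c(stepEnergy,
                    selectionEnergy(fm@specs[idx[selected]], cfg$budget))
    sch <- scheduleExtractors(fm@specs[idx[selected]])
    stepExt <- rbind(stepExt, c(total = sch@nExtractors,
                                generator = sch@nGenerator,
                                direct = sch@nDirect))
    if (constrained && is.na(boundStep) && sch@nExtractors == cfg$nExtMax)
      boundStep <- step
  }
  extMat <- matrix(if (is.null(stepExt)) integer(0) else
    as.integer(stepExt), ncol = 3L,
    dimnames = list(NULL, c("total", "generator", "direct")))
  new("SelectionResult", specs = fm@specs[idx[selected]],
      candidateIndex = as.integer(selected), metric = stepMetric,
      energy = stepEnergy, extractors = extMat,
      boundStep = boundStep, mode = mode)
}

#' Basic sequential forward search
#'
#' Starting from an empty target set, each step retrains a fresh classifier
#' for every remaining candidate joined to the current set and adds the
#' candidate with the highest evaluation accuracy (ties go to the stronger
#' filter rank). With `monotoneStop` the search ends as soon as no candidate
#' improves the running best, yielding a non-decreasing trajectory.
#'
#' @param candidates ranked candidate pool from [preselectTopK()].
#' @param fm the [FeatureMatrix-class] the pool indexes into.
#' @param labels class labels for all rows of `fm`.
#' @param trainMask logical vector marking training rows.
#' @param cfg a [selectionConfig()].
#' @return a [SelectionResult-class].
#' @export
sfsBasic <- function(candidates, fm, labels, trainMask, cfg)
  sfsEngine(candidates, fm, labels, trainMask, cfg, "basic")

#' Adapted (extractor-constrained) sequential forward search
#'
#' As [sfsBasic()], but a candidate is admissible only if the minimum
#' extractor count of the augmented set (its interval-overlap depth) stays
#' within `cfg$nExtMax`. The step at which the bound is first fully used is
#' recorded in `boundStep`.
#'
#' @inheritParams sfsBasic
#' @return a [SelectionResult-class].
#' @export
sfsAdapted <- function(candidates, fm, labels, trainMask, cfg)
  sfsEngine(candidates, fm, labels, trainMask, cfg, "adapted")

#' Optimized (energy-aware) sequential forward search
#'
#' As [sfsAdapted()], but candidates are scored by
#' `accuracy - lambda * E(S + F) / eRef`, with `E` the per-window extraction
#' energy of the augmented set under `cfg$budget` and `eRef` a configured
#' normalizer (default: the energy of a full-window feature). With
#' `lambda = 0` the scores equal the accuracies and the search reproduces
#' the adapted variant exactly.
#'
#' @inheritParams sfsBasic
#' @return a [SelectionResult-class].
#' @export
sfsOptimized <- function(candidates, fm, labels, trainMask, cfg)
  sfsEngine(candidates, fm, labels, trainMask, cfg, "optimized")

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d features selected\n", object@mode,
              length(object@specs)))
  if (length(object@metric))
    cat(sprintf("  final metric %.4f; extractors %d (%d gen, %d direct)\n",
                object@metric[length(object@metric)],
                object@extractors[nrow(object@extractors), "total"],
                object@extractors[nrow(object@extractors), "generator"],
                object@extractors[nrow(object@extractors), "direct"]))
})

#' @describeIn featureSpecs selected specs of a search result
#' @export
setMethod("featureSpecs", "SelectionResult", function(x) x@specs)

#' Serialize a selection result to JSON
#'
#' Specs are written as (channel, family, period, support, shift) records
#' with the metric/energy/extractor trajectories as arrays.
#'
#' @param res a [SelectionResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionResult <- function(res, path) {
  specs <- lapply(res@specs, function(s)
    list(channel = s$channel, family = s$wavelet@family,
         period = s$wavelet@period, support = s$wavelet@support,
         shift = s$wavelet@shift))
  obj <- list(mode = res@mode, specs = specs, metric = res@metric,
              energy = res@energy,
              extractors = as.data.frame(res@extractors),
              boundStep = res@boundStep)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}
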