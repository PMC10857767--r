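#' @import methods
NULL

#' Wavelet atom
#'
#' A single wavelet of the analysis dictionary, parameterized by its family,
#' oscillation period, support duration and time shift inside a fixed-size
#' analysis window. Frequencies are stored exactly as integer periods in
#' samples; the oscillation frequency in Hz is derived as `fs / period` to
#' keep the enumeration free of floating-point drift.
#'
#' @slot family character, one of `"haar"`, `"gabor"`, `"constant"`.
#' @slot period integer, oscillation period in samples (0 for constant).
#' @slot support integer, support duration t_s in samples.
#' @slot shift integer, time shift from window start, in samples.
#' @slot windowLen integer, analysis-window length in samples.
#' @slot fs numeric, signal sampling rate in Hz.
#' @slot gaborSigma numeric, Gaussian envelope width in samples (gabor only).
#' @slot gaborPhase numeric, carrier phase in radians (gabor only).
#' @slot polarity numeric, +1 or -1; sign of the leading haar half-period.
#'
#' @export
setClass("Wavelet",
  representation(
    family = "character",
    period = "integer",
    support = "integer",
    shift = "integer",
    windowLen = "integer",
    fs = "numeric",
    gaborSigma = "numeric",
    gaborPhase = "numeric",
    polarity = "numeric"
  ),
  prototype(
    family = "haar", gaborSigma = NA_real_, gaborPhase = NA_real_,
    polarity = 1
  )
)

setValidity("Wavelet", function(object) {
  msg <- character()
  if (!object@family %in% c("haar", "gabor", "constant"))
    msg <- c(msg, sprintf("unknown family '%s'", object@family))
  if (object@shift < 0L || object@shift + object@support > object@windowLen)
    msg <- c(msg, "support [shift, shift + support) must lie inside the window")
  if (object@family == "haar") {
    p <- object@period
    if (p < 2L || p %% 2L != 0L)
      msg <- c(msg, "haar period must be an even integer >= 2 samples")
    else {
      r <- object@support / p
      if (r < 1 || abs(log2(r) - round(log2(r))) > 1e-9)
        msg <- c(msg, "haar support must be a power-of-two multiple of the period")
    }
  }
  if (object@family == "constant") {
    if (object@support != object@windowLen || object@shift != 0L ||
        object@period != 0L)
      msg <- c(msg, "constant wavelet must span the full window with zero shift")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Wavelet dictionary
#'
#' An ordered collection of [Wavelet-class] atoms over a common analysis
#' window, together with a record of the enumeration rules that produced it.
#'
#' @slot wavelets list of [Wavelet-class].
#' @slot windowLen integer, samples.
#' @slot fs numeric, Hz.
#' @slot constructionParams list describing the enumeration rules used.
#'
#' @export
setClass("WaveletDictionary",
  representation(
    wavelets = "list",
    windowLen = "integer",
    fs = "numeric",
    constructionParams = "list"
  )
)

setValidity("WaveletDictionary", function(object) {
  keys <- vapply(object@wavelets, waveletKey, character(1))
  if (anyDuplicated(keys)) return("duplicate wavelet entries in dictionary")
  ok <- vapply(object@wavelets, function(w)
    w@windowLen == object@windowLen, logical(1))
  if (!all(ok)) return("all wavelets must share the dictionary window length")
  TRUE
})

#' Windowed multichannel dataset
#'
#' Fixed-length analysis windows of a multichannel signal with class labels
#' and a train/test split tag per window.
#'
#' @slot windows numeric array `[n_windows, n_channels, window_len]`.
#' @slot labels factor of length `n_windows`.
#' @slot fs numeric, sampling rate in Hz.
#' @slot channelNames character.
#' @slot split factor (`"train"`/`"test"`) of length `n_windows`.
#'
#' @export
setClass("WindowedDataset",
  representation(
    windows = "array",
    labels = "factor",
    fs = "numeric",
    channelNames = "character",
    split = "factor"
  )
)

setValidity("WindowedDataset", function(object) {
  d <- dim(object@windows)
  if (length(d) != 3L) return("windows must be a 3-D array")
  if (length(object@labels) != d[1L]) return("one label per window required")
  if (length(object@split) != d[1L]) return("one split tag per window required")
  if (length(object@channelNames) != d[2L])
    return("one channel name per channel required")
  if (!all(levels(object@split) %in% c("train", "test")))
    return("split levels must be 'train'/'test'")
  if (any(!is.finite(object@windows))) return("windows must be finite")
  TRUE
})

#' Feature matrix
#'
#' NUWS feature values for a set of windows, one column per feature spec
#' (a channel/wavelet pair).
#'
#' @slot values numeric matrix `[n_windows, n_features]`.
#' @slot specs list of feature specs; each is a `list(channel =, wavelet =)`.
#' @slot fs numeric, Hz of the originating dataset.
#' @slot quantized logical.
#' @slot bits integer, bit depth if quantized, otherwise `NA`.
#'
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    specs = "list",
    fs = "numeric",
    quantized = "logical",
    bits = "integer"
  ),
  prototype(quantized = FALSE, bits = NA_integer_)
)

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@values) != length(object@specs))
    return("one spec per value column required")
  if (any(!is.finite(object@values))) return("feature values must be finite")
  TRUE
})

#' Extractor schedule
#'
#' Assignment of selected features to parallel hardware extractors such that
#' wavelet supports served by one extractor never overlap inside the analysis
#' window. Extractors serving a constant (full-window) wavelet perform direct
#' integration and need no wavelet generator.
#'
#' @slot assignment integer vector, extractor index per feature.
#' @slot intervals list per extractor of `cbind(start, end)` sample intervals.
#' @slot nExtractors integer, total extractors used.
#' @slot nGenerator integer, extractors equipped with a wavelet generator.
#' @slot nDirect integer, direct-integration extractors.
#'
#' @export
setClass("ExtractorSchedule",
  representation(
    assignment = "integer",
    intervals = "list",
    nExtractors = "integer",
    nGenerator = "integer",
    nDirect = "integer"
  )
)

setValidity("ExtractorSchedule", function(object) {
  if (object@nGenerator + object@nDirect != object@nExtractors)
    return("generator + direct extractor counts must equal the total")
  for (iv in object@intervals) {
    if (nrow(iv) > 1L) {
      o <- order(iv[, 1L])
      if (any(iv[o, 1L][-1L] < iv[o, 2L][-nrow(iv)]))
        return("intervals within one extractor must be pairwise disjoint")
    }
  }
  TRUE
})

#' Selection result
#'
#' Ordered outcome of a sequential forward search: selected feature specs and
#' the per-step metric, energy and extractor-count trajectories.
#'
#' @slot specs list of selected feature specs, in selection order.
#' @slot candidateIndex integer, index of each pick in the candidate ranking.
#' @slot metric numeric, evaluation metric after each step.
#' @slot energy numeric, total per-window extraction energy (J) after each
#'   step (`NA` when no power budget was configured).
#' @slot extractors integer matrix, columns `total`, `generator`, `direct`.
#' @slot boundStep integer, first step at which the extractor budget
#'   `nExtMax` is fully used (`NA` if never, or unconstrained search).
#' @slot mode character, `"basic"`, `"adapted"` or `"optimized"`.
#'
#' @export
setClass("SelectionResult",
  representation(
    specs = "list",
    candidateIndex = "integer",
    metric = "numeric",
    energy = "numeric",
    extractors = "matrix",
    boundStep = "integer",
    mode = "character"
  )
)

setValidity("SelectionResult", function(object) {
  n <- length(object@specs)
  if (length(object@metric) != n || nrow(object@extractors) != n ||
      length(object@energy) != n || length(object@candidateIndex) != n)
    return("trajectory lengths must equal the number of selection steps")
  if (n && any(object@extractors[, "generator"] +
               object@extractors[, "direct"] != object@extractors[, "total"]))
    return("generator + direct must equal total at every step")
  TRUE
})

#' Power budget
#'
#' All power and rate constants of the sensor-node energy model: per-feature
#' extraction cost and the Nyquist / analog-to-information (A2I) / A2F
#' communication chains. Every field is in base SI units (W, Hz, J, s).
#' `pWavelet` (digital wavelet-generator power) has no published value and is
#' therefore a required argument; reports echo the value used.
#'
#' @slot pAmp numeric, amplification-stage power (W).
#' @slot pInt numeric, integrator power (W).
#' @slot pWavelet numeric, wavelet-generator power (W).
#' @slot pAdc numeric, ADC power (W).
#' @slot fsAdc numeric, ADC sampling rate (Hz).
#' @slot adcBits integer, ADC precision (bits).
#' @slot eBit numeric, radio energy per transmitted bit (J/bit).
#' @slot pLpf numeric, anti-aliasing filter power (W), Nyquist chain.
#' @slot fsNyq numeric, Nyquist-chain sampling rate (Hz).
#' @slot pA2i numeric, A2I converter power (W).
#' @slot a2iCompression numeric, A2I compression ratio.
#' @slot pClass numeric, in-sensor classifier power (W).
#' @slot tClass numeric, time per classification (s).
#' @slot nChannelsNyq integer, channels sampled by the Nyquist chain.
#'
#' @export
setClass("PowerBudget",
  representation(
    pAmp = "numeric", pInt = "numeric", pWavelet = "numeric",
    pAdc = "numeric", fsAdc = "numeric", adcBits = "integer",
    eBit = "numeric", pLpf = "numeric", fsNyq = "numeric",
    pA2i = "numeric", a2iCompression = "numeric",
    pClass = "numeric", tClass = "numeric", nChannelsNyq = "integer"
  )
)

setValidity("PowerBudget", function(object) {
  vals <- c(object@pAmp, object@pInt, object@pWavelet, object@pAdc,
            object@fsAdc, object@eBit, object@pLpf, object@fsNyq,
            object@pA2i, object@a2iCompression, object@pClass, object@tClass)
  if (any(vals < 0)) return("all powers, rates and energies must be >= 0")
  if (object@adcBits < 1L) return("adcBits must be >= 1")
  TRUE
})

#' Energy breakdown
#'
#' Acquisition / transmission / classification energy split for one
#' communication-chain configuration over a fixed signal duration.
#'
#' @slot acquisition numeric (J).
#' @slot transmission numeric (J).
#' @slot classification numeric (J).
#' @slot total numeric (J).
#' @slot perFeature numeric, per-feature per-window itemization (J), possibly
#'   empty for sample-based chains.
#' @slot chain character label (`"nyquist"`, `"a2i"`, `"a2f"`).
#'
#' @export
setClass("EnergyBreakdown",
  representation(
    acquisition = "numeric",
    transmission = "numeric",
    classification = "numeric",
    total = "numeric",
    perFeature = "numeric",
    chain = "character"
  )
)

setValidity("EnergyBreakdown", function(object) {
  parts <- c(object@acquisition, object@transmission, object@classification)
  if (any(parts < 0)) return("energy components must be >= 0")
  if (abs(object@total - sum(parts)) >
      1e-12 * max(1, abs(object@total)))
    return("total must equal the sum of its parts")
  TRUE
})

#' Classification metrics report
#'
#' Confusion matrix and derived metrics. For binary problems the second
#' factor level is the positive class; sensitivity, specificity and the
#' Matthews correlation coefficient (MCC) follow that convention. For
#' multiclass problems per-class recall/precision are reported and the
#' binary-only metrics are `NA`. An MCC whose denominator contains a zero
#' factor is reported as 0 with `degenerate = TRUE`.
#'
#' @slot confusion integer matrix, rows = truth, columns = prediction.
#' @slot accuracy numeric.
#' @slot sensitivity numeric (binary; recall of the positive class).
#' @slot specificity numeric (binary).
#' @slot mcc numeric (binary).
#' @slot perClass data.frame with `recall` and `precision` per class.
#' @slot degenerate logical, `TRUE` when the MCC denominator vanished.
#'
#' @export
setClass("MetricsReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    mcc = "numeric",
    perClass = "data.frame",
    degenerate = "logical"
  ),
  prototype(degenerate = FALSE)
)

setValidity("MetricsReport", function(object) {
  if (any(object@confusion < 0)) return("confusion entries must be >= 0")
  rates <- c(object@accuracy, object@sensitivity, object@specificity)
  rates <- rates[!is.na(rates)]
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  if (!is.na(object@mcc) && (object@mcc < -1 || object@mcc > 1))
    return("MCC must lie in [-1, 1]")
  TRUE
})
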