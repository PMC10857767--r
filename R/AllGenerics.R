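#' Sampled waveform of a wavelet
#'
#' Renders a wavelet atom as a length-`windowLen` amplitude sequence. Haar
#' atoms alternate between +1 and -1 half-period by half-period inside their
#' support and are 0 elsewhere; the constant atom is +1 across the whole
#' window; Gabor atoms are the real part of a Gaussian-windowed sinusoid on
#' the support, numerically de-meaned so the support sum is (near) zero.
#'
#' @param w a [Wavelet-class].
#' @return numeric vector of length `windowLen(w)`.
#' @examples
#' w <- haarDictionary(8, 360)@wavelets[[1]]
#' waveform(w)
#' @export
setGeneric("waveform", function(w) standardGeneric("waveform"))

#' Number of wavelets in a dictionary
#' @param x a [WaveletDictionary-class].
#' @param ... ignored.
#' @return integer.
#' @export
setGeneric("nWavelets", function(x, ...) standardGeneric("nWavelets"))

#' Window length accessor
#' @param x an object with an analysis-window length.
#' @return integer, samples.
#' @export
setGeneric("windowLen", function(x) standardGeneric("windowLen"))

#' Sampling-rate accessor
#' @param x an object carrying a sampling rate.
#' @return numeric, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Feature-spec accessor
#' @param x a [FeatureMatrix-class] or [SelectionResult-class].
#' @return list of feature specs (`list(channel =, wavelet =)`).
#' @export
setGeneric("featureSpecs", function(x) standardGeneric("featureSpecs"))

#' Feature-value accessor
#' @param x a [FeatureMatrix-class].
#' @return numeric matrix `[n_windows, n_features]`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Number of extractors accessor
#' @param x an [ExtractorSchedule-class].
#' @return integer.
#' @export
setGeneric("nExtractors", function(x) standardGeneric("nExtractors"))

#' Confusion-matrix accessor
#' @param x a [MetricsReport-class].
#' @return integer matrix, rows = truth, columns = prediction.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' Accuracy accessor
#' @param x a [MetricsReport-class].
#' @return numeric in \[0, 1\].
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
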