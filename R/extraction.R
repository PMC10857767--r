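# NUWS feature extraction: mixing a windowed signal with a wavelet and
# integrating over the wavelet support. Integration is a Riemann sum scaled
# by 1/fs, so features carry signal-units x seconds; the scale is immaterial
# to classification but fixed for reproducibility.

#' Create a feature spec
#'
#' Binds one wavelet to one signal channel.
#'
#' @param channel integer channel index (1-based).
#' @param wavelet a [Wavelet-class].
#' @return a feature spec (`list(channel, wavelet)`).
#' @export
featureSpec <- function(channel, wavelet) {
  stopifnot(is(wavelet, "Wavelet"), channel >= 1)
  list(channel = as.integer(channel), wavelet = wavelet)
}

#' All channel x wavelet feature specs of a dictionary
#'
#' @param dict a [WaveletDictionary-class].
#' @param channels integer vector of channel indices.
#' @return list of feature specs, wavelets varying fastest within a channel.
#' @export
dictionarySpecs <- function(dict, channels = 1L) {
  out <- vector("list", length(channels) * nWavelets(dict))
  k <- 0L
  for (ch in channels) {
    for (w in dict@wavelets) {
      k <- k + 1L
      out[[k]] <- featureSpec(ch, w)
    }
  }
  out
}

#' Extract one NUWS feature
#'
#' Multiplies one channel's window by the sampled wavelet and integrates
#' (Riemann sum scaled by `1/fs`). Linear in the signal: a zero-mean wavelet
#' annihilates constant signals, while the constant wavelet returns the
#' window mean times its duration.
#'
#' @param window numeric vector, one channel's samples.
#' @param w a [Wavelet-class] with matching `windowLen`.
#' @param fs sampling rate, Hz.
#' @return scalar feature value (signal-units x seconds).
#' @examples
#' w <- haarDictionary(8, 100)@wavelets[[1]]
#' extractFeature(waveform(w), w, 100)  # support / fs
#' @export
extractFeature <- function(window, w, fs) {
  if (length(window) != w@windowLen)
    stop("window length ", length(window),
         " does not match wavelet window length ", w@windowLen)
  sum(window * waveform(w)) / fs
}

#' Extract a feature matrix from a windowed dataset
#'
#' Computes `extractFeature` for every (window, spec) pair. Columns agree
#' with the scalar operation; extraction is vectorized per channel via a
#' waveform matrix product.
#'
#' @param ds a [WindowedDataset-class].
#' @param specs list of feature specs (see [featureSpec()]).
#' @return a [FeatureMatrix-class].
#' @export
extractMatrix <- function(ds, specs) {
  d <- dim(ds@windows)
  nWin <- d[1L]; nCh <- d[2L]; len <- d[3L]
  chans <- vapply(specs, function(s) s$channel, integer(1))
  if (length(specs) && (any(chans < 1L) || any(chans > nCh)))
    stop("unknown channel in feature specs (dataset has ", nCh, " channels)")
  vals <- matrix(0, nrow = nWin, ncol = length(specs))
  if (length(specs)) {
    for (ch in unique(chans)) {
      cols <- which(chans == ch)
      psi <- vapply(specs[cols], function(s) waveform(s$wavelet),
                    numeric(len))
      vals[, cols] <- (ds@windows[, ch, , drop = TRUE] %*% psi) / ds@fs
    }
  }
  new("FeatureMatrix", values = vals, specs = specs, fs = ds@fs)
}

#' @describeIn featureSpecs feature-matrix specs
#' @export
setMethod("featureSpecs", "FeatureMatrix", function(x) x@specs)

#' @describeIn featureValues feature-matrix values
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d windows x %d features%s\n",
              nrow(object@values), ncol(object@values),
              if (object@quantized)
                sprintf(" (quantized, %d bits)", object@bits) else ""))
})

#' Quantize a feature matrix
#'
#' Uniform mid-tread quantization to `2^bits` levels per feature. The
#' feature range `[min, max]` is learned on the training rows (mirroring a
#' fixed-range ADC calibrated on training data); the level spacing is
#' `(max - min) / (2^bits - 1)`, values outside the learned range are
#' clipped, and each value is mapped to the nearest level. Idempotent for a
#' fixed configuration.
#'
#' @param fm a [FeatureMatrix-class].
#' @param bits integer >= 1, quantizer resolution.
#' @param trainMask logical vector selecting the training rows used to learn
#'   the per-feature ranges.
#' @return a quantized [FeatureMatrix-class].
#' @export
quantizeFeatures <- function(fm, bits, trainMask) {
  if (length(bits) != 1L || bits < 1) stop("bits must be >= 1, got ", bits)
  bits <- as.integer(bits)
  stopifnot(length(trainMask) == nrow(fm@values), sum(trainMask) >= 1)
  vals <- fm@values
  nLevels <- 2^bits
  for (j in seq_len(ncol(vals))) {
    lo <- min(vals[trainMask, j]); hi <- max(vals[trainMask, j])
    if (hi > lo) {
      step <- (hi - lo) / (nLevels - 1)
      q <- round((pmin(pmax(vals[, j], lo), hi) - lo) / step)
      vals[, j] <- lo + q * step
    } else {
      vals[, j] <- lo
    }
  }
  new("FeatureMatrix", values = vals, specs = fm@specs, fs = fm@fs,
      quantized = TRUE, bits = bits)
}

#' Z-score standardize a feature matrix
#'
#' Centers and scales each feature using training-split statistics (applied
#' after optional quantization, before classifier input). Zero-variance
#' features are centered only.
#'
#' @inheritParams quantizeFeatures
#' @return list with `values` (standardized matrix), `center`, `scale`.
#' @export
standardizeFeatures <- function(fm, trainMask) {
  vals <- if (is(fm, "FeatureMatrix")) fm@values else fm
  stopifnot(length(trainMask) == nrow(vals))
  ctr <- colMeans(vals[trainMask, , drop = FALSE])
  scl <- apply(vals[trainMask, , drop = FALSE], 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(values = scale(vals, center = ctr, scale = scl), center = ctr,
       scale = scl)
}

#' Write a feature matrix to CSV
#'
#' Header columns describe each spec (`channel|family|period|support|shift`);
#' values are printed at full double precision so the round trip through
#' [readFeatureMatrix()] is exact for unquantized doubles.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  hdr <- vapply(fm@specs, function(s)
    sprintf("%d|%s|%d|%d|%d", s$channel, s$wavelet@family,
            s$wavelet@period, s$wavelet@support, s$wavelet@shift),
    character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s windowLen=%d quantized=%d bits=%d",
                     format(fm@fs, digits = 17),
                     if (length(fm@specs)) fm@specs[[1]]$wavelet@windowLen
                     else 0L,
                     as.integer(fm@quantized),
                     ifelse(is.na(fm@bits), -1L, fm@bits)), con)
  writeLines(paste(hdr, collapse = ","), con)
  apply(fm@values, 1L, function(r)
    writeLines(paste(format(r, digits = 17), collapse = ","), con))
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path file path.
#' @return a [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
  lines <- readLines(path)
  meta <- regmatches(lines[1L],
    regexec("# fs=([^ ]+) windowLen=(\\d+) quantized=(\\d) bits=(-?\\d+)",
            lines[1L]))[[1L]]
  fs <- as.numeric(meta[2L]); wl <- as.integer(meta[3L])
  quant <- meta[4L] == "1"; bits <- as.integer(meta[5L])
  hdr <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  specs <- lapply(hdr, function(h) {
    p <- strsplit(h, "|", fixed = TRUE)[[1L]]
    featureSpec(as.integer(p[1L]),
                newWavelet(p[2L], as.integer(p[3L]), as.integer(p[4L]),
                           as.integer(p[5L]), wl, fs))
  })
  vals <- do.call(rbind, lapply(lines[-(1:2)], function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]])))
  if (is.null(vals)) vals <- matrix(0, 0L, length(specs))
  new("FeatureMatrix", values = vals, specs = specs, fs = fs,
      quantized = quant, bits = if (bits < 0L) NA_integer_ else bits)
}
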