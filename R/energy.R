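# Sensor-node energy model: per-feature extraction cost and whole-chain
# acquisition/transmission/classification breakdowns for the Nyquist,
# analog-to-information (A2I) and A2F front-ends.

#' Construct a power budget
#'
#' Defaults are the published component values of the reference front-end:
#' 5.04 uW amplification stage (LNA + PGA), 625 nW Gm-C integrator, 0.3 uW
#' SAR ADC at 40 kHz with 10-bit precision, 3.7 nJ/bit BLE radio, 0.7 uW
#' anti-aliasing filter and 2 kHz rate for the Nyquist chain, 0.9 uW A2I
#' converter with compression ratio 4, and a 120 mW / 270 ns FPGA classifier
#' for the in-sensor variant. The digital wavelet-generator power
#' `pWavelet` has no published value and must be supplied explicitly; all
#' reports echo it.
#'
#' @param pWavelet wavelet-generator power, W (required).
#' @param pAmp amplification-stage power, W.
#' @param pInt integrator power, W.
#' @param pAdc ADC power, W.
#' @param fsAdc ADC sampling rate, Hz.
#' @param adcBits ADC precision, bits.
#' @param eBit radio energy per transmitted bit, J.
#' @param pLpf anti-aliasing-filter power (Nyquist chain), W.
#' @param fsNyq Nyquist-chain sampling rate, Hz.
#' @param pA2i A2I converter power, W.
#' @param a2iCompression A2I compression ratio.
#' @param pClass in-sensor classifier power, W.
#' @param tClass time per classification, s.
#' @param nChannelsNyq channels sampled by the Nyquist chain.
#' @return a [PowerBudget-class].
#' @examples
#' b <- powerBudget(pWavelet = 0.1e-6)
#' @export
powerBudget <- function(pWavelet, pAmp = 5.04e-6, pInt = 625e-9,
                        pAdc = 0.3e-6, fsAdc = 40e3, adcBits = 10L,
                        eBit = 3.7e-9, pLpf = 0.7e-6, fsNyq = 2e3,
                        pA2i = 0.9e-6, a2iCompression = 4,
                        pClass = 120e-3, tClass = 270e-9,
                        nChannelsNyq = 1L) {
  if (missing(pWavelet))
    stop("pWavelet has no default: supply the wavelet-generator power in W")
  new("PowerBudget", pAmp = pAmp, pInt = pInt, pWavelet = pWavelet,
      pAdc = pAdc, fsAdc = fsAdc, adcBits = as.integer(adcBits),
      eBit = eBit, pLpf = pLpf, fsNyq = fsNyq, pA2i = pA2i,
      a2iCompression = a2iCompression, pClass = pClass, tClass = tClass,
      nChannelsNyq = as.integer(nChannelsNyq))
}

setMethod("show", "PowerBudget", function(object) {
  cat(sprintf(paste0(
    "PowerBudget: Pamp=%g W, Pint=%g W, Pwavelet=%g W, Padc=%g W @ %g Hz ",
    "(%d bit)\n  eBit=%g J/bit, Nyquist: Plpf=%g W @ %g Hz x%d ch, ",
    "A2I: P=%g W (CR %g)\n"),
    object@pAmp, object@pInt, object@pWavelet, object@pAdc, object@fsAdc,
    object@adcBits, object@eBit, object@pLpf, object@fsNyq,
    object@nChannelsNyq, object@pA2i, object@a2iCompression))
})

#' Per-feature extraction energy
#'
#' `E = (Pamp + Pint + Pwavelet) * (t_s / fs) + Padc / Fs_adc`, where
#' `t_s / fs` is the wavelet support duration in seconds and the last term
#' is one ADC conversion. Constant-family (direct-integration) features
#' need no wavelet generator, so their `Pwavelet` term is dropped.
#'
#' @param w a [Wavelet-class].
#' @param b a [PowerBudget-class].
#' @return energy in joules.
#' @export
featureEnergy <- function(w, b) {
  pWav <- if (w@family == "constant") 0 else b@pWavelet
  (b@pAmp + b@pInt + pWav) * (w@support / w@fs) + b@pAdc / b@fsAdc
}

newBreakdown <- function(acq, tx, cls, perFeature, chain)
  new("EnergyBreakdown", acquisition = acq, transmission = tx,
      classification = cls, total = acq + tx + cls,
      perFeature = perFeature, chain = chain)

#' Nyquist-chain energy breakdown
#'
#' Continuous amplification + anti-aliasing filtering + ADC on every
#' channel, with every sample transmitted at the ADC precision.
#'
#' @param duration signal duration, s.
#' @param b a [PowerBudget-class].
#' @return an [EnergyBreakdown-class].
#' @export
chainNyquist <- function(duration, b) {
  stopifnot(duration > 0)
  acq <- (b@pAmp + b@pLpf + b@pAdc) * duration * b@nChannelsNyq
  tx <- b@fsNyq * duration * b@nChannelsNyq * b@adcBits * b@eBit
  newBreakdown(acq, tx, 0, numeric(0), "nyquist")
}

#' A2I (compressive-sampling) chain energy breakdown
#'
#' The converter acquires at `pA2i` and transmits the Nyquist sample stream
#' divided by its compression ratio; signal-reconstruction cost at the
#' aggregator is excluded.
#'
#' @inheritParams chainNyquist
#' @return an [EnergyBreakdown-class].
#' @export
chainA2i <- function(duration, b) {
  stopifnot(duration > 0)
  acq <- b@pA2i * duration
  tx <- (b@fsNyq * duration / b@a2iCompression) * b@adcBits * b@eBit
  newBreakdown(acq, tx, 0, numeric(0), "a2i")
}

#' A2F chain energy breakdown
#'
#' Extracts the selected features once per analysis window over the signal
#' duration. Without in-sensor classification every feature is transmitted
#' at the ADC precision; with it, only the classification result bits are
#' sent and the classifier energy `Pclass * tclass` is charged per window.
#' The optional shared-amplifier mode charges the amplification stage over
#' the union of wavelet supports per signal instead of per feature
#' (a dedicated amplifier per signal is never active twice at the same
#' instant), which can only lower the total.
#'
#' @param duration signal duration, s.
#' @param specs selected feature specs (non-empty).
#' @param windowPeriod analysis-window cadence, s (e.g. 0.711 s for
#'   contiguous ECG windows, 1.28 s for 50%-overlapped inertial windows).
#' @param b a [PowerBudget-class].
#' @param inSensor classify within the sensor and transmit only the result.
#' @param resultBits bits per transmitted classification result.
#' @param sharedAmplifier charge `pAmp` over per-signal support unions.
#' @return an [EnergyBreakdown-class].
#' @export
chainA2f <- function(duration, specs, windowPeriod, b, inSensor = FALSE,
                     resultBits = 1L, sharedAmplifier = FALSE) {
  stopifnot(duration > 0, windowPeriod > 0)
  if (!length(specs)) stop("empty feature selection")
  nWindows <- floor(duration / windowPeriod)
  perFeat <- vapply(specs, function(s) featureEnergy(s$wavelet, b),
                    numeric(1))
  acqWindow <- sum(perFeat)
  if (sharedAmplifier) {
    # replace the per-feature Pamp charge by one charge per signal over the
    # union of its supports
    fs <- specs[[1L]]$wavelet@fs
    chans <- vapply(specs, function(s) s$channel, integer(1))
    totalSupport <- sum(vapply(specs, function(s) s$wavelet@support,
                               integer(1))) / fs
    unionDur <- sum(vapply(unique(chans), function(ch) {
      iv <- vapply(specs[chans == ch], function(s)
        c(s$wavelet@shift, s$wavelet@shift + s$wavelet@support), numeric(2))
      iv <- iv[, order(iv[1L, ]), drop = FALSE]
      tot <- 0; curS <- iv[1L, 1L]; curE <- iv[2L, 1L]
      for (k in seq_len(ncol(iv))[-1L]) {
        if (iv[1L, k] > curE) {
          tot <- tot + (curE - curS); curS <- iv[1L, k]; curE <- iv[2L, k]
        } else curE <- max(curE, iv[2L, k])
      }
      (tot + (curE - curS)) / fs
    }, numeric(1)))
    acqWindow <- acqWindow - b@pAmp * totalSupport + b@pAmp * unionDur
  }
  acq <- nWindows * acqWindow
  if (inSensor) {
    tx <- nWindows * resultBits * b@eBit
    cls <- nWindows * b@pClass * b@tClass
  } else {
    tx <- nWindows * length(specs) * b@adcBits * b@eBit
    cls <- 0
  }
  newBreakdown(acq, tx, cls, perFeat, "a2f")
}

#' Compression ratio of an A2F selection
#'
#' `100 * (1 - n_features / n_samples)`, the fraction of Nyquist samples
#' per analysis window replaced by transmitted features, rounded to 0.1
#' percentage points for reporting.
#'
#' @param nFeatures transmitted features per window.
#' @param nSamples Nyquist samples per window.
#' @return percentage.
#' @examples
#' compressionRatio(7, 256)    # 97.3
#' compressionRatio(16, 384)   # 95.8
#' @export
compressionRatio <- function(nFeatures, nSamples) {
  stopifnot(nSamples > 0, nFeatures >= 0, nFeatures <= nSamples)
  round(100 * (1 - nFeatures / nSamples), 1)
}

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf(
    "EnergyBreakdown [%s]: total %.4g J (acq %.4g, tx %.4g, class %.4g)\n",
    object@chain, object@total, object@acquisition, object@transmission,
    object@classification))
})

#' Serialize an energy breakdown to JSON
#'
#' @param x an [EnergyBreakdown-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnergyBreakdown <- function(x, path) {
  writeLines(jsonlite::toJSON(list(
    chain = x@chain, acquisition = x@acquisition,
    transmission = x@transmission, classification = x@classification,
    total = x@total, perFeature = x@perFeature),
    auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
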