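# Synthetic windowed datasets with the statistical structure the A2F method
# assumes: heartbeat-aligned ECG-like windows with a rare "abnormal"
# morphology class, and 6-channel inertial windows with three static classes
# (distinct gravity orientations, near-zero oscillation) and three dynamic
# classes (distinct stride frequency and amplitude). Classes are built to be
# separable by few dictionary atoms: static classes by channel means (the
# constant wavelet), dynamic classes by oscillations whose periods sit on
# the Haar lattice.

gaussBump <- function(len, center, sigma, amplitude) {
  t <- seq_len(len) - 1
  amplitude * exp(-0.5 * ((t - center) / sigma)^2)
}

#' Simulate a heartbeat-aligned ECG-like dataset
#'
#' Each 256-sample window holds one stereotyped beat with the R peak at a
#' fixed sample. Normal windows carry a narrow QRS complex with P and T
#' waves; abnormal windows a widened, lower QRS and a shifted secondary
#' peak (an ectopic-like morphology). The class prior defaults to 85/15
#' normal/abnormal and the train/test split to a stratified 70/30.
#'
#' @param nWindows total windows (>= 10).
#' @param abnormalFraction prior probability of the abnormal class.
#' @param windowLen samples per window.
#' @param fs sampling rate, Hz.
#' @param rPeakIndex sample index (0-based) of the R peak.
#' @param noiseSd additive white-noise standard deviation, signal units
#'   (QRS amplitude is 1).
#' @param amplitudeJitterSd per-window multiplicative amplitude jitter sd.
#' @param trainFraction fraction of windows tagged `"train"`.
#' @param seed RNG seed; the same seed yields a bit-identical dataset.
#' @return a [WindowedDataset-class] with classes `normal`/`abnormal`
#'   (abnormal is the positive class).
#' @export
simulateEcg <- function(nWindows = 600L, abnormalFraction = 0.15,
                        windowLen = 256L, fs = 360, rPeakIndex = 100L,
                        noiseSd = 0.05, amplitudeJitterSd = 0.05,
                        trainFraction = 0.7, seed = 1L) {
  if (nWindows < 10L)
    stop("nWindows must be >= 10 for a non-degenerate split, got ", nWindows)
  stopifnot(abnormalFraction >= 0, abnormalFraction <= 1,
            rPeakIndex < windowLen)
  set.seed(seed)
  nAb <- round(nWindows * abnormalFraction)
  labels <- factor(c(rep("normal", nWindows - nAb), rep("abnormal", nAb)),
                   levels = c("normal", "abnormal"))
  labels <- labels[sample.int(nWindows)]

  normalTemplate <- gaussBump(windowLen, rPeakIndex - 30, 8, 0.15) +  # P
    gaussBump(windowLen, rPeakIndex, 4, 1.0) +                       # QRS
    gaussBump(windowLen, rPeakIndex + 60, 12, 0.3)                   # T
  abnormalTemplate <- gaussBump(windowLen, rPeakIndex, 11, 0.75) +   # wide QRS
    gaussBump(windowLen, rPeakIndex + 80, 10, 0.45)     # shifted second peak

  windows <- array(0, dim = c(nWindows, 1L, windowLen))
  for (i in seq_len(nWindows)) {
    tpl <- if (labels[i] == "abnormal") abnormalTemplate else normalTemplate
    amp <- 1 + stats::rnorm(1L, 0, amplitudeJitterSd)
    windows[i, 1L, ] <- amp * tpl + stats::rnorm(windowLen, 0, noiseSd)
  }
  split <- stratifiedSplit(labels, trainFraction)
  new("WindowedDataset", windows = windows, labels = labels, fs = fs,
      channelNames = "ecg", split = split)
}

#' Simulate a 6-channel inertial dataset
#'
#' Three static activities (sitting, standing, laying) are per-channel
#' constants — distinct gravity projections on the accelerometer axes —
#' plus noise, so every zero-mean wavelet feature vanishes on them and only
#' the constant (direct-integration) wavelet separates them. Three dynamic
#' activities (walking, upstairs, downstairs) oscillate at distinct
#' fundamental frequencies sitting on the Haar period lattice, with a
#' second harmonic and a small phase jitter.
#'
#' @param nWindows total windows, spread evenly over the 6 classes.
#' @param windowLen samples per window.
#' @param fs sampling rate, Hz.
#' @param staticMeans 3 x 6 matrix of per-class channel means (rows:
#'   sitting, standing, laying); rows must be pairwise distinct.
#' @param dynamicPeriods integer length-3, oscillation periods in samples
#'   (walking, upstairs, downstairs).
#' @param dynamicAmplitudes numeric length-3 accelerometer oscillation
#'   amplitudes.
#' @param phaseJitterSd sd of the per-window carrier-phase jitter, radians.
#' @param noiseSd additive white-noise sd.
#' @param trainFraction fraction of windows tagged `"train"`.
#' @param seed RNG seed.
#' @return a [WindowedDataset-class] with 6 activity classes.
#' @export
simulateInertial <- function(nWindows = 360L, windowLen = 128L, fs = 50,
                             staticMeans = rbind(
                               sitting  = c(0.00, 0.55, 0.85, 0, 0, 0),
                               standing = c(0.05, 0.95, 0.20, 0, 0, 0),
                               laying   = c(0.90, 0.10, 0.15, 0, 0, 0)),
                             dynamicPeriods = c(32L, 64L, 16L),
                             dynamicAmplitudes = c(0.8, 0.6, 1.1),
                             phaseJitterSd = 0.4, noiseSd = 0.1,
                             trainFraction = 0.7, seed = 1L) {
  stopifnot(nrow(staticMeans) == 3L, ncol(staticMeans) == 6L,
            length(dynamicPeriods) == 3L, length(dynamicAmplitudes) == 3L,
            all(dynamicPeriods >= 2), all(fs / dynamicPeriods < fs / 2))
  if (anyDuplicated(apply(staticMeans, 1L, paste, collapse = ",")))
    stop("static class mean vectors must be pairwise distinct")
  set.seed(seed)
  classes <- c("sitting", "standing", "laying",
               "walking", "upstairs", "downstairs")
  perClass <- rep(nWindows %/% 6L, 6L)
  perClass[seq_len(nWindows %% 6L)] <- perClass[seq_len(nWindows %% 6L)] + 1L
  labels <- factor(rep(classes, perClass), levels = classes)
  labels <- labels[sample.int(nWindows)]

  gravityBase <- c(0.10, 0.85, 0.30, 0, 0, 0)  # shared by dynamic classes
  gyroScale <- 0.4
  t <- seq_len(windowLen) - 1
  windows <- array(0, dim = c(nWindows, 6L, windowLen))
  for (i in seq_len(nWindows)) {
    cls <- as.integer(labels[i])
    if (cls <= 3L) {
      base <- matrix(rep(staticMeans[cls, ], each = windowLen),
                     nrow = 6L, byrow = TRUE)
    } else {
      k <- cls - 3L
      phi <- stats::rnorm(1L, 0, phaseJitterSd)
      carrier <- sin(2 * pi * t / dynamicPeriods[k] + phi) +
        0.2 * sin(4 * pi * t / dynamicPeriods[k] + 2 * phi)
      amp <- dynamicAmplitudes[k] * c(1, 0.8, 0.6,
                                      gyroScale, gyroScale, gyroScale)
      base <- outer(amp, carrier) + gravityBase
    }
    windows[i, , ] <- base +
      matrix(stats::rnorm(6L * windowLen, 0, noiseSd), 6L)
  }
  split <- stratifiedSplit(labels, trainFraction)
  new("WindowedDataset", windows = windows, labels = labels, fs = fs,
      channelNames = c("accx", "accy", "accz", "gyrx", "gyry", "gyrz"),
      split = split)
}

# Stratified train/test tagging; deterministic under the caller's RNG state.
stratifiedSplit <- function(labels, trainFraction) {
  split <- factor(rep("test", length(labels)), levels = c("train", "test"))
  for (cl in levels(labels)) {
    rows <- which(labels == cl)
    if (!length(rows)) next
    nTrain <- max(1L, round(length(rows) * trainFraction))
    split[sample(rows, nTrain)] <- "train"
  }
  split
}

#' Train-split mask of a windowed dataset
#'
#' @param ds a [WindowedDataset-class].
#' @return logical vector, `TRUE` for training windows.
#' @export
trainMask <- function(ds) ds@split == "train"

#' @describeIn samplingRate for a windowed dataset
#' @export
setMethod("samplingRate", "WindowedDataset", function(x) x@fs)

#' @describeIn windowLen for a windowed dataset
#' @export
setMethod("windowLen", "WindowedDataset", function(x)
  dim(x@windows)[3L])

setMethod("show", "WindowedDataset", function(object) {
  d <- dim(object@windows)
  cat(sprintf(
    "WindowedDataset: %d windows x %d channels x %d samples @ %g Hz\n",
    d[1L], d[2L], d[3L], object@fs))
  cat("  classes:", paste(sprintf("%s=%d", names(table(object@labels)),
                                  table(object@labels)), collapse = ", "),
      "\n")
  cat("  split:", sum(object@split == "train"), "train /",
      sum(object@split == "test"), "test\n")
})

#' Labels accessor
#'
#' @param ds a [WindowedDataset-class].
#' @return factor of class labels.
#' @export
datasetLabels <- function(ds) ds@labels
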