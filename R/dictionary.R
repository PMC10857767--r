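# Wavelet atoms and dictionary enumeration.
#
# The enumeration follows the frequency-doubling rule: starting from one
# oscillation period per analysis window, the period is halved down to two
# samples (half a period can never be shorter than one sampling interval);
# for each period the support doubles from one period up to the full window;
# shifts are restricted to multiples of the support so atoms sharing
# (period, support) never overlap.

waveletKey <- function(w) {
  sprintf("%s:%d:%d:%d:%s", w@family, w@period, w@support, w@shift,
          ifelse(is.na(w@gaborPhase), "-", format(w@gaborPhase, digits = 17)))
}

newWavelet <- function(family, period, support, shift, windowLen, fs,
                       gaborSigma = NA_real_, gaborPhase = NA_real_,
                       polarity = 1) {
  new("Wavelet", family = family, period = as.integer(period),
      support = as.integer(support), shift = as.integer(shift),
      windowLen = as.integer(windowLen), fs = fs,
      gaborSigma = gaborSigma, gaborPhase = gaborPhase, polarity = polarity)
}

#' Construct a single wavelet atom
#'
#' Mostly useful for tests and hand-built selections; dictionaries are the
#' usual source of atoms. Validity rules: the support must lie inside the
#' window; a Haar period must be an even integer with the support a
#' power-of-two multiple of it; a constant atom spans the whole window.
#'
#' @param family `"haar"`, `"gabor"` or `"constant"`.
#' @param period oscillation period in samples (0 for constant).
#' @param support support duration in samples.
#' @param shift time shift from window start in samples.
#' @param windowLen analysis-window length in samples.
#' @param fs sampling rate, Hz.
#' @param gaborSigma Gaussian envelope width in samples (gabor only).
#' @param gaborPhase carrier phase in radians (gabor only).
#' @param polarity sign of the leading haar half-period.
#' @return a [Wavelet-class].
#' @export
wavelet <- function(family, period, support, shift, windowLen, fs,
                    gaborSigma = NA_real_, gaborPhase = NA_real_,
                    polarity = 1) {
  newWavelet(family, period, support, shift, windowLen, fs,
             gaborSigma = gaborSigma, gaborPhase = gaborPhase,
             polarity = polarity)
}

checkWindowLen <- function(windowLen) {
  if (length(windowLen) != 1L || windowLen < 2)
    stop("window_len must be a single value >= 2, got ", windowLen)
  if (abs(log2(windowLen) - round(log2(windowLen))) > 1e-9)
    stop("window_len must be a power of two, got ", windowLen)
  as.integer(windowLen)
}

# All (period, support, shift) triples of the Haar lattice, in dictionary
# order: descending period (ascending frequency), ascending support,
# ascending shift.
haarLattice <- function(windowLen) {
  out <- vector("list", 64L)
  k <- 0L
  period <- windowLen
  while (period >= 2L) {
    support <- period
    while (support <= windowLen) {
      shifts <- seq.int(0L, windowLen - support, by = support)
      k <- k + 1L
      out[[k]] <- cbind(period = period, support = support, shift = shifts)
      support <- support * 2L
    }
    period <- period %/% 2L
  }
  do.call(rbind, out[seq_len(k)])
}

#' Build the Haar wavelet dictionary
#'
#' Enumerates every Haar atom admissible under the dictionary construction
#' rule for a power-of-two analysis window: periods
#' `P = windowLen, windowLen/2, ..., 2` samples, supports
#' `t_s = P, 2P, ..., windowLen`, and shifts restricted to multiples of the
#' support. Atoms are ordered by descending period, then ascending support,
#' then ascending shift; the optional constant (direct-integration) atom
#' comes last. For a 256-sample window this yields 502 atoms; for a
#' 128-sample window, 247 (+1 constant).
#'
#' @param windowLen analysis-window length in samples; must be a power of
#'   two >= 2.
#' @param fs sampling rate of the signal, Hz.
#' @param includeConstant append the all-ones constant wavelet spanning the
#'   whole window (needed to separate static activities, whose zero-mean
#'   wavelet features all vanish). Default `FALSE`.
#' @param polarity sign of the leading half-period (+1 by default; the
#'   classifier is sign-invariant under a consistent convention).
#' @return a [WaveletDictionary-class].
#' @examples
#' nWavelets(haarDictionary(256, 360))           # 502
#' nWavelets(haarDictionary(128, 50, TRUE))      # 248
#' @export
haarDictionary <- function(windowLen, fs, includeConstant = FALSE,
                           polarity = 1) {
  windowLen <- checkWindowLen(windowLen)
  stopifnot(fs > 0)
  lat <- haarLattice(windowLen)
  ws <- lapply(seq_len(nrow(lat)), function(i)
    newWavelet("haar", lat[i, "period"], lat[i, "support"], lat[i, "shift"],
               windowLen, fs, polarity = polarity))
  if (includeConstant)
    ws <- c(ws, list(newWavelet("constant", 0L, windowLen, 0L, windowLen, fs)))
  new("WaveletDictionary", wavelets = ws, windowLen = windowLen, fs = fs,
      constructionParams = list(family = "haar",
                                includeConstant = includeConstant,
                                polarity = polarity))
}

#' Build a Gabor wavelet dictionary
#'
#' Enumerates Gabor atoms (real part of a Gaussian-windowed sinusoid) on the
#' same (period, support, shift) lattice as the Haar enumeration, expanded
#' by a configurable carrier-phase grid; the Gaussian width follows
#' `sigma = support / sigmaDivisor`. Each atom is numerically de-meaned over
#' its support so it integrates to (near) zero.
#'
#' @inheritParams haarDictionary
#' @param phases numeric vector of carrier phases (radians).
#' @param sigmaDivisor positive divisor for the envelope rule
#'   `sigma = support / sigmaDivisor`.
#' @return a [WaveletDictionary-class].
#' @export
gaborDictionary <- function(windowLen, fs, phases = c(0, pi / 2),
                            sigmaDivisor = 6) {
  windowLen <- checkWindowLen(windowLen)
  stopifnot(fs > 0, sigmaDivisor > 0, length(phases) >= 1)
  lat <- haarLattice(windowLen)
  ws <- vector("list", nrow(lat) * length(phases))
  k <- 0L
  for (i in seq_len(nrow(lat))) {
    for (ph in phases) {
      k <- k + 1L
      ws[[k]] <- newWavelet("gabor", lat[i, "period"], lat[i, "support"],
                            lat[i, "shift"], windowLen, fs,
                            gaborSigma = lat[i, "support"] / sigmaDivisor,
                            gaborPhase = ph)
    }
  }
  new("WaveletDictionary", wavelets = ws, windowLen = windowLen, fs = fs,
      constructionParams = list(family = "gabor", phases = phases,
                                sigmaDivisor = sigmaDivisor))
}

#' @describeIn waveform render one atom
#' @export
setMethod("waveform", "Wavelet", function(w) {
  out <- numeric(w@windowLen)
  idx <- seq.int(w@shift + 1L, w@shift + w@support)
  if (w@family == "constant") {
    out[] <- 1
  } else if (w@family == "haar") {
    # position within the support, half-period parity decides the sign
    pos <- seq_len(w@support) - 1L
    half <- w@period %/% 2L
    out[idx] <- w@polarity * ifelse((pos %/% half) %% 2L == 0L, 1, -1)
  } else { # gabor
    t <- seq_len(w@support) - 1L
    center <- (w@support - 1) / 2
    env <- exp(-0.5 * ((t - center) / w@gaborSigma)^2)
    carrier <- cos(2 * pi * t / w@period + w@gaborPhase)
    g <- env * carrier
    out[idx] <- g - mean(g)
  }
  out
})

#' @describeIn nWavelets dictionary size
#' @export
setMethod("nWavelets", "WaveletDictionary", function(x, ...)
  length(x@wavelets))

#' @describeIn windowLen for a wavelet
#' @export
setMethod("windowLen", "Wavelet", function(x) x@windowLen)

#' @describeIn windowLen for a dictionary
#' @export
setMethod("windowLen", "WaveletDictionary", function(x) x@windowLen)

#' @describeIn samplingRate for a wavelet
#' @export
setMethod("samplingRate", "Wavelet", function(x) x@fs)

#' @describeIn samplingRate for a dictionary
#' @export
setMethod("samplingRate", "WaveletDictionary", function(x) x@fs)

#' Oscillation frequency of a wavelet, Hz
#'
#' Derived as `fs / period`; 0 for the constant atom.
#'
#' @param w a [Wavelet-class].
#' @return numeric, Hz.
#' @export
oscillationFrequency <- function(w) {
  if (w@family == "constant") 0 else w@fs / w@period
}

setMethod("show", "Wavelet", function(object) {
  cat(sprintf(
    "Wavelet [%s] period=%d support=%d shift=%d window=%d fs=%g Hz\n",
    object@family, object@period, object@support, object@shift,
    object@windowLen, object@fs))
})

setMethod("show", "WaveletDictionary", function(object) {
  fams <- table(vapply(object@wavelets, function(w) w@family, character(1)))
  cat(sprintf("WaveletDictionary: %d atoms over a %d-sample window @ %g Hz\n",
              length(object@wavelets), object@windowLen, object@fs))
  cat("  families:", paste(sprintf("%s=%d", names(fams), fams),
                           collapse = ", "), "\n")
})

#' Extract a wavelet by index
#'
#' @param x a [WaveletDictionary-class].
#' @param i integer index.
#' @param j,... ignored.
#' @return a [Wavelet-class].
#' @export
setMethod("[[", "WaveletDictionary", function(x, i, j, ...) x@wavelets[[i]])

#' Serialize a dictionary to a line-oriented JSON file
#'
#' One JSON record per wavelet with family, period, support, shift and
#' (for Gabor) sigma/phase, preceded by one header record. Integer lattice
#' parameters make the round trip bit-exact.
#'
#' @param dict a [WaveletDictionary-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDictionary <- function(dict, path) {
  header <- jsonlite::toJSON(
    list(windowLen = dict@windowLen, fs = dict@fs,
         constructionParams = dict@constructionParams),
    auto_unbox = TRUE, digits = NA)
  num17 <- function(x) if (is.na(x)) NA_character_ else
    sprintf("%.17g", x)   # strings keep the doubles bit-exact
  recs <- vapply(dict@wavelets, function(w) {
    jsonlite::toJSON(list(
      family = w@family, period = w@period, support = w@support,
      shift = w@shift, gaborSigma = num17(w@gaborSigma),
      gaborPhase = num17(w@gaborPhase),
      polarity = num17(w@polarity)), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a dictionary written by [writeDictionary()]
#'
#' @param path file path.
#' @return a [WaveletDictionary-class].
#' @export
readDictionary <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  ws <- lapply(lines[-1L], function(l) {
    r <- jsonlite::fromJSON(l)
    asNum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    newWavelet(r$family, r$period, r$support, r$shift,
               header$windowLen, header$fs,
               gaborSigma = asNum(r$gaborSigma),
               gaborPhase = asNum(r$gaborPhase),
               polarity = asNum(r$polarity))
  })
  new("WaveletDictionary", wavelets = ws,
      windowLen = as.integer(header$windowLen), fs = header$fs,
      constructionParams = as.list(header$constructionParams))
}
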