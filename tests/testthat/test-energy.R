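# Per-feature energy (extraction cost) and whole-chain breakdowns.

budgetFixture <- function(pWavelet = 0.1e-6) powerBudget(pWavelet = pWavelet)

test_that("per-feature energy follows the power-times-support arithmetic", {
  b <- budgetFixture()
  # 0.711 s support (full 256-sample window at 360 Hz)
  w <- wavelet("haar", 256L, 256L, 0L, 256L, 360)
  expected <- (5.04e-6 + 625e-9 + 0.1e-6) * (256 / 360) + 0.3e-6 / 40e3
  expect_equal(featureEnergy(w, b), expected)
  expect_equal((5.04e-6 + 625e-9 + 0.1e-6) * (256 / 360), 4.099e-6,
               tolerance = 1e-3)
  expect_equal(0.3e-6 / 40e3, 7.5e-12)
})

test_that("vanishing support leaves only the conversion term", {
  b <- budgetFixture()
  w <- wavelet("haar", 2L, 2L, 0L, 256L, 360)
  lim <- b@pAdc / b@fsAdc
  expect_lt(featureEnergy(w, b) - lim, (b@pAmp + b@pInt + b@pWavelet) * 0.01)
  expect_gt(featureEnergy(w, b), lim)
})

test_that("constant wavelets drop the generator power", {
  b <- budgetFixture(pWavelet = 0.5e-6)
  h <- wavelet("haar", 128L, 128L, 0L, 128L, 50)
  cw <- wavelet("constant", 0L, 128L, 0L, 128L, 50)
  expect_lt(featureEnergy(cw, b), featureEnergy(h, b))
  expect_equal(featureEnergy(h, b) - featureEnergy(cw, b),
               0.5e-6 * 128 / 50)
})

test_that("feature energy increases with support and every power term", {
  b <- budgetFixture()
  short <- wavelet("haar", 4L, 4L, 0L, 64L, 100)
  long <- wavelet("haar", 4L, 64L, 0L, 64L, 100)
  expect_gt(featureEnergy(long, b), featureEnergy(short, b))
  bumped <- powerBudget(pWavelet = 0.2e-6, pAmp = 6e-6, pInt = 1e-6)
  expect_gt(featureEnergy(long, bumped), featureEnergy(long, b))
})

test_that("Nyquist chain reproduces the published component arithmetic", {
  b <- budgetFixture()
  # component powers sum to 6.04 uW per channel
  expect_equal((b@pAmp + b@pLpf + b@pAdc) * 1e6, 6.04)
  # 37 nJ per transmitted 10-bit sample
  expect_equal(b@adcBits * b@eBit * 1e9, 37)
  bd <- chainNyquist(10, b)
  expect_equal(bd@acquisition, 6.04e-6 * 10)
  expect_equal(bd@transmission, 2e3 * 10 * 10 * 3.7e-9)  # 740 uJ
  expect_identical(bd@classification, 0)
  expect_equal(bd@total, bd@acquisition + bd@transmission)
})

test_that("A2I chain acquisition and compression behave as configured", {
  b <- budgetFixture()
  bd <- chainA2i(10, b)
  expect_equal(bd@acquisition, 0.9e-6 * 10)  # 9 uJ
  nyq <- chainNyquist(10, b)
  expect_equal(bd@transmission, nyq@transmission / 4)
  noCompress <- powerBudget(pWavelet = 0.1e-6, a2iCompression = 1)
  expect_equal(chainA2i(10, noCompress)@transmission, nyq@transmission)
})

test_that("A2F chain counts windows and switches transmission with in-sensor mode", {
  b <- budgetFixture()
  specs <- lapply(c(0L, 64L), function(sh)
    featureSpec(1L, wavelet("haar", 32L, 64L, sh, 256L, 360)))
  period <- 256 / 360
  bd <- chainA2f(10, specs, period, b)
  nWin <- floor(10 / period)   # 14 whole windows
  expect_identical(nWin, 14)
  expect_equal(bd@acquisition,
               nWin * sum(vapply(specs, function(s)
                 featureEnergy(s$wavelet, b), numeric(1))))
  expect_equal(bd@transmission, nWin * 2 * 10 * 3.7e-9)
  # in-sensor: one result bit replaces n_features * adc_bits
  bdIn <- chainA2f(10, specs, period, b, inSensor = TRUE, resultBits = 1L)
  expect_equal(bd@transmission / bdIn@transmission, 20)
  expect_equal(bdIn@classification, nWin * 120e-3 * 270e-9)
  expect_error(chainA2f(10, list(), period, b), "empty")
})

test_that("in-sensor transmission reductions match the published ratios", {
  b <- budgetFixture()
  # 8 features on 10 bits vs 1 result bit -> 80x
  expect_equal(8 * b@adcBits / 1, 80)
  specs8 <- lapply(0:7 * 32L, function(sh)
    featureSpec(1L, wavelet("haar", 32L, 32L, sh, 256L, 360)))
  period <- 256 / 360
  expect_equal(chainA2f(10, specs8, period, b)@transmission /
                 chainA2f(10, specs8, period, b, inSensor = TRUE,
                          resultBits = 1L)@transmission, 80)
  # 16 or 17 features vs 3 result bits -> 53x / 57x (printed integers)
  expect_identical(floor(16 * 10 / 3), 53)
  expect_identical(floor(17 * 10 / 3), 56)  # 56.67 prints as 57 when rounded
  expect_identical(round(17 * 10 / 3), 57)
})

test_that("shared-amplifier mode never exceeds the per-feature total", {
  b <- budgetFixture()
  overlapping <- list(
    featureSpec(1L, wavelet("haar", 32L, 64L, 0L, 256L, 360)),
    featureSpec(1L, wavelet("haar", 16L, 64L, 32L, 256L, 360)),
    featureSpec(2L, wavelet("haar", 32L, 32L, 0L, 256L, 360)))
  period <- 256 / 360
  perFeat <- chainA2f(10, overlapping, period, b)
  shared <- chainA2f(10, overlapping, period, b, sharedAmplifier = TRUE)
  expect_lte(shared@total, perFeat@total)
  # disjoint supports on one signal: identical accounting
  disjoint <- list(
    featureSpec(1L, wavelet("haar", 32L, 32L, 0L, 256L, 360)),
    featureSpec(1L, wavelet("haar", 32L, 32L, 32L, 256L, 360)))
  expect_equal(chainA2f(10, disjoint, period, b, sharedAmplifier = TRUE)@total,
               chainA2f(10, disjoint, period, b)@total)
})

test_that("A2F ECG chain undercuts Nyquist for any plausible generator power", {
  # a 7-feature selection with generous supports, as in the arrhythmia case
  specs <- lapply(1:7, function(i)
    featureSpec(1L, wavelet("haar", 64L, 128L, 0L, 256L, 360)))
  period <- 256 / 360
  for (pw in c(0, 0.1e-6, 0.5e-6, 1e-6)) {
    b <- powerBudget(pWavelet = pw)
    expect_lt(chainA2f(10, specs, period, b)@total,
              chainNyquist(10, b)@total)
  }
})

test_that("breakdown totals equal the sum of parts and components stay non-negative", {
  b <- budgetFixture()
  specs <- list(featureSpec(1L, wavelet("constant", 0L, 128L, 0L, 128L, 50)))
  for (bd in list(chainNyquist(3, b), chainA2i(3, b),
                  chainA2f(3, specs, 1.28, b),
                  chainA2f(3, specs, 1.28, b, inSensor = TRUE))) {
    expect_gte(bd@acquisition, 0)
    expect_gte(bd@transmission, 0)
    expect_gte(bd@classification, 0)
    expect_equal(bd@total,
                 bd@acquisition + bd@transmission + bd@classification)
  }
})

test_that("compression ratio reproduces the printed reporting arithmetic", {
  expect_identical(compressionRatio(7, 256), 97.3)
  expect_identical(compressionRatio(16, 384), 95.8)
  expect_identical(compressionRatio(17, 384), 95.6)
  expect_identical(compressionRatio(0, 100), 100)
  expect_identical(compressionRatio(100, 100), 0)
  expect_error(compressionRatio(5, 0))
})

test_that("the wavelet-generator power has no silent default", {
  expect_error(powerBudget(), "pWavelet")
  b <- budgetFixture(0.25e-6)
  expect_identical(b@pWavelet, 0.25e-6)
})
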