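# Information gain, pre-selection, extractor scheduling and the SFS
# variants on small controlled problems.

toyFeatureMatrix <- function(vals, windowLen = 64L, fs = 10) {
  specs <- lapply(seq_len(ncol(vals)), function(j)
    intervalSpec(2L, 2L * (j - 1L), windowLen))
  new("FeatureMatrix", values = vals, specs = specs, fs = fs)
}

test_that("information gain matches hand-computed toys", {
  # four points, pure bins at both ends: IG = H(D) = 1 bit
  expect_equal(informationGain(c(0, 1, 10, 11), c("A", "A", "B", "B")), 1)
  # constant feature carries no information
  expect_identical(informationGain(rep(2, 10), rep(c("A", "B"), 5)), 0)
  # feature with all classes mixed in one bin: IG = 0
  expect_equal(informationGain(c(1, 1 + 1e-12, 1 + 2e-12, 30),
                               c("A", "B", "A", "A")) <
                 entropyBits(c("A", "B", "A", "A")), TRUE)
})

test_that("information gain is bounded by the label entropy on random inputs", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    values <- rnorm(n)
    labels <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    ig <- informationGain(values, labels)
    expect_gte(ig, -1e-12)
    expect_lte(ig, entropyBits(labels) + 1e-12)
  }
})

test_that("information gain is invariant under positive affine transforms", {
  set.seed(5)
  values <- rnorm(200)
  labels <- sample(c("x", "y"), 200, replace = TRUE)
  base <- informationGain(values, labels)
  expect_equal(informationGain(3.5 * values + 11, labels), base)
  expect_equal(informationGain(0.01 * values - 2, labels), base)
})

test_that("information gain rejects mismatched lengths", {
  expect_error(informationGain(1:4, c("a", "b")), "lengths differ")
})

test_that("pre-selection ranks an informative feature first and breaks ties by order", {
  set.seed(77)
  n <- 80
  labels <- factor(rep(c("a", "b"), each = n / 2))
  informative <- as.numeric(labels == "b") + rnorm(n, 0, 0.01)
  noise <- matrix(rnorm(n * 19), n)
  vals <- cbind(noise[, 1:9], informative, noise[, 10:19])
  fm <- toyFeatureMatrix(vals)
  top <- preselectTopK(fm, labels, k = 5)
  expect_identical(top$index[1L], 10L)
  # k >= n_features returns a permutation of everything
  all20 <- preselectTopK(fm, labels, k = 100)
  expect_setequal(all20$index, 1:20)
  # identical columns tie and stay in dictionary order
  fm2 <- toyFeatureMatrix(cbind(noise[, 1], informative, informative))
  top2 <- preselectTopK(fm2, labels, k = 3)
  expect_identical(top2$index[1:2], c(2L, 3L))
})

test_that("greedy scheduling equals the exhaustive minimum on tiny instances", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    support <- 2L^sample(1:4, n, replace = TRUE)
    shift <- vapply(support, function(s) sample(0:(64L - s), 1L), integer(1))
    specs <- Map(intervalSpec, support, shift)
    sch <- scheduleExtractors(specs)
    expect_identical(nExtractors(sch),
                     bruteMinExtractors(shift, shift + support))
  }
})

test_that("scheduling handles the canonical cases", {
  # two non-overlapping wavelets share one extractor
  s1 <- list(intervalSpec(8L, 0L), intervalSpec(8L, 8L))
  expect_identical(nExtractors(scheduleExtractors(s1)), 1L)
  # identical supports need two
  s2 <- list(intervalSpec(8L, 0L), intervalSpec(8L, 0L))
  expect_identical(nExtractors(scheduleExtractors(s2)), 2L)
  # depth-3 toy: three intervals pile up at sample 8
  s3 <- list(intervalSpec(16L, 0L), intervalSpec(16L, 8L),
             intervalSpec(16L, 4L), intervalSpec(4L, 24L),
             intervalSpec(4L, 40L))
  sch <- scheduleExtractors(s3)
  expect_identical(nExtractors(sch), 3L)
  expect_identical(nExtractors(sch),
                   bruteMinExtractors(c(0, 8, 4, 24, 40),
                                      c(16, 24, 20, 28, 44)))
  # empty selection schedules nothing
  expect_identical(nExtractors(scheduleExtractors(list())), 0L)
})

test_that("constant-wavelet features occupy direct-integration extractors alone", {
  cw <- featureSpec(1L, wavelet("constant", 0L, 64L, 0L, 64L, 10))
  specs <- list(cw, intervalSpec(8L, 0L), intervalSpec(8L, 8L))
  sch <- scheduleExtractors(specs)
  expect_identical(sch@nExtractors, 2L)
  expect_identical(sch@nDirect, 1L)
  expect_identical(sch@nGenerator, 1L)
  constExt <- sch@assignment[1L]
  expect_identical(sum(sch@assignment == constExt), 1L)
})

quickCfg <- function(..., epochs = 40L, seed = 7L)
  selectionConfig(..., seed = seed,
                  classifier = classifierSpec(4L, epochs = epochs,
                                              seed = seed))

# Feature matrix where column 1 separates classes perfectly and the rest
# are noise; rows split into train/test.
sfsFixture <- function(n = 60L, p = 5L, seed = 11L) {
  set.seed(seed)
  labels <- factor(rep(c("a", "b"), each = n / 2))
  vals <- cbind(as.numeric(labels == "b") * 4 + rnorm(n, 0, 0.1),
                matrix(rnorm(n * (p - 1L)), n))
  fm <- toyFeatureMatrix(vals)
  mask <- rep(c(TRUE, TRUE, FALSE), length.out = n)
  list(fm = fm, labels = labels, mask = mask,
       cand = preselectTopK(fm, labels, k = p, rows = mask))
}

test_that("basic SFS picks the perfectly separating feature first", {
  fx <- sfsFixture()
  cfg <- quickCfg(nfMax = 2L)
  sel <- sfsBasic(fx$cand, fx$fm, fx$labels, fx$mask, cfg)
  expect_identical(fx$cand$index[sel@candidateIndex[1L]], 1L)
  expect_gte(sel@metric[1L], 0.95)
})

test_that("nfMax = 0 yields an empty result and empty pools are rejected", {
  fx <- sfsFixture()
  sel <- sfsBasic(fx$cand, fx$fm, fx$labels, fx$mask, quickCfg(nfMax = 0L))
  expect_identical(length(sel@specs), 0L)
  empty <- list(specs = list(), index = integer(0), ig = numeric(0))
  expect_error(sfsBasic(empty, fx$fm, fx$labels, fx$mask, quickCfg()),
               "empty candidate")
})

test_that("monotone stop yields a non-decreasing metric trajectory", {
  fx <- sfsFixture(p = 6L)
  cfg <- quickCfg(nfMax = 6L, monotoneStop = TRUE)
  sel <- sfsBasic(fx$cand, fx$fm, fx$labels, fx$mask, cfg)
  expect_gte(length(sel@metric), 1L)
  expect_true(all(diff(sel@metric) >= 0))
})

test_that("selection is bit-reproducible under a fixed seed", {
  fx <- sfsFixture()
  cfg <- quickCfg(nfMax = 3L)
  s1 <- sfsBasic(fx$cand, fx$fm, fx$labels, fx$mask, cfg)
  s2 <- sfsBasic(fx$cand, fx$fm, fx$labels, fx$mask, cfg)
  expect_identical(s1@candidateIndex, s2@candidateIndex)
  expect_identical(s1@metric, s2@metric)
})

test_that("adapted SFS respects the extractor bound", {
  # all five candidate wavelets overlap at sample 0, so nExtMax = 1 admits
  # only non-overlapping additions
  set.seed(21)
  n <- 60
  labels <- factor(rep(c("a", "b"), each = n / 2))
  sig <- as.numeric(labels == "b") * 3
  vals <- cbind(sig + rnorm(n, 0, 0.1), sig + rnorm(n, 0, 0.1),
                rnorm(n), rnorm(n))
  specs <- list(intervalSpec(16L, 0L), intervalSpec(16L, 0L),
                intervalSpec(16L, 16L), intervalSpec(16L, 32L))
  fm <- new("FeatureMatrix", values = vals, specs = specs, fs = 10)
  mask <- rep(c(TRUE, TRUE, FALSE), length.out = n)
  cand <- preselectTopK(fm, labels, k = 4, rows = mask)
  cfg <- quickCfg(nfMax = 3L, nExtMax = 1L)
  sel <- sfsAdapted(cand, fm, labels, mask, cfg)
  expect_true(all(sel@extractors[, "total"] <= 1L))
  # the two equally predictive overlapping features are never both selected
  chosen <- cand$index[sel@candidateIndex]
  expect_lt(sum(chosen %in% c(1L, 2L)), 2L)
  # and a relaxed bound reproduces the basic search
  cfgWide <- quickCfg(nfMax = 3L, nExtMax = 10L)
  selWide <- sfsAdapted(cand, fm, labels, mask, cfgWide)
  selBasic <- sfsBasic(cand, fm, labels, mask, quickCfg(nfMax = 3L))
  expect_identical(selWide@candidateIndex, selBasic@candidateIndex)
  expect_identical(selWide@metric, selBasic@metric)
})

test_that("optimized SFS with lambda = 0 reproduces the adapted search exactly", {
  fx <- sfsFixture()
  budget <- powerBudget(pWavelet = 0.1e-6)
  cfgA <- quickCfg(nfMax = 3L, nExtMax = 3L, budget = budget)
  cfgO <- quickCfg(nfMax = 3L, nExtMax = 3L, lambda = 0, budget = budget)
  sa <- sfsAdapted(fx$cand, fx$fm, fx$labels, fx$mask, cfgA)
  so <- sfsOptimized(fx$cand, fx$fm, fx$labels, fx$mask, cfgO)
  expect_identical(so@candidateIndex, sa@candidateIndex)
  expect_identical(so@metric, sa@metric)
  expect_identical(so@energy, sa@energy)
  expect_identical(so@extractors, sa@extractors)
})

test_that("optimized SFS prefers the cheaper of two equally accurate features", {
  # two identical predictive columns, one on a short support and one on a
  # long support; any lambda > 0 must choose the short one
  set.seed(8)
  n <- 60
  labels <- factor(rep(c("a", "b"), each = n / 2))
  sig <- as.numeric(labels == "b") * 4 + rnorm(n, 0, 0.05)
  vals <- cbind(long = sig, short = sig)
  specs <- list(intervalSpec(64L, 0L), intervalSpec(4L, 0L))
  fm <- new("FeatureMatrix", values = vals, specs = specs, fs = 10)
  mask <- rep(c(TRUE, TRUE, FALSE), length.out = n)
  cand <- list(specs = specs, index = 1:2, ig = c(1, 1))
  budget <- powerBudget(pWavelet = 0.1e-6)
  cfg <- quickCfg(nfMax = 1L, nExtMax = 2L, lambda = 0.05, budget = budget)
  sel <- sfsOptimized(cand, fm, labels, mask, cfg)
  expect_identical(cand$index[sel@candidateIndex[1L]], 2L)
})

test_that("three-candidate toy follows exhaustive score ranking", {
  # hand-set: col1 weak but cheap, col2 strong but expensive, col3 strong
  # and cheap -> optimized must open with col3
  set.seed(4)
  n <- 90
  labels <- factor(rep(c("a", "b"), each = n / 2))
  strong <- as.numeric(labels == "b") * 4 + rnorm(n, 0.05)
  weak <- as.numeric(labels == "b") * 0.5 + rnorm(n, 0, 1)
  vals <- cbind(weak, strong + rnorm(n, 0, 0.01), strong)
  specs <- list(intervalSpec(4L, 0L), intervalSpec(64L, 0L),
                intervalSpec(4L, 8L))
  fm <- new("FeatureMatrix", values = vals, specs = specs, fs = 10)
  mask <- rep(c(TRUE, TRUE, FALSE), length.out = n)
  cand <- list(specs = specs, index = 1:3, ig = c(0.2, 1, 1))
  budget <- powerBudget(pWavelet = 0.1e-6)
  cfg <- quickCfg(nfMax = 1L, nExtMax = 3L, lambda = 0.2, budget = budget)
  sel <- sfsOptimized(cand, fm, labels, mask, cfg)
  expect_identical(cand$index[sel@candidateIndex[1L]], 3L)
})

test_that("selection results serialize to JSON", {
  fx <- sfsFixture()
  sel <- sfsBasic(fx$cand, fx$fm, fx$labels, fx$mask, quickCfg(nfMax = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  writeSelectionResult(sel, path)
  obj <- jsonlite::fromJSON(readLines(path))
  expect_identical(length(obj$specs$channel), length(sel@specs))
  expect_equal(obj$metric, sel@metric)
})
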