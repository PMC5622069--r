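test_that("all generators are deterministic per seed", {
  truth <- mnxGroundTruth()
  s1 <- simulateSpectrum(truth, seed = 9)
  s2 <- simulateSpectrum(truth, seed = 9)
  expect_identical(mz(s1), mz(s2))
  expect_identical(intensity(s1), intensity(s2))
  expect_false(identical(intensity(s1),
                         intensity(simulateSpectrum(truth, seed = 10))))
  d1 <- simulateDissociation(truth, "SID", 200, "high", seed = 9)
  d2 <- simulateDissociation(truth, "SID", 200, "high", seed = 9)
  expect_identical(d1$fragments, d2$fragments)
  expect_identical(simulateCalibrants(n = 5, seed = 9),
                   simulateCalibrants(n = 5, seed = 9))
  # generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(simulateSpectrum(truth, seed = 99)); b <- runif(1)
  expect_identical(a, b)
})

test_that("a single charge and variant yields one peak at the model position", {
  truth <- mnxGroundTruth()
  bare <- GroundTruth(truth@catalog, truth@composition, truth@topology,
                      metalOccupancy = list())
  sp <- simulateSpectrum(bare, zCenter = 29, zSpread = 1, peakFwhmMz = 10,
                         noiseRel = 0, seed = 1)
  # zSpread 1 gives charges 28..30; restrict by intensity threshold instead
  pk <- pickPeaks(sp, minRelIntensity = 0.99)
  M <- compositionMass(subunitCounts(bare@composition), bare@catalog)
  expect_equal(peakCount(pk), 1L)
  expect_equal(mz(pk), forwardMz(M, 29), tolerance = 1e-5)
})

test_that("total metal load is the convolution of per-copy occupancies", {
  truth <- mnxGroundTruth()
  got <- occupancyProbs(totalOccupancy(truth))
  # independent oracle: direct enumeration over all per-copy count tuples
  dists <- c(rep(list(c(0.05, 0.9, 0.05) / 1), 3),       # three MnxE
             rep(list(c(0.25, 0.5, 0.25)), 3),           # three MnxF
             list(c(0, 0, 0.25, 0.5, 0.25)))             # one MnxG
  grid <- expand.grid(lapply(dists, function(d) seq_along(d) - 1L))
  prob <- Reduce(`*`, lapply(seq_along(dists), function(i)
    dists[[i]][grid[[i]] + 1L]))
  want <- tapply(prob, rowSums(grid), sum)
  expect_equal(unname(got[names(want)]), as.numeric(want), tolerance = 1e-12)
  expect_equal(sum(as.numeric(names(got)) * got), 9)  # expected 9 Cu
})

test_that("simulated envelopes deconvolve back to the true mass", {
  truth <- mnxGroundTruth()
  for (seed in c(5, 105)) {
    sp <- simulateSpectrum(truth, zCenter = 29, zSpread = 4, seed = seed)
    pk <- pickPeaks(sp, minRelIntensity = 0.05)
    envs <- assignCharges(pk, 20, 40, tolPpm = 500)
    expect_gt(length(envs), 0L)
    est <- neutralMass(envs[[which.max(vapply(envs, peakCount, integer(1)))]])
    expect_equal(estimatedMass(est), 211216, tolerance = 1e-3)
  }
})

test_that("low-energy SID cleaves the pendant; high energy has no homodimers", {
  truth <- mnxGroundTruth()
  low <- simulateDissociation(truth, "SID", 100, "low", seed = 2)
  cls <- observationClasses(low$observations)
  expect_setequal(names(cls), c("G1", "E3F3"))
  expect_true(all(cls == "major"))
  high <- simulateDissociation(truth, "SID", 5000, "high", seed = 2)
  labs <- names(observationClasses(high$observations))
  expect_false(any(c("E2", "E3", "F2", "F3") %in% labs))
  # all ring sizes appear, hexamers to monomers
  sizes <- sort(unique(high$fragments$size[high$fragments$label != "G1"]))
  expect_equal(sizes, 1:6)
  expect_error(simulateDissociation(truth, "UVPD", 10),
               class = "qmConfigError")
})

test_that("CID strips metals at the configured retention rate", {
  truth <- mnxGroundTruth()
  cid <- simulateDissociation(truth, "CID", 10000, seed = 6,
                              pRetainCID = 0.1)
  mono <- cid$fragments[cid$fragments$size == 1L, ]
  bound <- sum(mono$n_metals_bound * mono$count)
  kept <- sum(mono$n_metals * mono$count)
  # binomial oracle: observed retention within 3 SDs of p = 0.1
  p <- 0.1
  expect_lt(abs(kept / bound - p), 3 * sqrt(p * (1 - p) / bound))
  # SID, in contrast, mostly retains the metals
  sid <- simulateDissociation(truth, "SID", 5000, "high", seed = 6,
                              pRetainSID = 0.9)
  mono <- sid$fragments[sid$fragments$size == 1L, ]
  expect_gt(sum(mono$n_metals * mono$count) /
              sum(mono$n_metals_bound * mono$count), 0.8)
})

test_that("simulateDataset writes a self-consistent plain-text bundle", {
  truth <- mnxGroundTruth()
  dir <- withr::local_tempdir()
  simulateDataset(truth, dir, seed = 21)
  expect_true(all(file.exists(file.path(dir,
    c("peaks.tsv", "observations.csv", "fragments.csv", "calibrants.csv",
      "truth.json")))))
  sp <- readPeakList(file.path(dir, "peaks.tsv"))
  expect_gt(peakCount(sp), 100)
  obs <- readObservations(file.path(dir, "observations.csv"))
  expect_true("E3F3" %in% names(observationClasses(obs)))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$composition$MnxE, 3L)
})
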