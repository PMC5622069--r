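mp <- PROTON_MASS

test_that("charge assignment inverts the electrospray forward model", {
  # M = 100 kDa at z = 10..12
  pl <- PeakList(forwardMz(1e5, 10:12), rep(1, 3))
  envs <- assignCharges(pl, 1, 100)
  expect_length(envs, 1L)
  expect_equal(charges(envs[[1]]), c(12L, 11L, 10L))
  est <- neutralMass(envs[[1]])
  expect_equal(estimatedMass(est), 1e5, tolerance = 1e-9)
  expect_lt(massSD(est), 0.1)

  # the published intact mass at z = 27..31
  pl <- PeakList(forwardMz(211216, 27:31), rep(1, 5))
  envs <- assignCharges(pl, 20, 40)
  expect_length(envs, 1L)
  expect_equal(sort(charges(envs[[1]])), 27:31)
  expect_equal(estimatedMass(neutralMass(envs[[1]])), 211216,
               tolerance = 1e-9)
})

test_that("inconsistent spacings and single peaks yield no envelope", {
  # spacing implying z = 10.5 fails the integer-consistency check
  m1 <- forwardMz(1e5, 10)
  m2 <- m1 - (forwardMz(1e5, 10) - forwardMz(1e5, 11)) * 10 / 10.5
  expect_length(assignCharges(PeakList(c(m2, m1), c(1, 1)), 1, 100), 0L)
  expect_warning(out <- assignCharges(PeakList(5000, 1), 1, 100),
                 "ambiguous")
  expect_length(out, 0L)
})

test_that("synthesise-assign-invert recovers random masses within tolerance", {
  set.seed(91)
  for (i in 1:25) {
    M <- runif(1, 1e4, 1e6)
    zlo <- sample(5:40, 1)
    zs <- zlo:(zlo + sample(1:6, 1))
    pl <- PeakList(forwardMz(M, zs), runif(length(zs), 0.5, 2))
    envs <- assignCharges(pl, 1, 100, tolPpm = 20)
    expect_length(envs, 1L)
    expect_equal(estimatedMass(neutralMass(envs[[1]])), M,
                 tolerance = 20e-6)
  }
})

test_that("charge assignment ignores uniform intensity scaling", {
  pl1 <- PeakList(forwardMz(3e5, 20:24), c(1, 2, 3, 2, 1))
  pl2 <- PeakList(mz(pl1), intensity(pl1) * 1e4)
  e1 <- assignCharges(pl1, 1, 100)
  e2 <- assignCharges(pl2, 1, 100)
  expect_equal(lapply(e1, charges), lapply(e2, charges))
  expect_equal(estimatedMass(neutralMass(e1[[1]])),
               estimatedMass(neutralMass(e2[[1]])))
})

test_that("envelope fwhm maps to mass width; single members are flagged", {
  env <- ChargeEnvelope(forwardMz(211216, 27:31), 27:31,
                        fwhmMz = rep(55, 5))
  est <- neutralMass(env)
  expect_equal(estimatedMass(est), 211216, tolerance = 1e-6)
  expect_equal(massFWHM(est), 55 * 29)  # median z = 29
  one <- neutralMass(ChargeEnvelope(forwardMz(211216, 29), 29L))
  expect_true(one@lowConfidence)
  expect_equal(massSD(one), 0)
  expect_equal(one@nPeaks, 1L)
})

test_that("peak width converts to mass width linearly and checks domains", {
  expect_equal(massWidthFromPeakWidth(55, 29), 1595)
  expect_equal(massWidthFromPeakWidth(0, 17), 0)
  expect_equal(massWidthFromPeakWidth(7.3, 1), 7.3)
  # linear in both arguments
  expect_equal(massWidthFromPeakWidth(2 * 55, 29),
               2 * massWidthFromPeakWidth(55, 29))
  expect_equal(massWidthFromPeakWidth(55, 2 * 29),
               2 * massWidthFromPeakWidth(55, 29))
  expect_error(massWidthFromPeakWidth(-1, 10), class = "qmDomainError")
  expect_error(massWidthFromPeakWidth(10, 0), class = "qmDomainError")
})

test_that("adduct satellite series yield occupancy distributions", {
  # apo only
  expect_equal(occupancyProbs(detectAdductSeries(PeakList(2300, 10), 5, 63.546)),
               c("0" = 1))
  # 1:2:1 satellites at 63.546/5 Th spacing: occupancy {0,1,2} = {.25,.5,.25}
  pl <- PeakList(2300 + 0:2 * 63.546 / 5, c(1, 2, 1))
  occ <- detectAdductSeries(pl, 5, 63.546, maxAdducts = 3)
  expect_equal(occupancyProbs(occ),
               c("0" = 0.25, "1" = 0.5, "2" = 0.25))
  # dominant +1 satellite: modal occupancy 1
  pl <- PeakList(2450 + 0:2 * 63.546 / 5, c(0.1, 1, 0.05))
  occ <- detectAdductSeries(pl, 5, 63.546, maxAdducts = 2)
  expect_equal(modalOccupancy(occ), 1L)
  expect_error(detectAdductSeries(PeakList(numeric(), numeric()), 5, 63.5),
               class = "qmEmptyInput")
})

test_that("occupancy distributions always normalise with contiguous support", {
  set.seed(5)
  for (i in 1:20) {
    w <- runif(sample(1:6, 1))
    d <- OccupancyDistribution(w)
    expect_equal(sum(occupancyProbs(d)), 1, tolerance = 1e-12)
    expect_equal(names(occupancyProbs(d)),
                 as.character(seq_along(w) - 1L))
  }
  # detection from simulated monomer spectra stays normalised too
  truth <- mnxGroundTruth()
  mono <- GroundTruth(
    truth@catalog,
    Composition(c(MnxF = 1L), truth@catalog),
    TopologyGraph("F", matrix(integer(), ncol = 2), "connected"),
    metalOccupancy = truth@metalOccupancy["MnxF"])
  sp <- simulateSpectrum(mono, zCenter = 5, zSpread = 1, peakFwhmMz = 0.5,
                         noiseRel = 0, seed = 2, gridStep = 0.02)
  pk <- pickPeaks(sp, minRelIntensity = 0.05)
  series <- PeakList(mz(pk)[mz(pk) >= forwardMz(11907, 5) - 1e-3],
                     intensity(pk)[mz(pk) >= forwardMz(11907, 5) - 1e-3])
  occ <- detectAdductSeries(series, 5, 63.546, maxAdducts = 3)
  expect_equal(sum(occupancyProbs(occ)), 1, tolerance = 1e-12)
  # triangular truth occupancy recovered from the satellite intensities
  expect_equal(unname(occupancyProbs(occ)), c(0.25, 0.5, 0.25),
               tolerance = 0.02)
})
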