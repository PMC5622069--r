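## Charge-state assignment, neutral-mass estimation, and metal-adduct
## satellite-series analysis.
##
## The charging model is protonation only: an ion of neutral mass M at
## charge z appears at m/z = (M + z * m_p) / z with m_p = 1.007276 Da.
## Salt adducts are treated as mass heterogeneity, not charge carriers,
## as appropriate for electrospray from ammonium acetate.

#' Assign charge states to peak series
#'
#' For each adjacent peak pair (p1 at higher m/z, p2 at the next lower m/z)
#' the candidate charge of p1 is `z = round((p2 - m_p) / (p1 - p2))`, the
#' unique integer consistent with both peaks representing the same neutral
#' mass at consecutive charges. Envelopes are maximal runs of peaks whose
#' implied neutral masses agree within `tolPpm`; members carry consecutive
#' charges. When two assignments of a run both fit within tolerance, the one
#' with the lower RMS mass disagreement wins; remaining ties go to the lower
#' maximum charge.
#'
#' Charge assignment is invariant to uniform intensity scaling: intensities
#' play no role here beyond being carried along.
#'
#' @param peaks a [PeakList] with at least 2 peaks (a single peak is
#'   ambiguous and yields an empty list with a warning)
#' @param zMin,zMax allowed charge range, `1 <= zMin <= zMax <= 100`
#' @param tolPpm relative tolerance (ppm) for mass agreement within an
#'   envelope
#' @return list of [ChargeEnvelope] (possibly empty)
#' @examples
#' pl <- PeakList(c(8334.341, 9092.007, 10001.007), c(1, 1, 1))
#' assignCharges(pl, 5, 20)
#' @export
assignCharges <- function(peaks, zMin = 1L, zMax = 100L, tolPpm = 50) {
  stopifnot(zMin >= 1L, zMin <= zMax, zMax <= 100L)
  n <- peakCount(peaks)
  if (n < 2L) {
    warning("ambiguous: fewer than 2 peaks, no charge assignment possible")
    return(list())
  }
  mp <- PROTON_MASS
  # work in descending m/z: idx[1] has the lowest charge of any run
  o <- order(mz(peaks), decreasing = TRUE)
  pmz <- mz(peaks)[o]; pint <- intensity(peaks)[o]; pfw <- fwhmMz(peaks)[o]
  zPair <- rep(NA_integer_, n - 1L)
  okPair <- logical(n - 1L)
  for (i in seq_len(n - 1L)) {
    dmz <- pmz[i] - pmz[i + 1L]
    if (dmz <= 0) next
    zr <- (pmz[i + 1L] - mp) / dmz
    z <- as.integer(round(zr))
    if (z < zMin || z + 1L > zMax) next
    m1 <- z * (pmz[i] - mp)
    m2 <- (z + 1L) * (pmz[i + 1L] - mp)
    if (abs(m1 - m2) / m1 * 1e6 <= tolPpm) {
      zPair[i] <- z
      okPair[i] <- TRUE
    }
  }
  envelopes <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (!okPair[i]) { i <- i + 1L; next }
    j <- i
    # extend while consecutive pairs chain with incrementing charge and the
    # run's masses stay mutually within tolerance
    while (j + 1L <= n - 1L && okPair[j + 1L] &&
           zPair[j + 1L] == zPair[j] + 1L) {
      zs <- zPair[i] + 0:(j + 1L - i + 1L)
      ms <- zs * (pmz[i:(j + 2L)] - mp)
      if ((max(ms) - min(ms)) / mean(ms) * 1e6 > tolPpm) break
      j <- j + 1L
    }
    members <- i:(j + 1L)
    zs <- zPair[i] + (members - i)
    envelopes[[length(envelopes) + 1L]] <-
      ChargeEnvelope(mz = pmz[members], z = zs, intensity = pint[members],
                     fwhmMz = pfw[members])
    i <- j + 2L
  }
  envelopes
}

#' Estimate the neutral mass of a charge envelope
#'
#' The neutral mass is the intensity-weighted mean over members of
#' `z * (mz - m_p)`; the reported `sd` is the weighted standard deviation of
#' the per-member masses, and the mass-domain FWHM is the median over
#' members of `fwhm_mz * z` (see [massWidthFromPeakWidth()]).
#'
#' @param envelope a [ChargeEnvelope]
#' @return a [MassEstimate]; single-member envelopes are flagged low
#'   confidence with `sd = 0`
#' @export
neutralMass <- function(envelope) {
  stopifnot(is(envelope, "ChargeEnvelope"))
  m <- envelope@z * (envelope@mz - envelope@protonMass)
  w <- envelope@intensity
  if (all(w <= 0)) w <- rep(1, length(m))
  st <- weightedStats(m, w)
  MassEstimate(mass = st["mean"],
               sd = if (length(m) > 1L) st["sd"] else 0,
               fwhmMass = stats::median(envelope@fwhmMz * envelope@z),
               nPeaks = length(m),
               lowConfidence = length(m) < 2L)
}

#' Convert a peak width to a mass-determination width
#'
#' At charge z a peak width of `fwhm_mz` thomson corresponds to a width of
#' `fwhm_mz * z` daltons in the neutral-mass domain: the m/z axis is the
#' mass axis compressed z-fold (the constant proton offset does not affect
#' widths). For the ~211 kDa Mnx complex, the intact-complex peak FWHM of
#' 55 m/z at charge 29 corresponds to about 1.6 kDa of mass uncertainty.
#'
#' @param fwhmMz full width at half maximum in Th (>= 0)
#' @param z charge state (>= 1)
#' @return width in Da
#' @examples
#' massWidthFromPeakWidth(55, 29)  # 1595 Da, i.e. ~1.6 kDa
#' @export
massWidthFromPeakWidth <- function(fwhmMz, z) {
  if (any(fwhmMz < 0)) qmStop("fwhmMz must be >= 0", "qmDomainError")
  if (any(z < 1)) qmStop("z must be >= 1", "qmDomainError")
  fwhmMz * z
}

#' Read metal occupancy from an adduct satellite series
#'
#' A species binding k copies of an adduct of mass `adductDelta` appears, at
#' charge z, `k * adductDelta / z` thomson above the apo species. The lowest
#' m/z member of the supplied series is taken as the apo anchor (occupancy
#' 0); satellites are looked up at the expected positions and the occupancy
#' distribution is proportional to the matched peak intensities, with
#' unmatched expected positions contributing 0. Trailing never-observed
#' counts are dropped so the support runs 0..K(max observed).
#'
#' Modification-shifted series (e.g. gluconoylated protein and its
#' metal-bound satellites) are handled by running the detection once per
#' configured modification mass on a correspondingly filtered peak list.
#'
#' @param peaks a centroided [PeakList] containing the series
#' @param z charge state of the series
#' @param adductDelta adduct mass in Da (> 0). For Cu the atomic average
#'   63.546 is the default convention; if each bound Cu displaces `d`
#'   protons, use `63.546 - d * 1.008`
#' @param maxAdducts highest adduct count searched
#' @param tolPpm match tolerance on m/z (ppm)
#' @return an [OccupancyDistribution]
#' @examples
#' # MnxF 5+ series, satellites spaced 63.546/5 Th, intensities 1:2:1
#' apo <- 2300
#' pl <- PeakList(apo + 0:2 * 63.546 / 5, c(1, 2, 1))
#' detectAdductSeries(pl, z = 5, adductDelta = 63.546, maxAdducts = 3)
#' @export
detectAdductSeries <- function(peaks, z, adductDelta, maxAdducts = 5L,
                               tolPpm = 100) {
  stopifnot(adductDelta > 0, z >= 1)
  if (peakCount(peaks) == 0L)
    qmStop("no anchor peak: empty peak list", "qmEmptyInput")
  pmz <- mz(peaks); pint <- intensity(peaks)
  anchor <- pmz[1]
  expected <- anchor + (0:maxAdducts) * adductDelta / z
  inten <- numeric(maxAdducts + 1L)
  for (k in 0:maxAdducts) {
    d <- abs(pmz - expected[k + 1L])
    i <- which.min(d)
    if (d[i] / expected[k + 1L] * 1e6 <= tolPpm) inten[k + 1L] <- pint[i]
  }
  kmax <- max(which(inten > 0))
  OccupancyDistribution(inten[seq_len(kmax)])
}
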