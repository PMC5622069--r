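## Forward simulation: ground-truth complexes to spectra, dissociation
## tables and calibrant sets. Every generator is a pure function of
## (parameters, seed); the caller's RNG state is left untouched.

## map a topology node label (short label or full name) to its catalog row
.subunitRow <- function(catalog, label) {
  s <- subunits(catalog)
  i <- match(label, s$name)
  if (is.na(i)) i <- match(label, s$label)
  if (is.na(i))
    qmStop(sprintf("unknown subunit '%s'", label), "qmCatalogError")
  i
}

.occupancyFor <- function(truth, label) {
  occ <- truth@metalOccupancy
  if (label %in% names(occ)) return(occ[[label]])
  s <- subunits(truth@catalog)
  nm <- s$name[.subunitRow(truth@catalog, label)]
  if (nm %in% names(occ)) return(occ[[nm]])
  lb <- s$label[.subunitRow(truth@catalog, label)]
  if (lb %in% names(occ)) return(occ[[lb]])
  NULL
}

.convolveCounts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  out
}

#' Distribution of the total metal count of a complex
#'
#' Convolution of the per-copy occupancy distributions over every subunit
#' copy in the true composition (copies bind independently).
#'
#' @param truth a [GroundTruth]
#' @return an [OccupancyDistribution] over total bound-metal counts
#' @export
totalOccupancy <- function(truth) {
  p <- 1
  cnt <- truth@composition@counts
  for (nm in names(cnt)) {
    if (cnt[nm] == 0L) next
    d <- .occupancyFor(truth, nm)
    if (is.null(d)) next
    for (i in seq_len(cnt[nm])) p <- .convolveCounts(p, occupancyProbs(d))
  }
  OccupancyDistribution(p)
}

#' Simulate a native mass spectrum of a ground-truth complex
#'
#' Forward model of an intact-complex spectrum: Gaussian peaks at
#' `(M_k + z * m_p) / z` for every charge `z` in the envelope and every
#' metal-load variant `M_k = M_0 + k * delta` (the first catalog adduct),
#' with intensities from a discretised Gaussian envelope over z times the
#' total-occupancy probability of k, plus additive uniform noise scaled to
#' the base peak.
#'
#' @param truth a [GroundTruth]
#' @param zCenter centre of the charge envelope
#' @param zSpread half-width of the envelope in charge states (>= 1); the
#'   envelope covers `zCenter - zSpread .. zCenter + zSpread` with Gaussian
#'   weights of standard deviation `zSpread / 1.5`
#' @param peakFwhmMz per-peak FWHM in Th
#' @param noiseRel uniform noise amplitude as a fraction of the base peak
#' @param seed integer; same seed, same spectrum, bit for bit
#' @param gridStep profile grid spacing in Th (default `peakFwhmMz / 20`)
#' @return a [MassSpectrum] (profile)
#' @examples
#' sp <- simulateSpectrum(mnxGroundTruth(), seed = 42)
#' @export
simulateSpectrum <- function(truth, zCenter = 29L, zSpread = 4L,
                             peakFwhmMz = 55, noiseRel = 0.01, seed = 1L,
                             gridStep = NULL) {
  stopifnot(zSpread >= 1L, peakFwhmMz > 0, noiseRel >= 0)
  m0 <- compositionMass(truth@composition@counts, truth@catalog)
  a <- adducts(truth@catalog)
  if (nrow(a) && length(truth@metalOccupancy)) {
    occ <- occupancyProbs(totalOccupancy(truth))
    delta <- a$delta[1]
  } else {
    occ <- c("0" = 1)
    delta <- 0
  }
  zs <- seq.int(zCenter - zSpread, zCenter + zSpread)
  zw <- stats::dnorm(zs, zCenter, zSpread / 1.5)
  zw <- zw / max(zw)
  masses <- m0 + (seq_along(occ) - 1L) * delta
  pos <- outer(masses, zs, function(m, z) (m + z * PROTON_MASS) / z)
  amp <- outer(occ / max(occ), zw)
  sdmz <- peakFwhmMz / (2 * sqrt(2 * log(2)))
  if (is.null(gridStep)) gridStep <- peakFwhmMz / 20
  grid <- seq(min(pos) - 4 * peakFwhmMz, max(pos) + 4 * peakFwhmMz,
              by = gridStep)
  y <- numeric(length(grid))
  for (i in seq_along(masses)) {
    for (j in seq_along(zs)) {
      if (amp[i, j] < 1e-6) next
      lo <- findInterval(pos[i, j] - 5 * sdmz, grid)
      hi <- findInterval(pos[i, j] + 5 * sdmz, grid) + 1L
      idx <- max(1L, lo):min(length(grid), hi)
      y[idx] <- y[idx] + amp[i, j] * exp(-(grid[idx] - pos[i, j])^2 /
                                           (2 * sdmz^2))
    }
  }
  if (noiseRel > 0)
    y <- y + withSeed(seed, stats::runif(length(y), 0, noiseRel * max(y)))
  MassSpectrum(grid, y, metadata = list(source = "simulateSpectrum",
                                        seed = as.integer(seed)))
}

## pendant-node detection: the node whose removal leaves a single cycle
.splitPendant <- function(topology) {
  n <- length(topology@labels)
  e <- topology@edges
  deg <- tabulate(c(e), nbins = n)
  for (v in seq_len(n)) {
    keep <- e[e[, 1] != v & e[, 2] != v, , drop = FALSE]
    rest <- setdiff(seq_len(n), v)
    degRest <- tabulate(c(keep), nbins = n)[rest]
    if (length(rest) >= 3L && all(degRest == 2L) &&
        .edgesConnected(n - 1L, matrix(match(keep, rest)[seq_along(keep)],
                                       ncol = 2)))
      return(list(pendant = v, ring = rest))
  }
  NULL
}

## ring node order for arc sampling
.ringNodeOrder <- function(topology, ringNodes) {
  e <- topology@edges
  keep <- e[e[, 1] %in% ringNodes & e[, 2] %in% ringNodes, , drop = FALSE]
  sub <- TopologyGraph(topology@labels[ringNodes],
                       matrix(match(keep, ringNodes), ncol = 2),
                       family = "ring")
  ringNodes[.cycleOrder(sub)]
}

#' Simulate gas-phase dissociation of a ground-truth complex
#'
#' Forward model of SID and CID behaviour. SID at low energy cleaves the
#' weakest interface: for a ring-plus-pendant truth every event emits the
#' pendant-cleavage pair (e.g. the MnxG monomer and the intact E3F3
#' hexamer); a plain ring survives intact. SID at high energy samples
#' contiguous ring arcs with size-biased probability
#' `P(k) ~ exp(-|k - n/2| / tau)` and each bound metal is retained with
#' probability `pRetainSID` (SID keeps subunits folded, so metals mostly
#' stay). CID ejects single unfolded monomers, leaving the stripped
#' complex, and retains each metal with probability `pRetainCID` only.
#'
#' @param truth a [GroundTruth] whose topology is `ring` or
#'   `ring_plus_pendant`
#' @param mode `"SID"` or `"CID"`
#' @param nEvents number of dissociation events (>= 1)
#' @param energy `"low"` or `"high"` (SID only)
#' @param seed integer seed; deterministic per seed
#' @param pRetainSID,pRetainCID per-metal retention probabilities
#' @param tau arc-size bias scale (subunits)
#' @param thresholds abundance-class thresholds, see [classifyAbundance()]
#' @return list with `observations` (an [ObservationSet]) and `fragments`
#'   (data.frame: `label`, `size`, `n_metals_bound`, `n_metals` retained,
#'   `mass`, `count`)
#' @examples
#' sim <- simulateDissociation(mnxGroundTruth(), "SID", 500, "high", seed = 7)
#' sim$observations
#' @export
simulateDissociation <- function(truth, mode = c("SID", "CID"),
                                 nEvents = 1000L, energy = c("high", "low"),
                                 seed = 1L, pRetainSID = 0.9,
                                 pRetainCID = 0.1, tau = 1.5,
                                 thresholds = c(major = 0.2, minor = 0.02,
                                                trace = 0.005)) {
  if (!is.character(mode) || !all(mode %in% c("SID", "CID")))
    qmStop(sprintf("unknown dissociation mode '%s'", mode[1]), "qmConfigError")
  mode <- match.arg(mode)
  energy <- match.arg(energy)
  stopifnot(nEvents >= 1L)
  topo <- truth@topology
  sp <- if (topo@family == "ring_plus_pendant") .splitPendant(topo) else NULL
  ringNodes <- if (is.null(sp)) seq_along(topo@labels) else sp$ring
  ringOrder <- .ringNodeOrder(topo, ringNodes)
  ringLabels <- topo@labels[ringOrder]
  m <- length(ringLabels)
  pendantLabel <- if (is.null(sp)) NULL else topo@labels[sp$pendant]
  a <- adducts(truth@catalog)
  delta <- if (nrow(a)) a$delta[1] else 0
  s <- subunits(truth@catalog)
  labelMass <- function(lab) s$mass[.subunitRow(truth@catalog, lab)]
  pRetain <- if (mode == "SID") pRetainSID else pRetainCID
  drawMetals <- function(labs) {
    bound <- 0L
    for (l in labs) {
      d <- .occupancyFor(truth, l)
      if (is.null(d)) next
      k <- sample.int(length(occupancyProbs(d)), 1L,
                      prob = occupancyProbs(d)) - 1L
      bound <- bound + k
    }
    retained <- if (bound > 0L) stats::rbinom(1L, bound, pRetain) else 0L
    c(bound = bound, retained = retained)
  }
  rows <- list()
  addFrag <- function(labs) {
    met <- drawMetals(labs)
    lab <- .countsToLabel(labs)
    mass <- sum(vapply(labs, labelMass, numeric(1))) + met["retained"] * delta
    rows[[length(rows) + 1L]] <<-
      data.frame(label = lab, size = length(labs),
                 n_metals_bound = unname(met["bound"]),
                 n_metals = unname(met["retained"]), mass = unname(mass))
  }
  withSeed(seed, {
    if (mode == "SID" && energy == "low") {
      for (i in seq_len(nEvents)) {
        if (!is.null(pendantLabel)) {
          addFrag(pendantLabel)
          addFrag(ringLabels)
        } else addFrag(ringLabels)
      }
    } else if (mode == "SID") {
      sizes <- seq_len(m)
      pw <- exp(-abs(sizes - m / 2) / tau)
      for (i in seq_len(nEvents)) {
        if (!is.null(pendantLabel)) addFrag(pendantLabel)
        k <- sample(sizes, 1L, prob = pw)
        if (k == m) addFrag(ringLabels)
        else {
          start <- sample.int(m, 1L)
          addFrag(ringLabels[((start - 1L + 0:(k - 1L)) %% m) + 1L])
        }
      }
    } else {
      # CID: single-monomer ejection from the ring, stripped complex remains
      full <- c(ringLabels, pendantLabel)
      for (i in seq_len(nEvents)) {
        v <- sample.int(m, 1L)
        addFrag(ringLabels[v])
        addFrag(c(ringLabels[-v], pendantLabel))
      }
    }
  })
  frags <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(frags))),
                          frags[c("label", "size", "n_metals_bound",
                                  "n_metals", "mass")], FUN = sum)
  agg <- agg[order(agg$size, agg$label, agg$n_metals), , drop = FALSE]
  rownames(agg) <- NULL
  labelCounts <- tapply(rep(1L, nrow(frags)), frags$label, sum)
  labelCounts <- structure(as.integer(labelCounts), names = names(labelCounts))
  list(observations = classifyAbundance(labelCounts, thresholds),
       fragments = agg)
}

#' Simulate ion-mobility calibrant records
#'
#' Draws plausible protein ions (mass, charge, cross section) and computes
#' their drift times by inverting the power-law calibration forward model,
#' so a fit to the noise-free output recovers `(lnA, b)` exactly.
#'
#' @param lnA,b true calibration parameters
#' @param edc,gasMass instrument constants, see [fitCalibration()]
#' @param n number of calibrants (>= 2)
#' @param noiseRel multiplicative drift-time noise (standard deviation as a
#'   fraction; 0 for noise-free)
#' @param seed integer seed
#' @return data.frame with columns `name`, `mass`, `z`, `drift_time`,
#'   `ccs_lit`
#' @export
simulateCalibrants <- function(lnA = log(250), b = 0.55, edc = 1.57,
                               gasMass = 28.0134, n = 8L, noiseRel = 0,
                               seed = 1L) {
  stopifnot(n >= 2L)
  withSeed(seed, {
    mass <- stats::runif(n, 2e4, 8e5)
    z <- pmax(1L, as.integer(round(0.07 * sqrt(mass))))
    ccs <- 2.6 * mass^(2 / 3) * exp(stats::rnorm(n, 0, 0.05))
    mu <- .reducedMass(mass, gasMass)
    tprime <- ((ccs * sqrt(mu) / z) / exp(lnA))^(1 / b)
    mzv <- (mass + z * PROTON_MASS) / z
    td <- tprime + edc * sqrt(mzv) / 1000
    if (noiseRel > 0) td <- td * (1 + stats::rnorm(n, 0, noiseRel))
    data.frame(name = sprintf("cal%02d", seq_len(n)), mass = mass, z = z,
               drift_time = td, ccs_lit = ccs)
  })
}

#' Write a complete simulated dataset to a directory
#'
#' Generates a spectrum, SID observation/fragment tables and a calibrant
#' table from one ground truth and seed, as plain-text files
#' (`peaks.tsv`, `observations.csv`, `fragments.csv`, `calibrants.csv`,
#' `truth.json`).
#'
#' @param truth a [GroundTruth]
#' @param dir output directory (created if needed)
#' @param seed integer master seed for all generators
#' @param ... passed to [simulateSpectrum()]
#' @return `dir`, invisibly
#' @export
simulateDataset <- function(truth, dir, seed = truth@seed, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- simulateSpectrum(truth, seed = seed, ...)
  writePeakList(sp, file.path(dir, "peaks.tsv"))
  sid <- simulateDissociation(truth, "SID", nEvents = 1000L,
                              energy = "high", seed = seed + 1L)
  obs <- observationClasses(sid$observations)
  utils::write.csv(data.frame(composition = names(obs), class = unname(obs)),
                   file.path(dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(sid$fragments, file.path(dir, "fragments.csv"),
                   row.names = FALSE)
  utils::write.csv(simulateCalibrants(n = 8L, seed = seed + 2L),
                   file.path(dir, "calibrants.csv"), row.names = FALSE)
  s <- subunits(truth@catalog)
  jsonlite::write_json(list(
    composition = as.list(truth@composition@counts),
    topology = canonicalString(truth@topology),
    subunits = s, seed = seed), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
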