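#' Proton mass used by the electrospray charging model
#'
#' Average mass of the proton in daltons. Native electrospray in ammonium
#' acetate charges complexes by protonation only, so an ion of neutral mass
#' \eqn{M} and charge \eqn{z} appears at \eqn{m/z = (M + z m_p)/z}.
#'
#' @export
PROTON_MASS <- 1.007276

.ABUNDANCE_CLASSES <- c("major", "minor", "trace", "absent")
.TOPOLOGY_FAMILIES <- c("ring", "ring_plus_pendant", "tree", "connected")

qmStop <- function(msg, class) {
  stop(structure(
    class = c(class, "quatMSError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## ---------------------------------------------------------------------------
## MassSpectrum
## ---------------------------------------------------------------------------

#' MassSpectrum: an m/z versus intensity trace
#'
#' Ordered m/z-intensity pairs (profile or centroided) with free-form
#' metadata. The constructor sorts by m/z and sums intensities at duplicated
#' m/z values, so the stored axis is strictly increasing.
#'
#' @slot mz numeric, strictly increasing m/z values in thomson (Th)
#' @slot intensity numeric, non-negative intensities (arbitrary units)
#' @slot metadata list of free-text keys (instrument mode, activation type,
#'   source path, ...)
#'
#' @param mz,intensity numeric vectors of equal length
#' @param metadata named list
#' @return a `MassSpectrum`
#' @examples
#' sp <- MassSpectrum(c(1000, 1001, 1002), c(1, 5, 2))
#' mz(sp)
#' @export MassSpectrum
#' @exportClass MassSpectrum
#' @aliases MassSpectrum-class
setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric", metadata = "list"))

setValidity("MassSpectrum", function(object) {
  if (length(object@mz) == 0L) return("spectrum must be non-empty")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity lengths differ")
  if (any(!is.finite(object@mz)) || any(!is.finite(object@intensity)))
    return("non-finite mz or intensity")
  if (is.unsorted(object@mz, strictly = TRUE))
    return("mz must be strictly increasing")
  if (any(object@intensity < 0)) return("negative intensity")
  TRUE
})

MassSpectrum <- function(mz, intensity, metadata = list()) {
  if (length(mz) == 0L) qmStop("empty spectrum", "qmEmptyInput")
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  new("MassSpectrum", mz = mz, intensity = intensity, metadata = metadata)
}

#' @rdname MassSpectrum
#' @param object a `MassSpectrum`
#' @export
spectrumMetadata <- function(object) object@metadata

setMethod("mz", "MassSpectrum", function(object) object@mz)
setMethod("intensity", "MassSpectrum", function(object) object@intensity)
setMethod("peakCount", "MassSpectrum", function(object) length(object@mz))

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum: %d points, m/z %.2f-%.2f\n",
              length(object@mz), min(object@mz), max(object@mz)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## PeakList
## ---------------------------------------------------------------------------

#' PeakList: centroided peaks with width estimates
#'
#' @slot mz numeric, peak apex m/z (Th), strictly increasing
#' @slot intensity numeric, apex intensity
#' @slot fwhmMz numeric, full width at half maximum in Th (0 when unknown or
#'   when a flank was truncated during centroiding)
#'
#' @param mz,intensity,fwhmMz numeric vectors of equal length
#' @return a `PeakList`
#' @export PeakList
#' @exportClass PeakList
#' @aliases PeakList-class
setClass("PeakList",
  representation(mz = "numeric", intensity = "numeric", fwhmMz = "numeric"))

setValidity("PeakList", function(object) {
  n <- length(object@mz)
  if (length(object@intensity) != n || length(object@fwhmMz) != n)
    return("slot lengths differ")
  if (n == 0L) return(TRUE)
  if (any(object@mz <= 0)) return("mz must be positive")
  if (any(object@fwhmMz < 0)) return("fwhmMz must be >= 0")
  if (is.unsorted(object@mz)) return("peaks must be sorted by mz")
  if (any(diff(object@mz) < 1e-6)) return("duplicate mz within 1e-6 Th")
  TRUE
})

PeakList <- function(mz, intensity, fwhmMz = rep(0, length(mz))) {
  o <- order(mz)
  new("PeakList", mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      fwhmMz = as.numeric(fwhmMz[o]))
}

setMethod("mz", "PeakList", function(object) object@mz)
setMethod("intensity", "PeakList", function(object) object@intensity)
setMethod("fwhmMz", "PeakList", function(object) object@fwhmMz)
setMethod("peakCount", "PeakList", function(object) length(object@mz))

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: %d peaks", length(object@mz)))
  if (length(object@mz))
    cat(sprintf(", m/z %.2f-%.2f", min(object@mz), max(object@mz)))
  cat("\n")
})

#' Coerce a PeakList to a data.frame
#'
#' @param x a `PeakList`
#' @param ... ignored
#' @return data.frame with columns `mz`, `intensity`, `fwhm_mz`
#' @export
as.data.frame.PeakList <- function(x, ...) {
  data.frame(mz = x@mz, intensity = x@intensity, fwhm_mz = x@fwhmMz)
}

## ---------------------------------------------------------------------------
## ChargeEnvelope / MassEstimate
## ---------------------------------------------------------------------------

#' ChargeEnvelope: peaks with assigned consecutive charge states
#'
#' A maximal run of peaks whose implied neutral masses agree; charge
#' decreases as m/z increases.
#'
#' @slot mz,intensity,fwhmMz numeric, member peaks (ascending m/z)
#' @slot z integer, charge per member (strictly decreasing)
#' @slot protonMass numeric, mass of the charging proton (Da)
#'
#' @param mz,intensity,fwhmMz,z member vectors
#' @param protonMass charging proton mass in Da
#' @return a `ChargeEnvelope`
#' @export ChargeEnvelope
#' @exportClass ChargeEnvelope
#' @aliases ChargeEnvelope-class
setClass("ChargeEnvelope",
  representation(mz = "numeric", intensity = "numeric", fwhmMz = "numeric",
                 z = "integer", protonMass = "numeric"))

setValidity("ChargeEnvelope", function(object) {
  n <- length(object@mz)
  if (n == 0L) return("empty envelope")
  if (length(object@z) != n) return("z length differs from mz")
  if (any(object@z < 1L)) return("charges must be >= 1")
  if (n > 1L) {
    if (is.unsorted(object@mz, strictly = TRUE)) return("mz must increase")
    if (any(diff(object@z) >= 0L)) return("z must strictly decrease with mz")
  }
  TRUE
})

ChargeEnvelope <- function(mz, z, intensity = rep(1, length(mz)),
                           fwhmMz = rep(0, length(mz)),
                           protonMass = PROTON_MASS) {
  o <- order(mz)
  new("ChargeEnvelope", mz = as.numeric(mz[o]),
      intensity = as.numeric(intensity[o]), fwhmMz = as.numeric(fwhmMz[o]),
      z = as.integer(z[o]), protonMass = protonMass)
}

setMethod("mz", "ChargeEnvelope", function(object) object@mz)
setMethod("intensity", "ChargeEnvelope", function(object) object@intensity)
setMethod("fwhmMz", "ChargeEnvelope", function(object) object@fwhmMz)
setMethod("charges", "ChargeEnvelope", function(object) object@z)
setMethod("peakCount", "ChargeEnvelope", function(object) length(object@mz))

setMethod("show", "ChargeEnvelope", function(object) {
  cat(sprintf("ChargeEnvelope: %d members, z = %d..%d\n",
              length(object@mz), min(object@z), max(object@z)))
})

#' MassEstimate: a neutral mass with uncertainty
#'
#' @slot mass numeric, neutral mass M (Da)
#' @slot sd numeric, weighted standard deviation of per-member masses (Da)
#' @slot fwhmMass numeric, mass-domain FWHM (Da), median of per-member
#'   `fwhm_mz * z`
#' @slot nPeaks integer, number of envelope members used
#' @slot lowConfidence logical, `TRUE` when derived from a single peak
#'
#' @param mass,sd,fwhmMass,nPeaks,lowConfidence see slots
#' @return a `MassEstimate`
#' @export MassEstimate
#' @exportClass MassEstimate
#' @aliases MassEstimate-class
setClass("MassEstimate",
  representation(mass = "numeric", sd = "numeric", fwhmMass = "numeric",
                 nPeaks = "integer", lowConfidence = "logical"))

setValidity("MassEstimate", function(object) {
  if (object@mass <= 0) return("mass must be positive")
  if (object@sd < 0) return("sd must be >= 0")
  if (object@fwhmMass < 0) return("fwhmMass must be >= 0")
  TRUE
})

MassEstimate <- function(mass, sd = 0, fwhmMass = 0, nPeaks = 1L,
                         lowConfidence = FALSE) {
  new("MassEstimate", mass = unname(mass), sd = unname(sd),
      fwhmMass = unname(fwhmMass), nPeaks = as.integer(nPeaks),
      lowConfidence = lowConfidence)
}

#' @rdname MassEstimate
#' @param object a `MassEstimate`
#' @export
estimatedMass <- function(object) object@mass

#' @rdname MassEstimate
#' @export
massSD <- function(object) object@sd

#' @rdname MassEstimate
#' @export
massFWHM <- function(object) object@fwhmMass

setMethod("show", "MassEstimate", function(object) {
  cat(sprintf("MassEstimate: %.1f Da (sd %.2f, FWHM %.0f Da, %d peaks%s)\n",
              object@mass, object@sd, object@fwhmMass, object@nPeaks,
              if (object@lowConfidence) ", low confidence" else ""))
})

## ---------------------------------------------------------------------------
## OccupancyDistribution
## ---------------------------------------------------------------------------

#' OccupancyDistribution: fraction of molecules carrying k adducts
#'
#' Probabilities over adduct counts 0..K, contiguous from zero, summing to 1.
#'
#' @slot probs numeric, named "0", "1", ..., fractions summing to 1
#'
#' @param probs numeric vector of non-negative weights for counts `0..K`
#'   (normalised by the constructor)
#' @return an `OccupancyDistribution`
#' @export OccupancyDistribution
#' @exportClass OccupancyDistribution
#' @aliases OccupancyDistribution-class
setClass("OccupancyDistribution", representation(probs = "numeric"))

setValidity("OccupancyDistribution", function(object) {
  p <- object@probs
  if (length(p) == 0L) return("empty distribution")
  if (any(p < 0)) return("negative fraction")
  if (abs(sum(p) - 1) > 1e-9) return("fractions must sum to 1")
  if (!identical(names(p), as.character(seq_along(p) - 1L)))
    return("counts must be contiguous from 0")
  TRUE
})

OccupancyDistribution <- function(probs) {
  s <- sum(probs)
  if (s <= 0) qmStop("all-zero occupancy weights", "qmEmptyInput")
  p <- as.numeric(probs) / s
  names(p) <- as.character(seq_along(p) - 1L)
  new("OccupancyDistribution", probs = p)
}

#' @rdname OccupancyDistribution
#' @param object an `OccupancyDistribution`
#' @export
occupancyProbs <- function(object) object@probs

#' @rdname OccupancyDistribution
#' @export
modalOccupancy <- function(object) {
  as.integer(names(object@probs)[which.max(object@probs)])
}

#' @rdname OccupancyDistribution
#' @export
meanOccupancy <- function(object) {
  sum(as.numeric(names(object@probs)) * object@probs)
}

setMethod("show", "OccupancyDistribution", function(object) {
  cat("OccupancyDistribution:",
      paste(sprintf("%s:%.3f", names(object@probs), object@probs),
            collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## SubunitCatalog / Composition
## ---------------------------------------------------------------------------

#' SubunitCatalog: subunit and adduct masses with copy-number bounds
#'
#' The mass bookkeeping for composition solving: average subunit masses with
#' allowed copy ranges, plus adduct/modification masses (metals, covalent
#' artefacts) with maximum counts. `label` is the short symbol used in
#' composition strings such as `"E3F3"`; it defaults to the full name.
#'
#' @slot subunits data.frame with columns `name`, `label`, `mass` (Da,
#'   average), `min_copies`, `max_copies`
#' @slot adducts data.frame with columns `name`, `label`, `delta` (Da),
#'   `max_count`
#'
#' @param subunits data.frame with at least `name`, `mass`, `min_copies`,
#'   `max_copies` (optional `label`)
#' @param adducts data.frame with at least `name`, `delta`, `max_count`
#'   (optional `label`); may be empty
#' @return a `SubunitCatalog`
#' @examples
#' cat6 <- SubunitCatalog(data.frame(
#'   name = c("MnxG", "MnxE", "MnxF"), label = c("G", "E", "F"),
#'   mass = c(139000, 12000, 12000),
#'   min_copies = 0, max_copies = c(1, 8, 8)))
#' @export SubunitCatalog
#' @exportClass SubunitCatalog
#' @aliases SubunitCatalog-class
setClass("SubunitCatalog",
  representation(subunits = "data.frame", adducts = "data.frame"))

setValidity("SubunitCatalog", function(object) {
  s <- object@subunits
  need <- c("name", "label", "mass", "min_copies", "max_copies")
  if (!all(need %in% names(s))) return("missing subunit columns")
  if (nrow(s) == 0L) return("catalog must have at least one subunit")
  if (any(s$mass <= 0)) return("subunit masses must be positive")
  if (any(s$min_copies < 0) || any(s$min_copies > s$max_copies))
    return("require 0 <= min_copies <= max_copies")
  if (anyDuplicated(s$name) || anyDuplicated(s$label))
    return("subunit names/labels must be unique")
  a <- object@adducts
  if (nrow(a)) {
    if (!all(c("name", "label", "delta", "max_count") %in% names(a)))
      return("missing adduct columns")
    if (any(a$delta <= 0)) return("adduct deltas must be positive")
    if (anyDuplicated(c(s$name, a$name))) return("names must be unique")
  }
  TRUE
})

SubunitCatalog <- function(subunits, adducts = NULL) {
  subunits <- as.data.frame(subunits)
  if (is.null(subunits$label)) subunits$label <- subunits$name
  subunits$label <- as.character(subunits$label)
  subunits$name <- as.character(subunits$name)
  if (is.null(adducts) || NROW(adducts) == 0L) {
    adducts <- data.frame(name = character(), label = character(),
                          delta = numeric(), max_count = integer())
  } else {
    adducts <- as.data.frame(adducts)
    if (is.null(adducts$label)) adducts$label <- adducts$name
    adducts$name <- as.character(adducts$name)
    adducts$label <- as.character(adducts$label)
  }
  new("SubunitCatalog", subunits = subunits, adducts = adducts)
}

#' @rdname SubunitCatalog
#' @param object a `SubunitCatalog`
#' @export
subunits <- function(object) object@subunits

#' @rdname SubunitCatalog
#' @export
adducts <- function(object) object@adducts

setMethod("show", "SubunitCatalog", function(object) {
  cat(sprintf("SubunitCatalog: %d subunits (%s)", nrow(object@subunits),
              paste(object@subunits$name, collapse = ", ")))
  if (nrow(object@adducts))
    cat(sprintf(", %d adducts (%s)", nrow(object@adducts),
                paste(object@adducts$name, collapse = ", ")))
  cat("\n")
})

#' Composition: integer subunit and adduct counts
#'
#' An integer count vector over a catalog, with the theoretical mass it
#' implies and, when matched against an observation, the signed mass error
#' (observed minus theoretical).
#'
#' @slot counts named integer, copies per subunit name
#' @slot adductCounts named integer, count per adduct name
#' @slot theoreticalMass numeric (Da)
#' @slot massError numeric (Da, observed - theoretical; `NA` when not matched)
#'
#' @param counts,adductCounts named integer vectors
#' @param catalog a `SubunitCatalog` used to compute the theoretical mass
#' @param massError signed observed-minus-theoretical error in Da
#' @return a `Composition`
#' @export Composition
#' @exportClass Composition
#' @aliases Composition-class
setClass("Composition",
  representation(counts = "integer", adductCounts = "integer",
                 theoreticalMass = "numeric", massError = "numeric"))

setValidity("Composition", function(object) {
  if (any(object@counts < 0) || any(object@adductCounts < 0))
    return("counts must be non-negative")
  TRUE
})

Composition <- function(counts, catalog, adductCounts = integer(),
                        massError = NA_real_) {
  counts <- structure(as.integer(counts), names = names(counts))
  adductCounts <- structure(as.integer(adductCounts), names = names(adductCounts))
  obj <- new("Composition", counts = counts, adductCounts = adductCounts,
             theoreticalMass = 0, massError = massError)
  obj@theoreticalMass <- compositionMass(obj, catalog)
  obj
}

#' @rdname Composition
#' @param object a `Composition`
#' @export
subunitCounts <- function(object) object@counts

#' @rdname Composition
#' @export
adductCounts <- function(object) object@adductCounts

#' @rdname Composition
#' @export
theoreticalMass <- function(object) object@theoreticalMass

#' @rdname Composition
#' @export
massError <- function(object) object@massError

setMethod("show", "Composition", function(object) {
  cc <- object@counts[object@counts > 0]
  lab <- if (length(cc)) paste(names(cc), cc, sep = "x", collapse = " + ")
         else "(empty)"
  ad <- object@adductCounts[object@adductCounts > 0]
  if (length(ad))
    lab <- paste(lab, "+", paste(names(ad), ad, sep = "x", collapse = " + "))
  cat(sprintf("Composition: %s, %.2f Da", lab, object@theoreticalMass))
  if (!is.na(object@massError))
    cat(sprintf(" (error %+.2f Da)", object@massError))
  cat("\n")
})

## ---------------------------------------------------------------------------
## TopologyGraph / FragmentPrediction / ObservationSet / TopologyScore
## ---------------------------------------------------------------------------

#' TopologyGraph: labelled subunit connectivity
#'
#' A simple connected graph whose nodes are subunit copies (labelled by
#' subunit name) and whose edges are inter-subunit interfaces. Families:
#' `ring` (every node degree 2), `ring_plus_pendant` (a ring plus one pendant
#' node attached to one or more ring nodes), `tree`, and unconstrained
#' `connected`.
#'
#' @slot labels character, subunit name per node
#' @slot edges 2-column integer matrix of node index pairs
#' @slot family character, one of `ring`, `ring_plus_pendant`, `tree`,
#'   `connected`
#' @slot canonical character, canonical identifying string (for rings the
#'   lexicographically minimal rotation/reflection of the label sequence)
#'
#' @param labels,edges,family,canonical see slots; `canonical` defaults to a
#'   computed canonical form
#' @return a `TopologyGraph`
#' @export TopologyGraph
#' @exportClass TopologyGraph
#' @aliases TopologyGraph-class
setClass("TopologyGraph",
  representation(labels = "character", edges = "matrix", family = "character",
                 canonical = "character"))

setValidity("TopologyGraph", function(object) {
  n <- length(object@labels)
  if (n == 0L) return("no nodes")
  if (!object@family %in% .TOPOLOGY_FAMILIES) return("unknown family")
  e <- object@edges
  if (nrow(e)) {
    if (any(e < 1L) || any(e > n)) return("edge index out of range")
    if (any(e[, 1] == e[, 2])) return("self-loop")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) return("multi-edge")
  }
  # connectivity (BFS)
  if (n > 1L) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(e))) {
      adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
      adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
    }
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen)) return("graph must be connected")
  }
  deg <- tabulate(c(object@edges), nbins = n)
  if (object@family == "ring" && n >= 3L && any(deg != 2L))
    return("ring family requires every node degree 2")
  TRUE
})

TopologyGraph <- function(labels, edges, family = "connected",
                          canonical = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  obj <- new("TopologyGraph", labels = as.character(labels), edges = edges,
             family = family, canonical = canonical %||% "")
  if (identical(obj@canonical, ""))
    obj@canonical <- .graphCanonicalString(obj)
  obj
}

setMethod("nodeLabels", "TopologyGraph", function(object) object@labels)
setMethod("canonicalString", "TopologyGraph", function(object) object@canonical)

#' @rdname TopologyGraph
#' @param object a `TopologyGraph`
#' @export
topologyEdges <- function(object) object@edges

#' @rdname TopologyGraph
#' @export
topologyFamily <- function(object) object@family

setMethod("show", "TopologyGraph", function(object) {
  cat(sprintf("TopologyGraph (%s): %s [%d nodes, %d edges]\n", object@family,
              object@canonical, length(object@labels), nrow(object@edges)))
})

#' FragmentPrediction: subcomplexes a topology can release
#'
#' The multiset of compositions of all connected induced subgraphs of a
#' topology, keyed by composition label (e.g. `"E2F1"`) and, in `bySize`, by
#' subgraph node count.
#'
#' @slot multiset named integer, label to multiplicity
#' @slot bySize list of named integer vectors, indexed by subgraph size
#'
#' @param multiset,bySize see slots
#' @return a `FragmentPrediction`
#' @export FragmentPrediction
#' @exportClass FragmentPrediction
#' @aliases FragmentPrediction-class
setClass("FragmentPrediction",
  representation(multiset = "integer", bySize = "list"))

setValidity("FragmentPrediction", function(object) {
  if (any(object@multiset < 1L)) return("multiplicities must be >= 1")
  TRUE
})

FragmentPrediction <- function(multiset, bySize) {
  new("FragmentPrediction",
      multiset = structure(as.integer(multiset), names = names(multiset)),
      bySize = bySize)
}

#' @rdname FragmentPrediction
#' @param object a `FragmentPrediction`
#' @export
predictedMultiset <- function(object) object@multiset

#' @rdname FragmentPrediction
#' @export
predictedBySize <- function(object) object@bySize

setMethod("show", "FragmentPrediction", function(object) {
  cat("FragmentPrediction:",
      paste(sprintf("%sx%d", names(object@multiset), object@multiset),
            collapse = " "), "\n")
})

#' ObservationSet: observed fragment compositions with abundance classes
#'
#' @slot classes named character; names are composition labels, values one of
#'   `major`, `minor`, `trace`, `absent`
#'
#' @param classes named character vector (or two-column data.frame
#'   `composition`, `class`)
#' @return an `ObservationSet`
#' @export ObservationSet
#' @exportClass ObservationSet
#' @aliases ObservationSet-class
setClass("ObservationSet", representation(classes = "character"))

setValidity("ObservationSet", function(object) {
  if (!all(object@classes %in% .ABUNDANCE_CLASSES))
    return(sprintf("classes must be in {%s}",
                   paste(.ABUNDANCE_CLASSES, collapse = ", ")))
  if (is.null(names(object@classes)) || anyDuplicated(names(object@classes)))
    return("composition labels must be unique names")
  TRUE
})

ObservationSet <- function(classes) {
  if (is.data.frame(classes)) {
    cl <- as.character(classes$class)
    names(cl) <- as.character(classes$composition)
    classes <- cl
  }
  new("ObservationSet", classes = classes)
}

#' @rdname ObservationSet
#' @param object an `ObservationSet`
#' @export
observationClasses <- function(object) object@classes

setMethod("show", "ObservationSet", function(object) {
  cat(sprintf("ObservationSet: %d compositions (%d major, %d minor, %d trace, %d absent)\n",
              length(object@classes), sum(object@classes == "major"),
              sum(object@classes == "minor"), sum(object@classes == "trace"),
              sum(object@classes == "absent")))
})

#' TopologyScore: fit of a predicted fragment set to observations
#'
#' @slot total numeric, sum of per-composition contributions
#' @slot perComposition named numeric, contribution per composition label
#' @slot rank integer, 1 = best (set by [rankTopologies()]; `NA` otherwise)
#'
#' @param total,perComposition,rank see slots
#' @return a `TopologyScore`
#' @export TopologyScore
#' @exportClass TopologyScore
#' @aliases TopologyScore-class
setClass("TopologyScore",
  representation(total = "numeric", perComposition = "numeric",
                 rank = "integer"))

setValidity("TopologyScore", function(object) {
  if (length(object@perComposition) &&
      abs(object@total - sum(object@perComposition)) > 1e-9)
    return("total must equal the sum of contributions")
  TRUE
})

TopologyScore <- function(perComposition, rank = NA_integer_) {
  new("TopologyScore", total = sum(perComposition),
      perComposition = perComposition, rank = as.integer(rank))
}

#' @rdname TopologyScore
#' @param object a `TopologyScore`
#' @export
scoreTotal <- function(object) object@total

#' @rdname TopologyScore
#' @export
scoreBreakdown <- function(object) object@perComposition

setMethod("show", "TopologyScore", function(object) {
  cat(sprintf("TopologyScore: total %.1f over %d compositions%s\n",
              object@total, length(object@perComposition),
              if (!is.na(object@rank)) sprintf(" (rank %d)", object@rank) else ""))
})

## ---------------------------------------------------------------------------
## CCSCalibration
## ---------------------------------------------------------------------------

#' CCSCalibration: power-law drift-time to cross-section calibration
#'
#' Parameters of the travelling-wave calibration
#' \eqn{\ln CCS' = \ln a + b \ln t'} where \eqn{t'} is the EDC-corrected
#' drift time and \eqn{CCS' = CCS \sqrt{\mu} / z} the reduced cross section.
#'
#' @slot lnA numeric, intercept
#' @slot b numeric, exponent (> 0)
#' @slot edcCoefficient numeric, instrument EDC delay coefficient
#' @slot gasMass numeric, drift gas mass (Da)
#' @slot rSquared numeric in `[0, 1]`
#'
#' @param lnA,b,edcCoefficient,gasMass,rSquared see slots
#' @return a `CCSCalibration`
#' @export CCSCalibration
#' @exportClass CCSCalibration
#' @aliases CCSCalibration-class
setClass("CCSCalibration",
  representation(lnA = "numeric", b = "numeric", edcCoefficient = "numeric",
                 gasMass = "numeric", rSquared = "numeric"))

setValidity("CCSCalibration", function(object) {
  if (object@b <= 0) return("exponent b must be positive")
  if (object@rSquared < 0 || object@rSquared > 1)
    return("rSquared must lie in [0, 1]")
  TRUE
})

CCSCalibration <- function(lnA, b, edcCoefficient, gasMass, rSquared) {
  new("CCSCalibration", lnA = lnA, b = b, edcCoefficient = edcCoefficient,
      gasMass = gasMass, rSquared = rSquared)
}

#' @rdname CCSCalibration
#' @param object a `CCSCalibration`
#' @export
calibrationParams <- function(object) {
  c(ln_a = object@lnA, b = object@b, edc = object@edcCoefficient,
    gas_mass = object@gasMass, r_squared = object@rSquared)
}

setMethod("show", "CCSCalibration", function(object) {
  cat(sprintf("CCSCalibration: ln(a) = %.4f, b = %.4f, R^2 = %.6f\n",
              object@lnA, object@b, object@rSquared))
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' GroundTruth: a fully specified complex for forward simulation
#'
#' Everything the synthetic-data generators need: the catalog, the true
#' composition, the true topology, and per-subunit metal occupancy
#' distributions. All generators are pure functions of (truth, parameters,
#' seed).
#'
#' @slot catalog a `SubunitCatalog`
#' @slot composition a `Composition` consistent with the topology labels
#' @slot topology a `TopologyGraph`
#' @slot metalOccupancy named list of `OccupancyDistribution`, one per
#'   metal-binding subunit
#' @slot seed integer default seed
#'
#' @param catalog,composition,topology,metalOccupancy,seed see slots
#' @return a `GroundTruth`
#' @export GroundTruth
#' @exportClass GroundTruth
#' @aliases GroundTruth-class
setClass("GroundTruth",
  representation(catalog = "SubunitCatalog", composition = "Composition",
                 topology = "TopologyGraph", metalOccupancy = "list",
                 seed = "integer"))

setValidity("GroundTruth", function(object) {
  lab <- table(object@topology@labels)
  cnt <- object@composition@counts[object@composition@counts > 0]
  # topology nodes may carry either full subunit names or catalog short labels
  s <- object@catalog@subunits
  nm <- names(cnt)
  if (!all(names(lab) %in% nm))
    nm <- s$label[match(names(cnt), s$name)]
  names(cnt) <- nm
  if (!identical(sort(names(lab)), sort(nm)) ||
      any(as.integer(lab[nm]) != as.integer(cnt)))
    return("composition inconsistent with topology node labels")
  ok <- vapply(object@metalOccupancy, inherits, logical(1),
               "OccupancyDistribution")
  if (length(ok) && !all(ok))
    return("metalOccupancy entries must be OccupancyDistribution")
  TRUE
})

GroundTruth <- function(catalog, composition, topology,
                        metalOccupancy = list(), seed = 1L) {
  new("GroundTruth", catalog = catalog, composition = composition,
      topology = topology, metalOccupancy = metalOccupancy,
      seed = as.integer(seed))
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:\n  ")
  show(object@composition)
  cat("  ")
  show(object@topology)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
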