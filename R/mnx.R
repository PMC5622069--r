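## Ready-made objects for the Mnx manganese-oxidase complex, the system this
## package was built around: a ~211 kDa assembly of one multicopper-oxidase
## subunit MnxG (~139 kDa) and six ~12 kDa accessory subunits (three MnxE,
## three MnxF) arranged as an alternating hexamer, binding 10-15 Cu in total.

#' Subunit and adduct catalog for the Mnx complex
#'
#' With `round = TRUE`, the catalog carries the published approximate masses
#' (MnxG 139 kDa; MnxE and MnxF 12 kDa each), which suffice for
#' intact-complex stoichiometry at ~1.6 kDa tolerance. With `round = FALSE`
#' it carries *synthetic* reference masses: the exact subunit masses (with
#' MnxE's disulfide and MnxF's N-terminal truncation) are treated as
#' user-supplied catalog inputs, so the defaults here are plausible stand-ins
#' chosen such that the bare G1E3F3 complex plus a typical ~9-Cu load matches
#' the measured 211,216 Da intact mass. They are for simulation and testing,
#' not measured values.
#'
#' Adducts: Cu at its atomic average 63.546 Da (set `cuDisplacedProtons` to
#' 1 or 2 if each bound Cu is taken to displace protons, giving
#' 63.546 - d * 1.008); optionally the two covalent artefacts seen on
#' E/F monomers, gluconoylation (+176 Da) and AEBSF (+183 Da).
#'
#' @param round use the published rounded masses?
#' @param modifications include gluconoylation/AEBSF adducts?
#' @param maxCu maximum Cu count enumerated by the solver
#' @param cuDisplacedProtons protons displaced per bound Cu (0, 1 or 2)
#' @return a [SubunitCatalog]
#' @examples
#' mnxCatalog(round = TRUE)
#' @export
mnxCatalog <- function(round = FALSE, modifications = FALSE, maxCu = 20L,
                       cuDisplacedProtons = 0L) {
  stopifnot(cuDisplacedProtons %in% 0:2)
  masses <- if (round) c(MnxG = 139000, MnxE = 12000, MnxF = 12000)
            else c(MnxG = 138773, MnxE = 12050, MnxF = 11907)
  ad <- data.frame(name = "Cu", label = "Cu",
                   delta = 63.546 - cuDisplacedProtons * 1.008,
                   max_count = as.integer(maxCu))
  if (modifications)
    ad <- rbind(ad,
                data.frame(name = c("gluconoyl", "AEBSF"),
                           label = c("g", "b"), delta = c(176, 183),
                           max_count = c(1L, 1L)))
  SubunitCatalog(
    data.frame(name = names(masses), label = c("G", "E", "F"),
               mass = unname(masses), min_copies = 0L,
               max_copies = c(1L, 8L, 8L)),
    ad)
}

#' Observed SID subcomplex classes for the Mnx hexamer
#'
#' The high-energy SID observation set used for topology elimination:
#' heterodimers through the full hexamer are seen (E1F1 dimers dominate;
#' trimers split ~2:1 between E1F2 and E2F1), monomers are weak, homodimers
#' and homotrimers are not seen at all, and F2/E1F3 appear only at trace
#' level, consistent with secondary dissociation of larger pieces.
#'
#' @return an [ObservationSet]
#' @export
mnxObservations <- function() {
  ObservationSet(c(
    E1 = "minor", F1 = "minor",
    E1F1 = "major",
    E1F2 = "major", E2F1 = "minor",
    E2F2 = "major", E2F3 = "major", E3F3 = "major",
    F2 = "trace", E1F3 = "trace",
    E2 = "absent", E3 = "absent", F3 = "absent", E3F1 = "absent"))
}

#' Ground truth emulating the Mnx complex
#'
#' One MnxG pendant attached to an alternating E-F hexamer ring, with
#' per-subunit Cu occupancies encoding the qualitative metal-binding
#' picture: MnxE nearly always binds exactly one Cu (strong affinity), MnxF
#' binds 0-2 with a triangular distribution (weaker affinity), and MnxG
#' carries 2-4. The expected total load is 9 Cu, placing the simulated
#' intact mass at the measured 211,216 Da.
#'
#' @param catalog a [SubunitCatalog]; the default synthetic-mass catalog
#' @param seed default seed carried by the truth object
#' @return a [GroundTruth]
#' @examples
#' mnxGroundTruth()
#' @export
mnxGroundTruth <- function(catalog = mnxCatalog(), seed = 1L) {
  comp <- Composition(c(MnxG = 1L, MnxE = 3L, MnxF = 3L), catalog)
  topo <- TopologyGraph(
    labels = c("E", "F", "E", "F", "E", "F", "G"),
    edges = rbind(.ringEdges(6L), cbind(1:6, 7L)),
    family = "ring_plus_pendant")
  GroundTruth(
    catalog = catalog, composition = comp, topology = topo,
    metalOccupancy = list(
      MnxE = OccupancyDistribution(c(0.05, 0.9, 0.05)),
      MnxF = OccupancyDistribution(c(0.25, 0.5, 0.25)),
      MnxG = OccupancyDistribution(c(0, 0, 0.25, 0.5, 0.25))),
    seed = seed)
}
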