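## Integer composition solving: which subunit + adduct count vectors match a
## neutral mass within tolerance.

#' Theoretical mass of a composition
#'
#' Dot product of subunit counts with catalog masses plus adduct counts with
#' adduct deltas.
#'
#' @param composition a [Composition], or a named integer vector of subunit
#'   counts
#' @param catalog a [SubunitCatalog]
#' @param adductCounts named integer vector (ignored when `composition` is a
#'   `Composition`)
#' @return mass in Da
#' @examples
#' compositionMass(c(MnxG = 1, MnxE = 3, MnxF = 3), mnxCatalog(round = TRUE))
#' @export
compositionMass <- function(composition, catalog, adductCounts = integer()) {
  if (is(composition, "Composition")) {
    counts <- composition@counts
    adductCounts <- composition@adductCounts
  } else counts <- composition
  s <- subunits(catalog); a <- adducts(catalog)
  unknown <- c(setdiff(names(counts), s$name),
               setdiff(names(adductCounts), a$name))
  if (length(unknown))
    qmStop(sprintf("unknown catalog name(s): %s",
                   paste(unknown, collapse = ", ")), "qmCatalogError")
  m <- sum(counts * s$mass[match(names(counts), s$name)])
  if (length(adductCounts))
    m <- m + sum(adductCounts * a$delta[match(names(adductCounts), a$name)])
  as.numeric(m)
}

#' Solve integer compositions matching a neutral mass
#'
#' Exhaustively enumerates all subunit count vectors within the catalog
#' bounds, jointly with adduct counts, and keeps those whose theoretical
#' mass lies within `tol` of the observed mass. Candidates are ranked by
#' absolute mass error, then fewer total subunit copies (parsimony), then
#' lexicographically by name — fully deterministic and invariant to catalog
#' row order.
#'
#' Adducts are enumerated jointly but reported per subunit stoichiometry:
#' each returned row is a distinct subunit count vector carrying its
#' best-fitting adduct count and the range of adduct counts that fit
#' (`adduct_min`/`adduct_max`), so "E3F3 + n Cu" collapses to one row with
#' an occupancy range. Near-equal subunit masses (e.g. MnxE/MnxF, both ~12
#' kDa) make swaps mass-degenerate at intact-complex tolerance; such
#' degeneracy shows up as several rows with similar error, reported rather
#' than silently resolved.
#'
#' @param mass observed neutral mass (Da)
#' @param tol absolute tolerance (Da, > 0). For intact complexes the
#'   envelope's mass-domain FWHM is the natural choice (about 1.6 kDa for a
#'   211 kDa complex with 55 Th peaks at z = 29); for sub-10-kDa fragments
#'   about 2 Da
#' @param catalog a [SubunitCatalog]
#' @return list of [Composition] (empty when nothing fits), each with
#'   `massError` set; the adduct occupancy range is attached as attribute
#'   `adduct_range` on each element
#' @examples
#' cat6 <- mnxCatalog(round = TRUE)
#' sol <- solveCompositions(211216, 1600, cat6)
#' sol[[1]]
#' @export
solveCompositions <- function(mass, tol, catalog) {
  stopifnot(tol > 0)
  s <- subunits(catalog); a <- adducts(catalog)
  # deterministic order regardless of catalog row order
  s <- s[order(s$name), , drop = FALSE]
  a <- a[order(a$name), , drop = FALSE]
  ranges <- c(lapply(seq_len(nrow(s)),
                     function(i) s$min_copies[i]:s$max_copies[i]),
              lapply(seq_len(nrow(a)), function(i) 0:a$max_count[i]))
  space <- prod(vapply(ranges, length, numeric(1)))
  if (space > 1e8)
    qmStop(sprintf(paste0("search space of %.3g states exceeds 1e8; ",
                          "tighten copy-number bounds"), space),
           "qmSearchSpaceError")
  grid <- as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
  masses <- grid %*% c(s$mass, a$delta)
  err <- mass - masses
  keep <- which(abs(err) <= tol)
  if (!length(keep)) return(list())
  grid <- grid[keep, , drop = FALSE]
  err <- err[keep]
  nsub <- nrow(s)
  subKey <- apply(grid[, seq_len(nsub), drop = FALSE], 1L, paste,
                  collapse = ",")
  out <- list()
  for (key in unique(subKey)) {
    rows <- which(subKey == key)
    best <- rows[which.min(abs(err[rows]))]
    counts <- structure(grid[best, seq_len(nsub)], names = s$name)
    adCounts <- if (nrow(a))
      structure(grid[best, nsub + seq_len(nrow(a))], names = a$name)
    else integer()
    comp <- Composition(counts, catalog, adductCounts = adCounts,
                        massError = err[best])
    if (nrow(a)) {
      rng <- vapply(seq_len(nrow(a)), function(j) {
        v <- grid[rows, nsub + j]
        c(min(v), max(v))
      }, numeric(2))
      attr(comp, "adduct_range") <-
        data.frame(name = a$name, min = rng[1, ], max = rng[2, ])
    }
    out[[length(out) + 1L]] <- comp
  }
  # rank on errors rounded to 1e-6 Da so float summation order cannot flip
  # ties between mass-degenerate candidates
  errs <- round(vapply(out, function(x) abs(x@massError), numeric(1)), 6)
  copies <- vapply(out, function(x) sum(x@counts), numeric(1))
  keys <- vapply(out, function(x)
    paste(names(x@counts), x@counts, collapse = ";"), character(1))
  out[order(errs, copies, keys)]
}

#' Check that two fragments complement a precursor mass
#'
#' Dissociation conserves mass: the two products of a single cleavage must
#' sum to the precursor within tolerance. The residual is reported signed
#' (precursor minus fragment sum); a positive residual of a few hundred to a
#' thousand Da is typical when fragments shed loosely bound metals or when
#' catalog masses are approximate.
#'
#' @param precursorMass precursor neutral mass (Da)
#' @param fragmentMasses numeric length-2, the two product masses (Da)
#' @param tol absolute tolerance (Da)
#' @return list with `consistent` (logical) and `residual` (Da, signed)
#' @examples
#' complementCheck(211216, c(70700, 139000), tol = 1600)
#' @export
complementCheck <- function(precursorMass, fragmentMasses, tol) {
  stopifnot(precursorMass > 0, length(fragmentMasses) == 2L,
            all(fragmentMasses > 0))
  residual <- precursorMass - sum(fragmentMasses)
  list(consistent = abs(residual) <= tol, residual = residual)
}
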