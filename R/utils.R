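## Composition-label handling and small shared helpers.
##
## A composition label is the concatenation "<label><count>" over subunits
## with non-zero copies, ordered by catalog label (e.g. "E2F1", "G1").

#' Build a composition label from counts
#'
#' @param counts named integer vector (names are subunit *names* from the
#'   catalog); zero counts are dropped
#' @param catalog a [SubunitCatalog]
#' @return a single string such as `"E2F1"`; `"0"` for the empty composition
#' @examples
#' cat6 <- mnxCatalog()
#' compositionLabel(c(MnxE = 2, MnxF = 1), cat6)
#' @export
compositionLabel <- function(counts, catalog) {
  s <- subunits(catalog)
  counts <- counts[counts > 0]
  if (!length(counts)) return("0")
  unknown <- setdiff(names(counts), s$name)
  if (length(unknown))
    qmStop(sprintf("unknown subunit(s): %s", paste(unknown, collapse = ", ")),
           "qmCatalogError")
  lab <- s$label[match(names(counts), s$name)]
  o <- order(lab)
  paste0(lab[o], as.integer(counts[o]), collapse = "")
}

#' Parse a composition label into counts
#'
#' Inverse of [compositionLabel()]. Labels are matched greedily, longest
#' first, so multi-character subunit labels are safe.
#'
#' @param label a composition string such as `"E2F1"`
#' @param catalog a [SubunitCatalog]
#' @return named integer vector over all catalog subunit names
#' @export
parseCompositionLabel <- function(label, catalog) {
  s <- subunits(catalog)
  counts <- structure(integer(nrow(s)), names = s$name)
  if (identical(label, "0") || identical(label, "")) return(counts)
  labs <- s$label[order(-nchar(s$label))]
  rest <- label
  while (nzchar(rest)) {
    hit <- NULL
    for (l in labs) {
      if (startsWith(rest, l)) { hit <- l; break }
    }
    if (is.null(hit))
      qmStop(sprintf("cannot parse composition label '%s' (at '%s')",
                     label, rest), "qmParseError")
    rest <- substring(rest, nchar(hit) + 1L)
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    k <- if (length(m) && nzchar(m)) as.integer(m) else 1L
    if (length(m) && nzchar(m)) rest <- substring(rest, nchar(m) + 1L)
    nm <- s$name[s$label == hit]
    counts[nm] <- counts[nm] + k
  }
  counts
}

## Run expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Weighted mean/sd used by neutralMass.
weightedStats <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}
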