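## Independent oracles used across the suite. These deliberately share no
## code with the package internals they check.

## --- bracelet oracles ------------------------------------------------------

## canonicalise a bead string under rotation + reflection (string-set oracle)
oracleBraceletCanonical <- function(beads) {
  n <- length(beads)
  cands <- character(0)
  for (s in list(beads, rev(beads))) {
    for (r in seq_len(n)) {
      rot <- c(s[r:n], s[seq_len(r - 1L)])[seq_len(n)]
      cands <- c(cands, paste(rot, collapse = ""))
    }
  }
  min(cands)
}

## number of distinct bracelets with the given two-colour split, by
## exhaustive enumeration of all colourings
oracleBraceletCount <- function(nA, nB, colors = c("A", "B")) {
  n <- nA + nB
  grid <- expand.grid(rep(list(colors), n), stringsAsFactors = FALSE)
  keep <- apply(grid, 1L, function(r) sum(r == colors[1]) == nA)
  keys <- apply(grid[keep, , drop = FALSE], 1L, oracleBraceletCanonical)
  length(unique(keys))
}

## Burnside closed form for two-colour bracelets of composition (nA, nB):
## average, over the dihedral group, of the number of colourings with the
## exact content fixed by each element (computed from cycle lengths by DP).
oracleBraceletBurnside <- function(nA, nB) {
  n <- nA + nB
  fixedWithContent <- function(cycleLens) {
    ways <- c(1, rep(0, nA))  # ways[k+1] = colourings using k beads of A
    for (L in cycleLens) {
      nw <- rep(0, nA + 1L)
      for (k in 0:nA) {
        if (ways[k + 1L] == 0) next
        nw[k + 1L] <- nw[k + 1L] + ways[k + 1L]           # cycle coloured B
        if (k + L <= nA) nw[k + L + 1L] <- nw[k + L + 1L] + ways[k + 1L]
      }
      ways <- nw
    }
    ways[nA + 1L]
  }
  total <- 0
  for (d in 0:(n - 1L)) {                     # rotations
    g <- .gcd(n, d)
    total <- total + fixedWithContent(rep(n / g, g))
  }
  if (n %% 2L == 0L) {                        # reflections, even n
    total <- total + (n / 2) * fixedWithContent(c(1, 1, rep(2, (n - 2) / 2)))
    total <- total + (n / 2) * fixedWithContent(rep(2, n / 2))
  } else {                                    # reflections, odd n
    total <- total + n * fixedWithContent(c(1, rep(2, (n - 1) / 2)))
  }
  total / (2 * n)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

## --- ring arc oracle -------------------------------------------------------

## compositions of all contiguous arcs of a ring, by direct enumeration
oracleRingArcs <- function(beads) {
  n <- length(beads)
  out <- character(0)
  for (k in seq_len(n - 1L)) {
    for (s in seq_len(n)) {
      arc <- beads[((s - 1L + 0:(k - 1L)) %% n) + 1L]
      t <- table(arc)
      nm <- sort(names(t))
      out <- c(out, paste0(nm, as.integer(t[nm]), collapse = ""))
    }
  }
  t <- table(beads)
  nm <- sort(names(t))
  c(out, paste0(nm, as.integer(t[nm]), collapse = ""))
}

## --- brute-force composition solver ----------------------------------------

## independent enumeration: expand all count combinations, sum masses
## explicitly, filter by tolerance, group adduct variants by subunit vector
## keeping the best, and order by (|error|, total copies, label)
oracleSolve <- function(mass, tol, subs, ads = NULL) {
  ranges <- lapply(seq_len(nrow(subs)), function(i) subs$min[i]:subs$max[i])
  if (!is.null(ads))
    ranges <- c(ranges, lapply(seq_len(nrow(ads)), function(i) 0:ads$max[i]))
  g <- expand.grid(ranges)
  tm <- numeric(nrow(g))
  for (i in seq_len(nrow(subs))) tm <- tm + g[[i]] * subs$mass[i]
  if (!is.null(ads))
    for (i in seq_len(nrow(ads))) tm <- tm + g[[nrow(subs) + i]] * ads$delta[i]
  err <- mass - tm
  g <- g[abs(err) <= tol, , drop = FALSE]
  err <- err[abs(err) <= tol]
  if (!nrow(g)) return(data.frame())
  subKey <- apply(g[, seq_len(nrow(subs)), drop = FALSE], 1L, paste,
                  collapse = ",")
  rows <- lapply(split(seq_len(nrow(g)), subKey), function(idx) {
    b <- idx[which.min(abs(err[idx]))]
    data.frame(key = subKey[b], err = err[b],
               copies = sum(g[b, seq_len(nrow(subs))]))
  })
  df <- do.call(rbind, rows)
  lex <- vapply(strsplit(df$key, ","), function(v)
    paste(subs$name, v, collapse = ";"), character(1))
  df <- df[order(round(abs(df$err), 6), df$copies, lex), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## --- minimal mzML writer ---------------------------------------------------

writeTinyMzML <- function(mzv, iv, path) {
  enc <- function(x)
    jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                  endian = "little"))
  arr <- function(acc, nm, x) sprintf(
    paste0('<binaryDataArray encodedLength="%d">',
           '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
           '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
           '<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
           '<binary>%s</binary></binaryDataArray>'),
    nchar(enc(x)), acc, nm, enc(x))
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://x"/></cvList>',
    '<run id="r1"><spectrumList count="1" defaultDataProcessingRef="dp1">',
    '<spectrum index="0" id="scan=1" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
    '<binaryDataArrayList count="2">%s%s</binaryDataArrayList>',
    '</spectrum></spectrumList></run></mzML>'),
    length(mzv),
    arr("MS:1000514", "m/z array", mzv),
    arr("MS:1000515", "intensity array", iv))
  writeLines(xml, path)
  path
}

## --- forward model ---------------------------------------------------------

## m/z of neutral mass M at charge z under the protonation charging model
forwardMz <- function(M, z, mp = 1.007276) (M + z * mp) / z
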