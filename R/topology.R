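## Candidate arrangement enumeration, SID fragment prediction as connected
## induced subgraphs, and scoring against observed subcomplexes.
##
## The physical picture: surface-induced dissociation cleaves inter-subunit
## interfaces while subunits stay folded, so the fragments a complex can
## release intact are exactly the connected induced subgraphs of its
## connectivity graph. An arrangement whose predicted fragment set disagrees
## with the observed subcomplex compositions (e.g. predicts homodimers that
## are never seen) is eliminated.

## label-count helpers (short labels, no catalog needed) -------------------

.countsToLabel <- function(labels) {
  t <- table(labels)
  nm <- sort(names(t))
  paste0(nm, as.integer(t[nm]), collapse = "")
}

.parseLabelGeneric <- function(label) {
  if (!grepl("^([A-Za-z]+[0-9]+)+$", label))
    qmStop(sprintf("malformed composition label '%s'", label), "qmParseError")
  parts <- regmatches(label, gregexpr("[A-Za-z]+[0-9]+", label))[[1]]
  nm <- sub("[0-9]+$", "", parts)
  ct <- as.integer(sub("^[A-Za-z]+", "", parts))
  structure(ct, names = nm)
}

.isSubMultiset <- function(a, b) {
  # is counts-vector a contained in b?
  all(names(a) %in% names(b)) && all(a <= b[names(a)])
}

## canonical forms ----------------------------------------------------------

.dihedralCanonical <- function(seq) {
  n <- length(seq)
  if (n == 1L) return(seq[1])
  best <- NULL
  for (s in list(seq, rev(seq))) {
    for (r in seq_len(n)) {
      cand <- paste(c(s[r:n], s[seq_len(r - 1L)])[seq_len(n)], collapse = ",")
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

.graphCanonicalString <- function(topology) {
  n <- length(topology@labels)
  if (topology@family == "ring") {
    cyc <- .cycleOrder(topology)
    if (!is.null(cyc)) return(.dihedralCanonical(topology@labels[cyc]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(topology@edges))
    g <- igraph::add_edges(g, t(topology@edges))
  colors <- as.integer(factor(topology@labels,
                              levels = sort(unique(topology@labels))))
  cp <- igraph::canonical_permutation(g, colors = colors)$labeling
  newlab <- character(n)
  newlab[cp] <- topology@labels
  gp <- igraph::permute(g, cp)
  e <- igraph::as_edgelist(gp)
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  paste0(paste(newlab, collapse = ","), "|",
         paste(apply(e, 1L, paste, collapse = "-"), collapse = ";"))
}

## returns node indices in cycle order, or NULL if not a single cycle
.cycleOrder <- function(topology) {
  n <- length(topology@labels)
  if (n <= 2L) return(seq_len(n))
  e <- topology@edges
  if (nrow(e) != n) return(NULL)
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  if (any(lengths(adj) != 2L)) return(NULL)
  ord <- integer(n); ord[1] <- 1L; prev <- 0L
  for (i in 2:n) {
    nb <- adj[[ord[i - 1L]]]
    nxt <- nb[nb != prev][1]
    prev <- ord[i - 1L]; ord[i] <- nxt
  }
  ord
}

## distinct permutations of a label multiset (counts: named integer)
.multisetPermutations <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (nm in names(remaining)[remaining > 0]) {
      remaining[nm] <- remaining[nm] - 1L
      rec(c(prefix, nm), remaining)
      remaining[nm] <- remaining[nm] + 1L
    }
  }
  rec(character(), counts)
  out
}

.ringEdges <- function(n) {
  if (n == 1L) return(matrix(integer(), ncol = 2))
  if (n == 2L) return(matrix(c(1L, 2L), ncol = 2))
  cbind(seq_len(n), c(2:n, 1L))
}

## ---------------------------------------------------------------------------

#' Enumerate inequivalent subunit arrangements
#'
#' Returns exactly one representative per equivalence class of labelled
#' arrangements under graph isomorphism respecting subunit labels. For the
#' `ring` family this is bracelet equivalence (rotation and reflection) and
#' the representative carries the lexicographically smallest
#' rotation/reflection of its label sequence as canonical string. For
#' `ring_plus_pendant` the named pendant subunit is attached to
#' `pendantDegree` contiguous ring nodes (default: all of them, i.e. one
#' pendant-ring super-interface). `tree` and `connected` families are
#' enumerated by brute force with igraph-based labelled-isomorphism
#' deduplication and are bounded to small n.
#'
#' @param composition a [Composition], or a named count vector
#' @param family one of `"ring"`, `"ring_plus_pendant"`, `"tree"`,
#'   `"connected"`
#' @param catalog optional [SubunitCatalog]; when given, nodes carry the
#'   catalog's short labels (so canonical strings read `"E,F,E,F,E,F"`
#'   rather than full subunit names)
#' @param pendant subunit (label) to place as the pendant node
#'   (`ring_plus_pendant` only; defaults to the unique subunit with one
#'   copy)
#' @param pendantDegree number of contiguous ring nodes the pendant touches
#' @return list of [TopologyGraph], sorted by canonical string
#' @examples
#' enumerateArrangements(c(E = 3, F = 3), "ring")  # EEEFFF, EEFEFF, EFEFEF
#' @export
enumerateArrangements <- function(composition,
                                  family = c("ring", "ring_plus_pendant",
                                             "tree", "connected"),
                                  catalog = NULL, pendant = NULL,
                                  pendantDegree = NULL) {
  family <- match.arg(family)
  counts <- if (is(composition, "Composition")) composition@counts
            else composition
  counts <- counts[counts > 0]
  if (!is.null(catalog)) {
    s <- subunits(catalog)
    names(counts) <- s$label[match(names(counts), s$name)]
  }
  n <- sum(counts)
  if (n > 10L)
    qmStop(sprintf("arrangement enumeration is bounded to 10 subunit copies (got %d)", n),
           "qmSearchSpaceError")
  if (n == 1L)
    return(list(TopologyGraph(names(counts), matrix(integer(), ncol = 2),
                              family = family)))
  out <- switch(family,
    ring = .enumerateRings(counts),
    ring_plus_pendant = .enumerateRingPendant(counts, pendant, pendantDegree),
    tree = .enumerateTrees(counts),
    connected = .enumerateConnected(counts))
  out[order(vapply(out, canonicalString, character(1)))]
}

.enumerateRings <- function(counts) {
  perms <- .multisetPermutations(counts)
  seen <- character()
  out <- list()
  n <- sum(counts)
  for (p in perms) {
    key <- .dihedralCanonical(p)
    if (key %in% seen) next
    seen <- c(seen, key)
    lab <- strsplit(key, ",", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <-
      TopologyGraph(lab, .ringEdges(n), family = "ring", canonical = key)
  }
  out
}

.enumerateRingPendant <- function(counts, pendant, pendantDegree) {
  if (is.null(pendant)) {
    singles <- names(counts)[counts == 1L]
    if (length(singles) != 1L)
      qmStop("pendant subunit must be named (no unique single-copy subunit)",
             "qmConfigError")
    pendant <- singles
  }
  if (!pendant %in% names(counts) || counts[pendant] < 1L)
    qmStop(sprintf("pendant subunit '%s' not in composition", pendant),
           "qmConfigError")
  ringCounts <- counts
  ringCounts[pendant] <- ringCounts[pendant] - 1L
  ringCounts <- ringCounts[ringCounts > 0]
  m <- sum(ringCounts)
  k <- if (is.null(pendantDegree)) m else as.integer(pendantDegree)
  stopifnot(k >= 1L, k <= m)
  perms <- .multisetPermutations(ringCounts)
  seen <- character()
  out <- list()
  for (p in perms) {
    for (start in seq_len(m)) {
      mask <- integer(m)
      mask[((start - 1L + 0:(k - 1L)) %% m) + 1L] <- 1L
      key <- .dihedralCanonical(paste0(p, "@", mask))
      if (key %in% seen) next
      seen <- c(seen, key)
      parts <- strsplit(strsplit(key, ",", fixed = TRUE)[[1]], "@", fixed = TRUE)
      lab <- vapply(parts, `[`, character(1), 1L)
      att <- which(vapply(parts, `[`, character(1), 2L) == "1")
      edges <- rbind(.ringEdges(m), cbind(att, m + 1L))
      out[[length(out) + 1L]] <-
        TopologyGraph(c(lab, pendant), edges, family = "ring_plus_pendant",
                      canonical = paste0(key, "+", pendant))
      if (k == m) break  # attachment position is immaterial
    }
  }
  out
}

.enumerateTrees <- function(counts) {
  n <- sum(counts)
  if (n > 7L)
    qmStop("tree enumeration is bounded to 7 subunit copies", "qmSearchSpaceError")
  labels <- rep(names(counts), counts)
  if (n == 2L)
    return(list(TopologyGraph(labels, matrix(c(1L, 2L), ncol = 2), "tree")))
  pruefer <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  .dedupGraphs(lapply(seq_len(nrow(pruefer)), function(i)
    TopologyGraph(labels, .prueferToEdges(pruefer[i, ], n), family = "tree")))
}

.prueferToEdges <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(integer(), ncol = 2)
  for (v in seq) {
    leaf <- which(degree == 1L)[1]
    edges <- rbind(edges, c(leaf, v))
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  rbind(edges, last)
}

.enumerateConnected <- function(counts) {
  n <- sum(counts)
  if (n > 6L)
    qmStop("connected-family enumeration is bounded to 6 subunit copies",
           "qmSearchSpaceError")
  labels <- rep(names(counts), counts)
  allEdges <- t(utils::combn(n, 2L))
  ne <- nrow(allEdges)
  out <- list()
  for (mask in seq_len(2^ne) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
    if (length(sel) < n - 1L) next
    edges <- allEdges[sel, , drop = FALSE]
    if (!.edgesConnected(n, edges)) next
    out[[length(out) + 1L]] <-
      TopologyGraph(labels, edges, family = "connected")
  }
  .dedupGraphs(out)
}

.edgesConnected <- function(n, edges) {
  parent <- seq_len(n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    while (parent[a] != a) a <- parent[a]
    while (parent[b] != b) b <- parent[b]
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }, integer(1))
  length(unique(roots)) == 1L
}

.dedupGraphs <- function(graphs) {
  keys <- vapply(graphs, canonicalString, character(1))
  graphs[!duplicated(keys)]
}

#' Predict the subcomplexes a topology can release
#'
#' Enumerates every connected induced subgraph of the topology and tallies
#' the multiset of their subunit compositions. For a ring these are exactly
#' the contiguous arcs (n arcs of every size below n, plus the full ring);
#' with a pendant node, fragments containing the pendant are the pendant
#' together with any connected arc containing an attachment point.
#'
#' @param topology a [TopologyGraph] (at most 10 nodes)
#' @return a [FragmentPrediction]
#' @examples
#' ring <- enumerateArrangements(c(E = 3, F = 3), "ring")[[3]]  # EFEFEF
#' predictedMultiset(predictSubcomplexes(ring))
#' @export
predictSubcomplexes <- function(topology) {
  n <- length(topology@labels)
  if (n > 16L)
    qmStop("subcomplex prediction is bounded to 16 nodes", "qmSearchSpaceError")
  adj <- vector("list", n)
  e <- topology@edges
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  multiset <- integer()
  bySize <- rep(list(integer()), n)
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!.subsetConnected(members, adj)) next
    lab <- .countsToLabel(topology@labels[members])
    multiset[lab] <- (if (lab %in% names(multiset)) multiset[[lab]] else 0L) + 1L
    k <- length(members)
    bySize[[k]][lab] <-
      (if (lab %in% names(bySize[[k]])) bySize[[k]][[lab]] else 0L) + 1L
  }
  FragmentPrediction(multiset, bySize)
}

.subsetConnected <- function(members, adj) {
  k <- length(members)
  if (k == 1L) return(TRUE)
  inset <- logical(length(adj))
  inset[members] <- TRUE
  seen <- logical(length(adj))
  seen[members[1]] <- TRUE
  queue <- members[1]
  count <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (inset[w] && !seen[w]) {
        seen[w] <- TRUE; count <- count + 1L; queue <- c(queue, w)
      }
    }
  }
  count == k
}

#' Default scoring weights for topology elimination
#'
#' Rows: whether a composition is predicted by the topology; columns: its
#' observed abundance class. The defaults encode the elimination logic used
#' for SID data: a predicted fragment that is never observed is strong
#' evidence against an arrangement (absence of predicted homodimers is
#' disqualifying), an observed fragment no arc can produce is stronger
#' evidence still, and trace species are excusable as secondary-dissociation
#' products.
#'
#' @return 2 x 4 numeric matrix with rownames `predicted`, `not_predicted`
#'   and colnames `major`, `minor`, `trace`, `absent`
#' @export
defaultScoreWeights <- function() {
  matrix(c(2, 1, 0, -2,
           -3, -1, 0, 0),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("predicted", "not_predicted"), .ABUNDANCE_CLASSES))
}

#' Score a fragment prediction against observed subcomplexes
#'
#' The total is the sum, over the union of predicted and observed
#' composition labels, of `weights[predicted?, class]`, where a
#' predicted-but-unobserved label counts as class `"absent"`. Multiplicities
#' are deliberately not compared to intensities: observed abundance ratios
#' of symmetric arcs need not match their arc multiplicities (interface
#' energetics and secondary dissociation distort them), so only the
#' presence/absence/abundance-class pattern carries evidence.
#'
#' @param prediction a [FragmentPrediction]
#' @param observed an [ObservationSet]
#' @param weights scoring matrix as in [defaultScoreWeights()]
#' @param secondaryDissociation when `TRUE`, labels of class `"trace"` whose
#'   composition is contained in some predicted fragment contribute zero (they
#'   plausibly arise from secondary dissociation of a larger released
#'   multimer rather than from the intact complex)
#' @return a [TopologyScore]
#' @export
scoreTopology <- function(prediction, observed,
                          weights = defaultScoreWeights(),
                          secondaryDissociation = FALSE) {
  obs <- observationClasses(observed)
  predLabels <- names(predictedMultiset(prediction))
  allLabels <- union(predLabels, names(obs))
  contrib <- numeric(length(allLabels))
  names(contrib) <- allLabels
  predCounts <- lapply(predLabels, .parseLabelGeneric)
  for (lab in allLabels) {
    .parseLabelGeneric(lab)  # validates syntax
    predicted <- lab %in% predLabels
    cls <- if (lab %in% names(obs)) obs[[lab]] else "absent"
    w <- weights[if (predicted) "predicted" else "not_predicted", cls]
    if (secondaryDissociation && cls == "trace") {
      cnt <- .parseLabelGeneric(lab)
      if (any(vapply(predCounts, function(p) .isSubMultiset(cnt, p),
                     logical(1))))
        w <- 0
    }
    contrib[lab] <- w
  }
  TopologyScore(contrib)
}

#' Enumerate, predict, score and rank candidate topologies
#'
#' The full elimination procedure: enumerate all inequivalent arrangements
#' of a composition within a family, predict each one's releasable
#' subcomplexes, score the predictions against the observed set, and sort
#' by descending score (ties broken by canonical string, ascending).
#'
#' @inheritParams enumerateArrangements
#' @inheritParams scoreTopology
#' @param observed an [ObservationSet]
#' @return list of `list(topology = TopologyGraph, score = TopologyScore)`
#'   in rank order; each score carries its rank
#' @examples
#' obs <- mnxObservations()
#' rk <- rankTopologies(c(E = 3, F = 3), "ring", obs)
#' canonicalString(rk[[1]]$topology)  # the alternating ring
#' @export
rankTopologies <- function(composition, family, observed,
                           weights = defaultScoreWeights(),
                           secondaryDissociation = FALSE, catalog = NULL,
                           pendant = NULL, pendantDegree = NULL) {
  tops <- enumerateArrangements(composition, family, catalog = catalog,
                                pendant = pendant,
                                pendantDegree = pendantDegree)
  scores <- lapply(tops, function(tp)
    scoreTopology(predictSubcomplexes(tp), observed, weights,
                  secondaryDissociation))
  totals <- vapply(scores, scoreTotal, numeric(1))
  keys <- vapply(tops, canonicalString, character(1))
  o <- order(-totals, keys)
  out <- vector("list", length(o))
  for (r in seq_along(o)) {
    sc <- scores[[o[r]]]
    sc@rank <- as.integer(r)
    out[[r]] <- list(topology = tops[[o[r]]], score = sc)
  }
  out
}

#' Classify fragment abundances into observation classes
#'
#' Converts raw fragment counts or intensities into the abundance classes
#' used for scoring, relative to the most abundant fragment: `major` at or
#' above 20%, `minor` from 2%, `trace` from 0.5%, `absent` below 0.5%.
#' Thresholds are conventions, fully configurable.
#'
#' @param abundance named numeric vector (composition label to count or
#'   intensity)
#' @param thresholds named numeric, lower bounds (as fractions of the
#'   maximum) for `major`, `minor` and `trace`
#' @return an [ObservationSet]
#' @export
classifyAbundance <- function(abundance,
                              thresholds = c(major = 0.2, minor = 0.02,
                                             trace = 0.005)) {
  stopifnot(all(c("major", "minor", "trace") %in% names(thresholds)))
  rel <- abundance / max(abundance)
  cls <- ifelse(rel >= thresholds["major"], "major",
         ifelse(rel >= thresholds["minor"], "minor",
         ifelse(rel >= thresholds["trace"], "trace", "absent")))
  names(cls) <- names(abundance)
  ObservationSet(cls)
}
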