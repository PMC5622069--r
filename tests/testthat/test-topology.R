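test_that("ring arrangements enumerate one representative per bracelet", {
  arr <- enumerateArrangements(c(E = 3, F = 3), "ring")
  expect_equal(vapply(arr, canonicalString, character(1)),
               c("E,E,E,F,F,F", "E,E,F,E,F,F", "E,F,E,F,E,F"))
  arr <- enumerateArrangements(c(E = 2, F = 2), "ring")
  expect_equal(vapply(arr, canonicalString, character(1)),
               c("E,E,F,F", "E,F,E,F"))
  # one subunit: the single-node graph
  solo <- enumerateArrangements(c(G = 1), "ring")
  expect_length(solo, 1L)
  expect_equal(nodeLabels(solo[[1]]), "G")
})

test_that("bracelet counts match string-set and Burnside oracles", {
  for (n in 2:8) {
    for (nA in 0:n) {
      counts <- c(A = nA, B = n - nA)
      got <- length(enumerateArrangements(counts[counts > 0], "ring"))
      expect_equal(got, oracleBraceletCount(nA, n - nA),
                   info = sprintf("n=%d nA=%d (string-set)", n, nA))
      expect_equal(got, oracleBraceletBurnside(nA, n - nA),
                   info = sprintf("n=%d nA=%d (Burnside)", n, nA))
    }
  }
})

test_that("ring subcomplex predictions are the contiguous arcs", {
  arr <- enumerateArrangements(c(E = 3, F = 3), "ring")
  byKey <- function(a) vapply(a, canonicalString, character(1))
  alt <- arr[[which(byKey(arr) == "E,F,E,F,E,F")]]
  pred <- predictedMultiset(predictSubcomplexes(alt))
  expect_equal(pred[order(names(pred))],
               c(E1 = 3L, E1F1 = 6L, E1F2 = 3L, E2F1 = 3L, E2F2 = 6L,
                 E2F3 = 3L, E3F2 = 3L, E3F3 = 1L, F1 = 3L))
  blk <- arr[[which(byKey(arr) == "E,E,E,F,F,F")]]
  dim2 <- predictedBySize(predictSubcomplexes(blk))[[2]]
  expect_equal(dim2[order(names(dim2))], c(E1F1 = 2L, E2 = 2L, F2 = 2L))
  # a single node predicts only itself
  solo <- TopologyGraph("G", matrix(integer(), ncol = 2), "connected")
  expect_equal(predictedMultiset(predictSubcomplexes(solo)), c(G1 = 1L))
})

test_that("arc enumeration matches the brute-force ring oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    beads <- sample(c("E", "F", "G"), n, replace = TRUE)
    tg <- TopologyGraph(beads, cbind(seq_len(n), c(2:n, 1)), "ring")
    got <- predictedMultiset(predictSubcomplexes(tg))
    want <- table(oracleRingArcs(beads))
    expect_equal(got[order(names(got))],
                 structure(as.integer(want), names = names(want)))
  }
})

test_that("an n-ring has n connected induced subgraphs of every size below n", {
  for (n in 3:8) {
    beads <- rep(c("E", "F"), length.out = n)
    tg <- TopologyGraph(beads, cbind(seq_len(n), c(2:n, 1)), "ring")
    bySize <- predictedBySize(predictSubcomplexes(tg))
    for (k in seq_len(n - 1L)) expect_equal(sum(bySize[[k]]), n)
    expect_equal(sum(bySize[[n]]), 1L)
  }
})

test_that("predictions are invariant under ring rotation and reflection", {
  beads <- c("E", "F", "E", "F", "E", "F")
  base <- predictedMultiset(predictSubcomplexes(
    TopologyGraph(beads, cbind(1:6, c(2:6, 1)), "ring")))
  for (rot in list(beads[c(3:6, 1:2)], rev(beads))) {
    got <- predictedMultiset(predictSubcomplexes(
      TopologyGraph(rot, cbind(1:6, c(2:6, 1)), "ring")))
    expect_equal(got[order(names(got))], base[order(names(base))])
  }
})

test_that("ring arc predictions are closed under complementation", {
  arr <- enumerateArrangements(c(E = 3, F = 2, G = 1), "ring")
  full <- c(E = 3L, F = 2L, G = 1L)
  for (tg in arr) {
    pred <- predictedMultiset(predictSubcomplexes(tg))
    for (lab in names(pred)) {
      cnt <- quatMS:::.parseLabelGeneric(lab)
      comp <- full
      comp[names(cnt)] <- comp[names(cnt)] - cnt
      comp <- comp[comp > 0]
      if (!length(comp)) next  # complement of the full ring is empty
      compLab <- paste0(sort(names(comp)),
                        as.integer(comp[sort(names(comp))]), collapse = "")
      expect_true(compLab %in% names(pred),
                  info = sprintf("%s: %s missing complement %s",
                                 canonicalString(tg), lab, compLab))
    }
  }
})

test_that("scoring is additive and maximal under perfect agreement", {
  arr <- enumerateArrangements(c(E = 3, F = 3), "ring")
  alt <- arr[[3]]
  pred <- predictSubcomplexes(alt)
  perfect <- ObservationSet(
    structure(rep("major", length(predictedMultiset(pred))),
              names = names(predictedMultiset(pred))))
  w <- defaultScoreWeights()
  smax <- scoreTopology(pred, perfect, w)
  expect_equal(scoreTotal(smax),
               length(predictedMultiset(pred)) * w["predicted", "major"])
  # removing one composition changes the total by exactly its contribution
  obs <- mnxObservations()
  full <- scoreTopology(pred, obs, w)
  cls <- observationClasses(obs)
  dropped <- ObservationSet(cls[names(cls) != "E2F2"])
  less <- scoreTopology(pred, dropped, w)
  expect_equal(scoreTotal(full) - scoreTotal(less),
               scoreBreakdown(full)[["E2F2"]] -
                 if ("E2F2" %in% names(scoreBreakdown(less)))
                   scoreBreakdown(less)[["E2F2"]] else 0)
  expect_error(scoreTopology(pred, ObservationSet(c("2bad?" = "major")), w),
               class = "qmParseError")
})

test_that("the observed SID set singles out the alternating hexamer", {
  rk <- rankTopologies(c(E = 3, F = 3), "ring", mnxObservations())
  expect_equal(canonicalString(rk[[1]]$topology), "E,F,E,F,E,F")
  totals <- vapply(rk, function(r) scoreTotal(r$score), numeric(1))
  expect_gt(totals[1], totals[2])  # strictly highest
  # the blocked arrangement is punished for its predicted-but-absent
  # homodimers and homotrimers
  blk <- rk[[which(vapply(rk, function(r) canonicalString(r$topology),
                          character(1)) == "E,E,E,F,F,F")]]
  bd <- scoreBreakdown(blk$score)
  expect_lt(bd[["E2"]], 0)
  expect_lt(bd[["F3"]], 0)
  expect_lt(scoreTotal(blk$score), scoreTotal(rk[[1]]$score))
})

test_that("self-consistent observations rank their own topology first", {
  arr <- enumerateArrangements(c(E = 3, F = 3), "ring")
  blk <- arr[[1]]  # E,E,E,F,F,F
  pred <- predictedMultiset(predictSubcomplexes(blk))
  obs <- ObservationSet(structure(rep("major", length(pred)),
                                  names = names(pred)))
  rk <- rankTopologies(c(E = 3, F = 3), "ring", obs)
  expect_equal(canonicalString(rk[[1]]$topology), "E,E,E,F,F,F")
})

test_that("pendant arrangements predict the primary cleavage pair", {
  truth <- mnxGroundTruth()
  pred <- predictedMultiset(predictSubcomplexes(truth@topology))
  expect_true(all(c("G1", "E3F3") %in% names(pred)))
  sim <- simulateDissociation(truth, "SID", 50, "low", seed = 3)
  cls <- observationClasses(sim$observations)
  expect_setequal(names(cls), c("G1", "E3F3"))
  expect_true(all(cls == "major"))
})

test_that("secondary-dissociation mode excuses trace sub-pieces", {
  pred <- FragmentPrediction(c(E2F2 = 1L), list())
  obs <- ObservationSet(c(F2 = "trace"))
  w <- defaultScoreWeights()
  w["not_predicted", "trace"] <- -5
  hard <- scoreTopology(pred, obs, w)
  soft <- scoreTopology(pred, obs, w, secondaryDissociation = TRUE)
  expect_equal(scoreBreakdown(hard)[["F2"]], -5)
  expect_equal(scoreBreakdown(soft)[["F2"]], 0)
})

test_that("abundance classification applies the documented thresholds", {
  obs <- classifyAbundance(c(A1 = 1000, B1 = 300, C1 = 30, D1 = 7, E1 = 2))
  expect_equal(unname(observationClasses(obs)[c("A1", "B1", "C1", "D1", "E1")]),
               c("major", "major", "minor", "trace", "absent"))
})

test_that("tree and connected families dedup labelled isomorphs", {
  # 3 labelled nodes E,E,F: trees are paths; distinct centres E or F give 2
  trees <- enumerateArrangements(c(E = 2, F = 1), "tree")
  expect_length(trees, 2L)
  # connected graphs on E,E,F: 2 paths + 1 triangle
  conn <- enumerateArrangements(c(E = 2, F = 1), "connected")
  expect_length(conn, 3L)
  expect_error(enumerateArrangements(c(E = 6, F = 6), "ring"),
               class = "qmSearchSpaceError")
})
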