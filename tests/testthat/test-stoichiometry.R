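test_that("composition masses are catalog dot products", {
  cat6 <- mnxCatalog(round = TRUE)
  expect_equal(compositionMass(c(MnxG = 1, MnxE = 3, MnxF = 3), cat6), 211000)
  expect_equal(compositionMass(integer(), cat6), 0)
  expect_equal(compositionMass(c(MnxG = 1, MnxE = 3, MnxF = 3), cat6,
                               adductCounts = c(Cu = 10)),
               211000 + 635.46)
  expect_error(compositionMass(c(MnxQ = 1), cat6), class = "qmCatalogError")
  # a returned Composition's theoretical mass is recomputable exactly
  cp <- Composition(c(MnxG = 1, MnxE = 3, MnxF = 3), cat6,
                    adductCounts = c(Cu = 10))
  expect_identical(theoreticalMass(cp), compositionMass(cp, cat6))
})

test_that("intact-mass solving constrains the subunit stoichiometry", {
  cat6 <- mnxCatalog(round = TRUE)
  sols <- solveCompositions(211216, 1600, cat6)
  expect_gt(length(sols), 0L)
  for (cp in sols) {
    cnt <- subunitCounts(cp)
    expect_equal(unname(cnt["MnxG"]), 1L)
    expect_equal(unname(cnt["MnxE"] + cnt["MnxF"]), 6L)
  }
})

test_that("exact masses at tight tolerance give single-subunit answers", {
  cat6 <- SubunitCatalog(data.frame(
    name = c("A", "B"), mass = c(12000, 139000),
    min_copies = 0, max_copies = c(8, 2)))
  sols <- solveCompositions(12000, 1, cat6)
  expect_length(sols, 1L)
  expect_equal(unname(subunitCounts(sols[[1]])), c(1L, 0L))
  expect_equal(massError(sols[[1]]), 0)
})

test_that("solver agrees with an independent brute-force enumerator", {
  set.seed(23)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    subs <- data.frame(name = paste0("S", seq_len(k)),
                       mass = round(runif(k, 5000, 40000), 1),
                       min = 0L, max = sample(2:5, k, replace = TRUE))
    target <- sum(subs$mass * sapply(subs$max, function(m) sample(0:m, 1)))
    tol <- runif(1, 10, 5000)
    cat6 <- SubunitCatalog(data.frame(name = subs$name, mass = subs$mass,
                                      min_copies = subs$min,
                                      max_copies = subs$max))
    got <- solveCompositions(target, tol, cat6)
    want <- oracleSolve(target, tol, subs)
    expect_length(got, nrow(want))
    if (nrow(want)) {
      gotKeys <- vapply(got, function(cp)
        paste(subunitCounts(cp)[subs$name], collapse = ","), character(1))
      expect_identical(gotKeys, want$key)
      expect_equal(vapply(got, massError, numeric(1)), want$err)
    }
  }
})

test_that("solver ranking is deterministic and invariant to catalog order", {
  make <- function(perm) SubunitCatalog(
    data.frame(name = c("MnxG", "MnxE", "MnxF")[perm],
               mass = c(139000, 12000, 12000)[perm],
               min_copies = 0, max_copies = c(1, 8, 8)[perm]))
  a <- solveCompositions(211216, 1600, make(1:3))
  b <- solveCompositions(211216, 1600, make(c(3, 1, 2)))
  keyOf <- function(cp) paste(names(subunitCounts(cp)),
                              subunitCounts(cp), collapse = ";")
  expect_identical(vapply(a, keyOf, character(1)),
                   vapply(b, keyOf, character(1)))
})

test_that("widening the tolerance never drops a composition", {
  cat6 <- mnxCatalog(round = TRUE)
  keyOf <- function(cp) paste(subunitCounts(cp), collapse = ",")
  small <- vapply(solveCompositions(211216, 400, cat6), keyOf, character(1))
  big <- vapply(solveCompositions(211216, 2500, cat6), keyOf, character(1))
  expect_true(all(small %in% big))
})

test_that("adduct variants collapse to one stoichiometry with a range", {
  cat6 <- mnxCatalog(round = TRUE)
  sols <- solveCompositions(211216, 1600, cat6)
  best <- sols[[1]]
  rng <- attr(best, "adduct_range")
  expect_s3_class(rng, "data.frame")
  expect_true(rng$min[rng$name == "Cu"] < rng$max[rng$name == "Cu"])
})

test_that("complementary SID products reconstruct the precursor", {
  # hexamer (70.7 kDa) + catalytic subunit (139 kDa) vs 211,216 Da intact
  chk <- complementCheck(211216, c(70700, 139000), tol = 1600)
  expect_true(chk$consistent)
  expect_equal(chk$residual, 1516)
  # exact halves
  expect_equal(complementCheck(2e5, c(1e5, 1e5), 1)$residual, 0)
  # wrong fragment mass fails
  expect_false(complementCheck(211216, c(70700, 120000), 1600)$consistent)
})

test_that("oversized search spaces are refused with guidance", {
  big <- SubunitCatalog(data.frame(
    name = paste0("S", 1:6), mass = rep(10000, 6),
    min_copies = 0, max_copies = rep(30, 6)))
  expect_error(solveCompositions(1e5, 10, big), "1e",
               class = "qmSearchSpaceError")
})
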