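cliqueDf <- function(mz, area, ids = NULL) {
  data.frame(id = if (is.null(ids)) sprintf("f%d", seq_along(mz)) else ids,
             mz = mz, area = area, stringsAsFactors = FALSE)
}

test_that("isotope collapse keeps the most abundant peak of each envelope", {
  fx <- cliqueDf(c(341.09, 340.084, 339.077), c(1, 10, 100))
  out <- collapseIsotopes(fx, er = 0)
  expect_equal(out$mz, 339.077)   # gaps 1.006 / 1.007 chain into one envelope

  far <- cliqueDf(c(350, 345), c(1, 5))
  expect_equal(nrow(collapseIsotopes(far, er = 0)), 2L)

  # the clique's most abundant feature always survives (property)
  set.seed(3)
  for (i in 1:20) {
    f <- cliqueDf(sort(100 + cumsum(runif(6, 0.3, 2))), runif(6))
    out <- collapseIsotopes(f, er = 0.016)
    expect_true(f$id[which.max(f$area)] %in% out$id)
  }
})

test_that("the isotope window boundary sits at 1.008 Da when er = 0", {
  for (case in list(c(1.0075, 1L), c(1.0085, 2L), c(1.008, 1L))) {
    fx <- cliqueDf(c(300, 300 + case[1]), c(10, 1))
    expect_equal(nrow(collapseIsotopes(fx, er = 0)), case[2],
                 label = sprintf("gap=%g", case[1]))
  }
})

test_that("monomer/dimer matching accumulates w_r + w_a onto the monomer", {
  M <- 340.079
  fx <- cliqueDf(c(M - PROTON, 2 * M - PROTON), c(5e4, 5e4))
  mm <- matchMassDifferences(fx, adductRules("negative"), er = 0.016)
  expect_equal(nrow(mm$map), 1L)
  expect_equal(mm$map$impliedMz, M - PROTON)
  expect_equal(mm$map$totalWeight, 10 + 2)   # w_r printed max + equal areas

  none <- cliqueDf(c(100, 200.5), c(1, 1))
  expect_equal(nrow(matchMassDifferences(none, adductRules("negative"),
                                         er = 0.016)$map), 0L)
})

test_that("weight accumulation equals the exhaustive pair x rule oracle", {
  rules <- adductRules("negative")
  set.seed(11)
  for (i in 1:8) {
    M <- runif(1, 150, 500)
    mono <- M - PROTON
    mzs <- c(mono, 2 * M - PROTON, mono + 46.005479, mono - 18.010565,
             mono + 35.976678, mono + runif(1, 3, 9))
    pick <- sample(6, sample(3:6, 1))
    fx <- cliqueDf(mzs[pick], runif(length(pick), 1e3, 1e5))
    got <- matchMassDifferences(fx, rules, er = 0.016)$map
    want <- oracleWeightMap(fx, rules, er = 0.016)
    got <- got[order(got$impliedMz), ]
    want <- want[order(want$impliedMz), ]
    expect_equal(got$impliedMz, want$impliedMz, tolerance = 1e-9)
    expect_equal(got$totalWeight, want$totalWeight, tolerance = 1e-9)
  }
})

test_that("adding a supporting pair never decreases a candidate's weight", {
  M <- 300
  mono <- M - PROTON
  base <- cliqueDf(c(mono, 2 * M - PROTON), c(1e4, 8e3))
  w1 <- matchMassDifferences(base, adductRules("negative"), 0.016)$map
  more <- rbind(base, cliqueDf(mono + 46.005479, 5e3, ids = "extra"))
  w2 <- matchMassDifferences(more, adductRules("negative"), 0.016)$map
  expect_gt(w2$totalWeight[w2$impliedMz == mono],
            w1$totalWeight[w1$impliedMz == mono] - 1e-12)
})

test_that("candidate #1 requires support, detection and m/z above the base", {
  feats <- cliqueDf(c(200, 250), c(1e4, 5e3))
  emptyMap <- data.frame(impliedMz = numeric(), totalWeight = numeric(),
                         nMatches = integer())
  expect_null(candidate1(emptyMap, feats))
  # implied ion below the base peak's m/z is rejected
  below <- data.frame(impliedMz = 150, totalWeight = 3, nMatches = 1)
  expect_null(candidate1(below, feats, er = 0.016))
  # implied ion not detected within er is rejected
  ghost <- data.frame(impliedMz = 260, totalWeight = 3, nMatches = 1)
  expect_null(candidate1(ghost, feats, er = 0.016))
  # detected, supported, above the base -> returned
  ok <- data.frame(impliedMz = 250.004, totalWeight = 3, nMatches = 1)
  expect_equal(candidate1(ok, feats, er = 0.016)$id, "f2")
})

test_that("candidate #2 finds the neutral-loss parent or the top base peak", {
  losses <- neutralLossRules("plant")
  # base peak is the highest m/z -> candidate #2 is the base peak
  top <- cliqueDf(c(385.1, 380.0), c(1e5, 10))
  expect_equal(candidate2(top, losses)$mz, 385.1)
  # hexose loss: parent 162.0528 above the base peak
  glyco <- cliqueDf(c(385.1, 385.1 + 162.0528234), c(1e5, 2e4))
  expect_equal(candidate2(glyco, losses, er = 0.016)$mz,
               385.1 + 162.0528234)
  # higher features, no matching loss -> none
  nohit <- cliqueDf(c(385.1, 485.1), c(1e5, 2e4))
  expect_null(candidate2(nohit, losses, er = 0.016))
})

test_that("candidate #3 needs m/z above the base and area above 50 percent", {
  expect_equal(candidate3(cliqueDf(c(400, 500), c(100, 49)))$mz, 400)
  expect_equal(candidate3(cliqueDf(c(400, 500), c(100, 51)))$mz, 500)
  # with two eligible features the higher m/z wins
  expect_equal(candidate3(cliqueDf(c(400, 500, 550), c(100, 60, 52)))$mz, 550)
  # nothing above the base peak -> the base peak
  expect_equal(candidate3(cliqueDf(c(400, 300), c(100, 90)))$mz, 400)
})

test_that("the identification cascade decides along its four paths", {
  rules <- adductRules("negative")
  losses <- neutralLossRules("plant")

  single <- cliqueDf(327.05, 1e5)
  r1 <- identifyPseudomolecular(single, rules, losses)
  expect_equal(r1$source, "single_feature")
  expect_equal(r1$pseudoMz, 327.05)

  # monomer + dimer + 13C isotopologues: direct acceptance at nominal 339
  M <- 340.079
  mal <- cliqueDf(c(M - PROTON, M - PROTON + C13,
                    2 * M - PROTON, 2 * M - PROTON + C13),
                  c(1e5, 1e4, 3e4, 6e3))
  r2 <- identifyPseudomolecular(mal, rules, losses)
  expect_equal(r2$source, "weight_accept")
  expect_equal(floor(r2$pseudoMz), 339)
  expect_false(r2$virtual)

  # no rule support, base is the highest m/z: #2 = #3 = base, 2-of-3 vote
  lone <- cliqueDf(c(410, 300.123), c(1e5, 7e4))
  r3 <- identifyPseudomolecular(lone, rules, losses)
  expect_equal(r3$source, "candidate_vote")
  expect_equal(r3$pseudoMz, 410)

  # glycoside: base peak is a hexose fragment, the parent wins the fallback
  glyco <- cliqueDf(c(385.1, 385.1 + 162.0528234), c(1e5, 2e4))
  r4 <- identifyPseudomolecular(glyco, rules, losses)
  expect_equal(r4$source, "highest_mz_fallback")
  expect_equal(r4$pseudoMz, 385.1 + 162.0528234)

  expect_error(identifyPseudomolecular(cliqueDf(numeric(), numeric()),
                                       rules, losses), "empty")
})

test_that("direct acceptance can name a virtual, undetected ion", {
  # two sodium/potassium-type adducts of the same molecule whose implied
  # pseudomolecular ion itself was never detected
  rules <- data.frame(label = c("strong pair A", "strong pair B"),
                      mode = "positive", kind = "fixed",
                      deltaMz = c(30, 50), wr = c(3, 3),
                      impliedOffset = c(-20, -20), stringsAsFactors = FALSE)
  fx <- cliqueDf(c(520, 550, 570), c(1e5, 8e4, 6e4))
  r <- identifyPseudomolecular(fx, rules, neutralLossRules("generic"))
  expect_equal(r$source, "weight_accept")
  expect_true(r$virtual)
  expect_equal(r$pseudoMz, 500)
  expect_true(is.na(r$pseudoId))
})

test_that("rule tables round-trip through their TSV config format", {
  dir <- withr::local_tempdir()
  ap <- file.path(dir, "adducts.tsv")
  writeAdductRules(adductRules("positive"), ap)
  expect_equal(readAdductRules(ap), adductRules("positive"))
  np <- file.path(dir, "losses.tsv")
  writeNeutralLosses(neutralLossRules("animal"), np)
  got <- readNeutralLosses(np)
  want <- neutralLossRules("animal")
  rownames(want) <- NULL
  expect_equal(got, want)
  expect_error(readAdductRules(np), "columns")
})
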