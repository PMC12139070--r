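mutateAt <- function(window, pos, to) {
  substr(window, pos, pos) <- to
  window
}

## a non-pairing, non-wobble base opposite a given sRNA base
clashBase <- function(srnaBase) {
  switch(srnaBase, A = "C", C = "A", G = "A", T = "C", U = "C")
}

test_that("perfect complement scores zero and seed/wobble penalties apply", {
  s <- "TGGAGCTCCCTTCATTCCAAT"  # 21 nt
  expect_equal(expectation(scoreDuplex(s, revComp(s))), 0)

  ## one mismatch opposite sRNA position 5: penalty 1 doubled in the seed
  w <- revComp(s)
  p5 <- nchar(w) - 4  # sRNA position i pairs window position (len - i + 1)
  w5 <- mutateAt(w, p5, clashBase(substr(s, 5, 5)))
  expect_equal(expectation(scoreDuplex(s, w5)), 2.0)

  ## one G:U opposite sRNA position 20 (outside the seed): 0.5
  s20 <- substr(s, 20, 20)
  stopifnot(s20 %in% c("A", "G", "T"))
  wob <- if (s20 == "G") "T" else if (s20 == "T") "G" else NA
  if (is.na(wob)) {
    s <- mutateAt(s, 20, "G"); w <- revComp(s); wob <- "T"
  }
  w20 <- mutateAt(revComp(s), nchar(s) - 19, wob)
  expect_equal(expectation(scoreDuplex(s, w20)), 0.5)
})

test_that("scoring matches the recursive oracle on random duplex pairs", {
  set.seed(101)
  sch <- scoringScheme()
  for (rep in 1:40) {
    n <- sample(20:22, 1)
    s <- randomDna(n)
    w <- if (runif(1) < 0.5) randomDna(n + sample(-2:2, 1)) else {
      ## near-complement with a few mutations
      x <- revComp(s)
      for (k in sample(n, sample(0:4, 1))) x <- mutateAt(x, k, randomDna(1))
      x
    }
    if (nchar(w) < 10) next
    expect_equal(expectation(scoreDuplex(s, w, sch)),
                 oracleDuplexScore(s, w, sch), tolerance = 1e-9,
                 info = paste(s, w))
  }
})

test_that("window shorter than 10 nt is rejected", {
  expect_error(scoreDuplex("ACGTACGTACGTACGTACGTA", "ACGTACGTA"),
               "shorter than 10")
})

test_that("adding a mismatch never decreases the expectation", {
  set.seed(102)
  for (rep in 1:20) {
    s <- randomDna(21)
    w <- revComp(s)
    e0 <- expectation(scoreDuplex(s, w))
    pos <- sample(nchar(w), 1)
    srnaPos <- nchar(w) - pos + 1
    w2 <- mutateAt(w, pos, clashBase(substr(s, srnaPos, srnaPos)))
    e1 <- expectation(scoreDuplex(s, w2))
    expect_gte(e1, e0)
    expect_gt(e1, 0)
  }
})

test_that("seed multiplier scales seed-region defects by the multiplier ratio", {
  s <- "TGGAGCTCCCTTCATTCCAAT"
  w <- mutateAt(revComp(s), nchar(s) - 4, clashBase(substr(s, 5, 5)))
  e2 <- expectation(scoreDuplex(s, w, scoringScheme(seedMultiplier = 2)))
  e1 <- expectation(scoreDuplex(s, w, scoringScheme(seedMultiplier = 1)))
  expect_equal(e2 / e1, 2)
})

test_that("predictTargets finds an embedded perfect complement", {
  set.seed(103)
  s <- setNames(randomDna(21), "mir1")
  tx <- randomDna(300)
  substr(tx, 120, 140) <- revComp(unname(s))
  sites <- predictTargets(s, c(t1 = tx))
  hit <- sites[sites$expectation == 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 120L)
  expect_equal(hit$end, 140L)
  expect_equal(hit$predicted_cleavage, 140L - 9L)
})

test_that("predictTargets equals the exhaustive brute-force scan", {
  set.seed(104)
  for (rep in 1:2) {
    s <- setNames(randomDna(21), "m")
    tx <- randomDna(110)
    if (rep %% 2 == 0) {
      ## plant a decent site so that non-empty results are exercised
      at <- sample(60, 1)
      near <- revComp(unname(s))
      near <- mutateAt(near, 5, randomDna(1))
      substr(tx, at, at + 20) <- near
    }
    sch <- scoringScheme(maxExpectation = 5)
    got <- predictTargets(s, c(t = tx), sch)
    want <- oracleTargetScan(unname(s), tx, sch)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$expectation, want$expectation, tolerance = 1e-9)
  }
})

test_that("an impossible threshold yields no sites", {
  set.seed(105)
  s <- setNames(randomDna(21), "m")
  tx <- paste0(randomDna(50), revComp(unname(s)), randomDna(50))
  sites <- predictTargets(s, c(t = tx), scoringScheme(maxExpectation = -1))
  expect_equal(nrow(sites), 0L)
})

test_that("predicted cleavage follows the position-10 convention", {
  set.seed(106)
  s <- randomDna(21)
  ## gap-free duplex ending at 120 and at 607
  for (endPos in c(120L, 607L)) {
    d <- scoreDuplex(s, revComp(s), siteStart = endPos - 20L)
    expect_equal(siteEnd(d), endPos)
    expect_equal(predictedCleavage(d), endPos - 9L)
  }
})

test_that("a target bulge 3' of sRNA position 10 leaves the cleavage site", {
  set.seed(107)
  s <- randomDna(21)
  w <- revComp(s)
  ## insert an extra target base opposite the region pairing sRNA 15..16:
  ## window positions 1..6 face sRNA 16..21, so inserting after window
  ## position 6 bulges the target 3' of sRNA position 10 on the sRNA scale
  w2 <- paste0(substr(w, 1, 6), "A", substr(w, 7, nchar(w)))
  d <- scoreDuplex(s, w2, siteStart = 100L)
  expect_true("target_bulge" %in% pairingStates(d))
  ## siteEnd shifted by +1 but the base paired to position 10 is unchanged
  ## relative to the duplex: cleavage = siteEnd - 10 (one bulged base between)
  cl <- predictedCleavage(d)
  at10 <- which(d@srnaPositions == 10L)
  expect_equal(cl, d@targetPositions[at10])
  expect_false(isTRUE(attr(cl, "flagged")))
  ## the bulge lies 3' of position 10 on the sRNA: positions 1..9 pairing
  ## unchanged relative to site end
  expect_equal(siteEnd(d) - d@targetPositions[which(d@srnaPositions == 1L)], 0L)
})
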