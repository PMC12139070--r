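test_that("MFEI arithmetic and degenerate inputs", {
  m <- computeMfei(strrep("GCAT", 25), -50)  # 100 nt, GC 50%
  expect_equal(m$amfe, 50)
  expect_equal(m$mfei, 1.0)

  ## 120 nt, GC 40%
  seq2 <- paste0(strrep("GC", 24), strrep("AT", 36))
  m2 <- computeMfei(seq2, -30)
  expect_equal(m2$gc_percent, 40)
  expect_equal(m2$mfei, 0.625)

  expect_error(computeMfei(strrep("AT", 30), -10), "GC")
  expect_error(computeMfei("ACGT", 5))
})

test_that("MFEI is invariant under duplication with proportional MFE", {
  set.seed(201)
  s <- randomDna(80)
  m1 <- computeMfei(s, -40)
  m2 <- computeMfei(strrep(s, 2), -80)
  expect_equal(m1$mfei, m2$mfei)
})

test_that("generator duplex has 2-nt 3' overhangs and no asymmetric bulges", {
  mp <- makePrecursor("TCGGACCAGGCTTCATTCCCCT", config = simConfig(seed = 1))
  g <- extractDuplex(mp$hairpin)
  expect_equal(g$overhang_3p_mature, 2L)
  expect_equal(g$overhang_3p_star, 2L)
  expect_equal(g$asymmetric_bulges, 0L)
  expect_equal(g$mismatched_mature_bases, 2L)
})

test_that("blunt and bulged hand-drawn duplexes are measured correctly", {
  ## fully paired blunt duplex: 8-nt arms, 4-nt loop
  seq <- "GGGGGGGGAAAACCCCCCCC"
  db <- "((((((((....))))))))"
  hp <- hairpinCandidate(seq, db, -10, 1, 8, 13, 20)
  g <- extractDuplex(hp)
  expect_equal(g$overhang_3p_mature, 0L)
  expect_equal(g$overhang_3p_star, 0L)
  expect_equal(g$asymmetric_bulges, 0L)
  expect_equal(g$mismatched_mature_bases, 0L)

  ## one 2-nt bulge on the mature strand only:
  ## mature GGGG AA GGGG pairs CCCCCCCC on the star side
  seq2 <- "GGGGAAGGGGAAAACCCCCCCC"
  db2 <- "((((..((((....))))))))"
  hp2 <- hairpinCandidate(seq2, db2, -10, 1, 10, 15, 22)
  g2 <- extractDuplex(hp2)
  expect_equal(g2$asymmetric_bulges, 1L)
  expect_equal(g2$mismatched_mature_bases, 0L)

  ## symmetric internal loop = mismatches, not bulges
  seq3 <- "GGGGAAGGGGAAAACCCCTTCCCC"
  db3 <- "((((..((((....))))..))))"
  hp3 <- hairpinCandidate(seq3, db3, -10, 1, 10, 15, 24)
  g3 <- extractDuplex(hp3)
  expect_equal(g3$asymmetric_bulges, 0L)
  expect_equal(g3$mismatched_mature_bases, 2L)

  ## no pairing between the annotated arms at all
  seq4 <- "GGGGAAAACCCCTTTTTTTT"
  db4 <- "((((....))))........"
  hp4 <- hairpinCandidate(seq4, db4, -5, 13, 16, 17, 20)
  expect_error(extractDuplex(hp4), "malformed")
})

test_that("criteria boundaries are strict", {
  mp <- makePrecursor("TCGGACCAGGCTTCATTCCCCT", config = simConfig(seed = 1))
  hp <- mp$hairpin
  rep10 <- validatePrecursor(hp, 10)
  expect_true(rep10$overall)

  ## read support: "more than two reads" means 2 fails
  rep2 <- validatePrecursor(hp, 2)
  expect_false(rep2$reads_ok)
  expect_false(rep2$overall)
  expect_true(rep2$mfe_ok && rep2$overhang_ok && rep2$duplex_ok && rep2$mfei_ok)

  ## free energy: -29.9 fails the strict < -30 bound
  hpWeak <- hp; hpWeak@mfe <- -29.9
  repW <- validatePrecursor(hpWeak, 10)
  expect_false(repW$mfe_ok)

  ## MFEI boundary: force mfei below 0.85 with a barely negative energy
  hpLow <- hp; hpLow@mfe <- -31
  repL <- validatePrecursor(hpLow, 10)
  expect_true(repL$mfe_ok)
  expect_false(repL$mfei_ok)
})

test_that("toggling one threshold flips exactly one criterion", {
  mp <- makePrecursor("TCGGACCAGGCTTCATTCCCCT", config = simConfig(seed = 2))
  hp <- mp$hairpin
  base <- validatePrecursor(hp, 5)
  expect_true(base$overall)
  flags <- c("reads_ok", "mfe_ok", "overhang_ok", "duplex_ok", "mfei_ok")
  tweaks <- list(
    criteriaThresholds(minReads = 6L),
    criteriaThresholds(maxMfe = hp@mfe - 1),
    criteriaThresholds(requiredOverhang = 3L),
    criteriaThresholds(maxMismatches = 1L),
    criteriaThresholds(minMfei = 2))
  for (i in seq_along(tweaks)) {
    r <- validatePrecursor(hp, 5, tweaks[[i]])
    expect_false(r[[flags[i]]])
    expect_identical(unlist(r[flags[-i]]), unlist(base[flags[-i]]))
    expect_false(r$overall)
  }
})

test_that("excess star mismatches fail the duplex criterion", {
  mp <- makePrecursor("TCGGACCAGGCTTCATTCCCCT", starMismatches = 6L,
                      config = simConfig(seed = 4))
  r <- validatePrecursor(mp$hairpin, 10)
  expect_false(r$duplex_ok)
})

test_that("a hairpin needs a terminal loop", {
  expect_error(makePrecursor("TCGGACCAGGCTTCATTCCCCT", loopLength = 0),
               "loop")
  expect_error(makePrecursor("TCGGACCNGGCTTCATTCCCCT"), "non-nucleotide")
})

test_that("fallback fold maximises pairing and flags itself approximate", {
  f <- foldFallback("GGGGAAAACCCC")
  expect_equal(f$pairs, 4L)
  expect_equal(f$dotbracket, "((((....))))")
  expect_true(f$approximate)

  f0 <- foldFallback("AAAA")
  expect_equal(f0$pairs, 0L)
  expect_equal(f0$pseudo_mfe, 0)

  set.seed(202)
  for (rep in 1:8) {
    s <- randomDna(sample(8:14, 1))
    expect_equal(foldFallback(s)$pairs, oracleMaxPairs(s), info = s)
  }
})
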