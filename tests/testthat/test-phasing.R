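alignmentRow <- function(start, len = 21L, strand = "+", count = 1L,
                         tid = "t") {
  data.frame(read_sequence = strrep("A", len), transcript_id = tid,
             start = as.integer(start), end = as.integer(start + len - 1L),
             strand = strand, count = as.integer(count),
             stringsAsFactors = FALSE)
}

test_that("phase statistics count in- and out-of-phase mass", {
  tx <- setNames(strrep("ACGT", 100), "t")
  cfg <- phasingConfig()
  empty <- alignmentRow(1)[0, ]
  s0 <- phaseStatistics(empty, tx, 1L, 0L, cfg)
  expect_equal(s0@k, 0L); expect_equal(s0@P, 0); expect_equal(s0@U, 0)

  ## 3 in-phase (cycles 0,1,2 of register 1 mod 21), one off-phase
  al <- rbind(alignmentRow(22, count = 10), alignmentRow(43, count = 10),
              alignmentRow(64, count = 10), alignmentRow(30, count = 3))
  st <- phaseStatistics(al, tx, 22L, 22L %% 21L, cfg)
  expect_equal(st@k, 3L)
  expect_equal(st@P, 30)
  expect_equal(st@U, 3)

  ## off-length reads always count toward U
  al2 <- rbind(alignmentRow(22, count = 5), alignmentRow(43, len = 22L,
                                                         count = 7))
  st2 <- phaseStatistics(al2, tx, 22L, 1L, cfg)
  expect_equal(st2@P, 5); expect_equal(st2@U, 7)

  ## antisense reads fold onto the sense register via the Dicer offset
  al3 <- rbind(alignmentRow(22, count = 4),
               alignmentRow(41, strand = "-", count = 6))
  st3 <- phaseStatistics(al3, tx, 22L, 1L, cfg)
  expect_equal(st3@P, 10)
  expect_equal(st3@k, 2L)  # cycles 0 and 1
})

test_that("statistics match a direct per-read classification", {
  set.seed(401)
  tx <- setNames(strrep("ACGT", 150), "t")
  cfg <- phasingConfig()
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    al <- do.call(rbind, lapply(seq_len(n), function(i)
      alignmentRow(sample(350, 1), len = sample(20:22, 1),
                   strand = sample(c("+", "-"), 1), count = sample(1:9, 1))))
    ws <- 1L + 21L * sample(0:3, 1)
    r <- sample(0:20, 1)
    st <- phaseStatistics(al, tx, ws, r, cfg)
    ## oracle: classify each read independently
    eff <- ifelse(al$strand == "-", al$start + 2L, al$start)
    len <- al$end - al$start + 1L
    inw <- eff >= ws & eff <= ws + 189L - 1L
    inp <- inw & len == 21L & (eff %% 21L) == (r %% 21L)
    expect_equal(st@P, sum(al$count[inp]))
    expect_equal(st@U, sum(al$count[inw & !inp]))
    expect_equal(st@k, length(unique((eff[inp] - ws) %/% 21L)))
  }
})

test_that("phasing score follows the closed form", {
  expect_equal(phasingScore(new("PhaseStatistics", k = 2L, P = 100, U = 0)), 0)
  expect_equal(phasingScore(new("PhaseStatistics", k = 3L, P = 33, U = 10)),
               log(31))
  expect_equal(phasingScore(new("PhaseStatistics", k = 5L, P = 10, U = 0)),
               3 * log(101))
})

test_that("hypergeometric p-value equals exhaustive enumeration (m <= 12)", {
  expect_equal(phasingPvalue(2, 2, period = 5, cycles = 2), 1 / 45)
  expect_equal(phasingPvalue(0, 4, period = 4, cycles = 3), 1.0)
  for (period in c(3, 4)) {
    for (n in 1:5) {
      cycles <- 3
      for (k in 0:min(n, cycles)) {
        expect_equal(phasingPvalue(k, n, period = period, cycles = cycles),
                     oraclePhasingPvalue(k, n, period, cycles),
                     tolerance = 1e-12,
                     info = sprintf("p=%d n=%d k=%d", period, n, k))
      }
    }
  }
  ## monotone decreasing in k
  pv <- vapply(0:5, function(k) phasingPvalue(k, 5, period = 21, cycles = 9),
               numeric(1))
  expect_true(all(diff(pv) <= 0))
  expect_error(phasingPvalue(2, 500, period = 21, cycles = 9), "occupied")
})

test_that("a synthetic phased locus is recovered with its period and origin", {
  sim <- simulatePhasiRNALocus(simConfig(seed = 42))
  al <- mapReads(sim$reads, sim$transcript)
  loci <- detectPhasingLoci(al, sim$transcript)
  expect_equal(length(loci), 1L)
  expect_equal(locusPeriod(loci[[1]]), sim$truth$period)
  expect_equal(registerOrigin(loci[[1]]), sim$truth$origin)
  expect_lt(phaseStats(loci[[1]])@pvalue, 1e-6)
})

test_that("pure noise yields no locus at the default threshold", {
  set.seed(43)
  tx <- setNames(randomDna(600), "t")
  al <- do.call(rbind, lapply(1:40, function(i)
    alignmentRow(sample(570, 1), len = sample(20:22, 1),
                 strand = sample(c("+", "-"), 1))))
  expect_equal(length(detectPhasingLoci(al, tx)), 0L)
})

test_that("two disjoint loci on one transcript are reported separately", {
  cfg1 <- simConfig(seed = 91, transcriptLength = 2000L,
                    cleavagePosition = 200L, nRegisters = 8L, occupancy = 1,
                    noiseFraction = 0)
  sim1 <- simulatePhasiRNALocus(cfg1)
  ## second locus placed far downstream on the same transcript
  cfg2 <- simConfig(seed = 92, transcriptLength = 2000L,
                    cleavagePosition = 1400L, nRegisters = 8L, occupancy = 1,
                    noiseFraction = 0)
  sim2 <- simulatePhasiRNALocus(cfg2)
  al2 <- sim2$alignments
  al <- rbind(sim1$alignments, al2)
  loci <- detectPhasingLoci(al, sim1$transcript)
  expect_equal(length(loci), 2L)
  expect_equal(registerOrigin(loci[[1]]), 201L)
  expect_equal(registerOrigin(loci[[2]]), 1401L)
  expect_lt(loci[[1]]@end, loci[[2]]@start)
})

test_that("register enumeration tiles the locus and names both strands", {
  cfg <- simConfig(seed = 55, transcriptLength = 400L, cleavagePosition = 100L,
                   nRegisters = 5L, occupancy = 1, noiseFraction = 0)
  sim <- simulatePhasiRNALocus(cfg)
  loci <- detectPhasingLoci(sim$alignments, sim$transcript)
  expect_equal(length(loci), 1L)
  sp <- enumerateRegisters(loci[[1]], "GeneX", sim$alignments, sim$transcript)
  expect_equal(nrow(sp), 10L)
  expect_equal(sum(sp$strand == "+"), 5L)
  expect_false(any(duplicated(sp$name)))
  expect_equal(sp$name[1], "GeneX-siRD1(+)")
  expect_equal(sp$name[2], "GeneX-siRD1(-)")
  ## sense D1 starts at the origin; antisense D1 two bases upstream
  expect_equal(sp$start[sp$name == "GeneX-siRD1(+)"], 101L)
  expect_equal(sp$start[sp$name == "GeneX-siRD1(-)"], 99L)
  ## sense registers tile without gaps or overlaps
  sense <- sp[sp$strand == "+", ]
  expect_equal(sense$start[-1], head(sense$end, -1) + 1L)
  ## abundances match the generator truth
  for (k in 1:5) {
    expect_equal(sp$abundance[sp$name == sprintf("GeneX-siRD%d(+)", k)],
                 unname(sim$truth$abundance[k, "+"]))
    expect_equal(sp$abundance[sp$name == sprintf("GeneX-siRD%d(-)", k)],
                 unname(sim$truth$abundance[k, "-"]))
  }
})

test_that("unoccupied registers are still enumerated with abundance zero", {
  cfg <- simConfig(seed = 56, transcriptLength = 500L, cleavagePosition = 100L,
                   nRegisters = 8L, occupancy = 0.6, noiseFraction = 0)
  sim <- simulatePhasiRNALocus(cfg)
  loci <- detectPhasingLoci(sim$alignments, sim$transcript)
  expect_equal(length(loci), 1L)
  sp <- enumerateRegisters(loci[[1]], "G", sim$alignments, sim$transcript)
  occ <- sim$truth$occupancy
  ## every register between the first and last occupied one is present
  firstK <- min(which(rowSums(occ) > 0))
  for (k in seq_len(nrow(sp) / 2)) {
    truthK <- k + firstK - 1L
    if (truthK > nrow(occ)) break
    row <- sp[sp$strand == "+" & sp$register == k, ]
    if (!occ[truthK, "+"]) expect_equal(row$abundance, 0L)
  }
  expect_true(any(sp$abundance == 0L) || all(rowSums(!occ) == 0))
})

test_that("type-I error of window acceptance is controlled", {
  tx <- setNames(strrep("ACGT", 60), "t")  # 240 nt
  cfg <- phasingConfig()
  hits <- 0L
  set.seed(44)
  for (i in 1:200) {
    al <- do.call(rbind, lapply(1:30, function(j)
      alignmentRow(sample(169, 1))))
    ## window acceptance rule of the detector: best register score above the
    ## threshold AND register-corrected hypergeometric p-value below the
    ## family-wise bound
    best <- 0; bestK <- 0L
    for (r in 0:20) {
      st <- phaseStatistics(al, tx, 1L, r, cfg)
      sc <- phasingScore(st, cfg)
      if (sc > best) { best <- sc; bestK <- st@k }
    }
    if (best >= cfg@minScore) {
      eff <- ifelse(al$strand == "-", al$start + 2L, al$start)
      nOcc <- length(unique(eff[eff >= 1 & eff <= 189]))
      pv <- phasingPvalue(bestK, nOcc, cfg)
      if (pv * 21 <= cfg@maxPvalue) hits <- hits + 1L
    }
  }
  expect_lte(hits / 200, 0.05)
})


test_that("loci are recovered with the exact period in 95% of replicates", {
  recovered <- 0L
  for (i in 1:200) {
    cfg <- simConfig(seed = 6000 + i, transcriptLength = 500L,
                     cleavagePosition = 100L, nRegisters = 8L,
                     occupancy = 0.6, noiseFraction = 0.05)
    sim <- simulatePhasiRNALocus(cfg)
    loci <- detectPhasingLoci(sim$alignments, sim$transcript)
    if (length(loci) >= 1L &&
        any(vapply(loci, locusPeriod, integer(1)) == 21L))
      recovered <- recovered + 1L
  }
  expect_gte(recovered / 200, 0.95)
})
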