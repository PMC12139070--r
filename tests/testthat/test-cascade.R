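## build a two-tier cascade: a primary locus on transcript A, one of whose
## antisense phasiRNAs seeds a secondary locus on transcript B
makeTwoTierCascade <- function(seed) {
  cfgA <- simConfig(seed = seed, transcriptLength = 500L,
                    cleavagePosition = 100L, nRegisters = 8L, occupancy = 1,
                    noiseFraction = 0)
  simA <- simulatePhasiRNALocus(cfgA, transcriptId = "TXA")
  lociA <- detectPhasingLoci(simA$alignments, simA$transcript)
  spA <- enumerateRegisters(lociA[[1]], "TXA", simA$alignments,
                            simA$transcript)
  trueTrigger <- spA[spA$name == "TXA-siRD5(-)", ]

  cfgB <- simConfig(seed = seed + 1L, transcriptLength = 500L,
                    cleavagePosition = 150L, nRegisters = 8L, occupancy = 1,
                    noiseFraction = 0, triggerLength = 21L)
  simB <- simulatePhasiRNALocus(cfgB, transcriptId = "TXB")
  ## replace the embedded site with the perfect complement of the phasiRNA
  txB <- unname(simB$transcript)
  substr(txB, simB$truth$site_start, simB$truth$site_end) <-
    revComp(trueTrigger$sequence)
  transcriptB <- setNames(txB, "TXB")
  lociB <- detectPhasingLoci(simB$alignments, transcriptB)

  decoys <- spA[spA$strand == "-" & spA$register %in% c(1, 3, 7), ]
  pool <- setNames(c(trueTrigger$sequence, decoys$sequence,
                     unname(simA$trigger)),
                   c(trueTrigger$name, decoys$name, "miR-primary"))
  list(simA = simA, lociA = lociA, spA = spA, transcriptB = transcriptB,
       lociB = lociB, pool = pool, trueName = trueTrigger$name)
}

test_that("the seeding phasiRNA is top-ranked with a register match", {
  cas <- makeTwoTierCascade(7001L)
  expect_equal(length(cas$lociB), 1L)
  hyp <- inferTriggers(cas$lociB[[1]], cas$pool,
                       c(cas$simA$transcript, cas$transcriptB))
  expect_gt(nrow(hyp), 0L)
  expect_equal(hyp$srna_id[1], cas$trueName)
  expect_true(hyp$register_match[1])
  expect_equal(hyp$expectation[1], 0)
  expect_equal(hyp$cleavage[1], 150L)
})

test_that("register arithmetic holds for every register-match hypothesis", {
  cas <- makeTwoTierCascade(7002L)
  hyp <- inferTriggers(cas$lociB[[1]], cas$pool,
                       c(cas$simA$transcript, cas$transcriptB))
  m <- hyp[hyp$register_match, ]
  for (i in seq_len(nrow(m))) {
    r <- (m$cleavage[i] + 1L - registerOrigin(cas$lociB[[1]])) %%
      locusPeriod(cas$lociB[[1]])
    expect_true(min(r, locusPeriod(cas$lociB[[1]]) - r) <= 1L)
  }
})

test_that("cleavage off the register lattice is not a register match", {
  cas <- makeTwoTierCascade(7003L)
  locus <- cas$lociB[[1]]
  ## a synthetic hypothesis whose cleavage sits 29 nt downstream of the
  ## origin: (cleavage + 1 - origin) = 30 = 9 mod 21, beyond the tolerance
  tx <- cas$transcriptB
  up <- registerOrigin(locus) + 29L  # cleavage position
  srna <- setNames(revComp(substr(tx, up - 11L, up + 9L)), "offlattice")
  hyp <- inferTriggers(locus, srna, tx)
  expect_equal(nrow(hyp), 1L)
  expect_equal(hyp$cleavage, up)
  expect_false(hyp$register_match)
})

test_that("an empty or non-targeting pool yields no hypotheses", {
  cas <- makeTwoTierCascade(7004L)
  expect_equal(nrow(inferTriggers(cas$lociB[[1]], character(0),
                                  cas$transcriptB)), 0L)
  set.seed(1)
  far <- setNames(randomDna(21), "unrelated")
  hyp <- inferTriggers(cas$lociB[[1]], far, cas$transcriptB)
  expect_true(nrow(hyp) == 0L || all(hyp$expectation <= 3.5))
})

test_that("the true secondary trigger is top-ranked in at least 90% of replicates", {
  top <- 0L
  for (i in 1:100) {
    cas <- makeTwoTierCascade(7100L + 2L * i)
    if (length(cas$lociB) < 1L) next
    hyp <- inferTriggers(cas$lociB[[1]], cas$pool,
                         c(cas$simA$transcript, cas$transcriptB))
    if (nrow(hyp) && hyp$srna_id[1] == cas$trueName) top <- top + 1L
  }
  expect_gte(top / 100, 0.90)
})

test_that("the reported three-gene cascade topology is reproduced as a network", {
  ## relationships: the miRNA cleaves T33 and T45 triggering their loci; the
  ## register-10 antisense phasiRNA of each cleaves T26 at one shared
  ## position; T45's own phasiRNAs also cleave T45 (cis)
  sites <- data.frame(
    srna_id = c("miR", "miR", "T33-siRD10(-)", "T45-siRD10(-)",
                "T45-siRD8(-)"),
    transcript_id = c("T33", "T45", "T26", "T26", "T45"),
    start = c(578L, 578L, 774L, 774L, 300L),
    end = c(598L, 598L, 794L, 794L, 320L),
    expectation = c(0, 0.5, 1, 1.5, 2),
    predicted_cleavage = c(587L, 587L, 785L, 785L, 309L),
    stringsAsFactors = FALSE)
  evid <- data.frame(srna_id = c("miR", "T33-siRD10(-)"),
                     transcript_id = c("T33", "T26"),
                     validated = c(TRUE, TRUE),
                     evidence = c("degradome", "race"),
                     stringsAsFactors = FALSE)
  mkLocus <- function(tid, origin) new("PhasingLocus", transcriptId = tid,
    start = origin, end = origin + 10L * 21L - 1L, period = 21L,
    registerOrigin = origin,
    statistics = new("PhaseStatistics", k = 9L, P = 100, U = 1,
                     score = 40, pvalue = 1e-10))
  loci <- list(mkLocus("T33", 588L), mkLocus("T45", 588L),
               mkLocus("T26", 786L))
  phasi <- data.frame(
    name = c("T33-siRD10(-)", "T45-siRD10(-)", "T45-siRD8(-)",
             "T26-siRD1(+)"),
    transcript_id = c("T33", "T45", "T45", "T26"),
    start = c(775L, 775L, 733L, 786L), stringsAsFactors = FALSE)
  net <- buildCascadeNetwork(sites, evid, loci, phasi)
  expect_equal(sum(net$kind == "cleaves"), 5L)
  expect_equal(sum(net$kind == "produces"), 4L)
  ## three-tier chain: miR -> T33 -> T33-siRD10(-) -> T26 -> T26-siRD1(+)
  expect_true(any(net$source == "miR" & net$target == "T33"))
  expect_true(any(net$source == "T33" & net$target == "T33-siRD10(-)"))
  expect_true(any(net$source == "T33-siRD10(-)" & net$target == "T26"))
  expect_true(any(net$source == "T26" & net$target == "T26-siRD1(+)"))
  ## self-reinforcing cis edge on T45
  expect_true(any(net$source == "T45-siRD8(-)" & net$target == "T45"))
  ## degradome/race evidence propagated
  expect_equal(net$evidence[net$source == "miR" & net$target == "T33"],
               "degradome")
  expect_equal(net$evidence[net$source == "T33-siRD10(-)"], "race")
  ## deterministic ordering
  expect_equal(net, net[order(net$source, net$target, net$kind), ],
               ignore_attr = TRUE)
  ## dangling production reference is an error
  bad <- rbind(phasi, data.frame(name = "X-siRD1(+)", transcript_id = "X",
                                 start = 1L))
  expect_error(buildCascadeNetwork(sites, evid, loci, bad), "X")
})

test_that("produces edges always lie inside a detected locus (containment)", {
  set.seed(7200)
  for (i in 1:5) {
    cfg <- simConfig(seed = 7200L + i, transcriptLength = 500L,
                     cleavagePosition = 100L, nRegisters = 6L,
                     occupancy = 0.9, noiseFraction = 0.05)
    sim <- simulatePhasiRNALocus(cfg, transcriptId = "T")
    loci <- detectPhasingLoci(sim$alignments, sim$transcript)
    if (!length(loci)) next
    sp <- enumerateRegisters(loci[[1]], "T", sim$alignments, sim$transcript)
    sp$transcript_id <- "T"
    net <- buildCascadeNetwork(
      data.frame(srna_id = character(), transcript_id = character(),
                 expectation = numeric(), predicted_cleavage = integer()),
      NULL, loci, sp)
    prod <- net[net$kind == "produces", ]
    off <- phasingConfig()@antisenseOffset
    expect_true(all(prod$position >= loci[[1]]@start - off &
                    prod$position <= loci[[1]]@end))
  }
})

test_that("an isolated sRNA yields an empty edge list", {
  net <- buildCascadeNetwork(
    data.frame(srna_id = character(), transcript_id = character(),
               expectation = numeric(), predicted_cleavage = integer()))
  expect_equal(nrow(net), 0L)
})
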