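## S4 classes for the central objects. Tabular collections (reads, alignments,
## degradome signals, target-site tables, phasiRNA species, cascade edges) are
## plain data.frames documented with their reader/constructor functions.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ScoringScheme: penalties for expectation-scored duplex alignment
#'
#' The expectation of an sRNA:mRNA duplex is the penalty sum of its aligned
#' columns: 0 for a Watson-Crick pair, `wobblePenalty` for a G:U pair,
#' `mismatchPenalty` for a mismatch, and affine gap penalties for bulges.
#' Penalties at sRNA positions `seedStart..seedEnd` (counted from the sRNA 5'
#' end) are multiplied by `seedMultiplier`. Sites with expectation at most
#' `maxExpectation` are reported. At most `maxBulges` gap events are allowed
#' in a duplex (plant miRNA duplexes are near-ungapped).
#'
#' @slot mismatchPenalty,wobblePenalty,gapOpenPenalty,gapExtendPenalty numeric
#'   penalties in score units, all >= 0.
#' @slot seedStart,seedEnd integer sRNA positions bounding the seed region.
#' @slot seedMultiplier numeric factor applied to penalties in the seed.
#' @slot maxExpectation numeric reporting threshold.
#' @slot maxBulges integer maximum number of gap events per duplex.
#' @export
setClass("ScoringScheme",
  representation(
    mismatchPenalty = "numeric", wobblePenalty = "numeric",
    gapOpenPenalty = "numeric", gapExtendPenalty = "numeric",
    seedStart = "integer", seedEnd = "integer",
    seedMultiplier = "numeric", maxExpectation = "numeric",
    maxBulges = "integer"
  ),
  prototype(
    mismatchPenalty = 1.0, wobblePenalty = 0.5,
    gapOpenPenalty = 2.0, gapExtendPenalty = 0.5,
    seedStart = 2L, seedEnd = 13L,
    seedMultiplier = 2.0, maxExpectation = 3.5,
    maxBulges = 2L
  )
)

setValidity("ScoringScheme", function(object) {
  pen <- c(object@mismatchPenalty, object@wobblePenalty,
           object@gapOpenPenalty, object@gapExtendPenalty)
  if (any(pen < 0)) return("all penalties must be >= 0")
  if (object@seedStart < 1L || object@seedEnd < object@seedStart)
    return("need 1 <= seedStart <= seedEnd")
  if (object@seedMultiplier < 0) return("seedMultiplier must be >= 0")
  if (object@maxBulges < 0L) return("maxBulges must be >= 0")
  TRUE
})

#' Construct a scoring scheme
#'
#' @param mismatchPenalty,wobblePenalty,gapOpenPenalty,gapExtendPenalty
#'   penalties (score units).
#' @param seedStart,seedEnd seed-region bounds (sRNA positions from the 5'
#'   end).
#' @param seedMultiplier factor applied to penalties in the seed region.
#' @param maxExpectation reporting threshold for target sites.
#' @param maxBulges maximum gap events per duplex.
#' @return a [ScoringScheme-class] object.
#' @examples
#' scoringScheme()
#' scoringScheme(maxExpectation = 2)
#' @export
scoringScheme <- function(mismatchPenalty = 1.0, wobblePenalty = 0.5,
                          gapOpenPenalty = 2.0, gapExtendPenalty = 0.5,
                          seedStart = 2L, seedEnd = 13L, seedMultiplier = 2.0,
                          maxExpectation = 3.5, maxBulges = 2L) {
  new("ScoringScheme",
      mismatchPenalty = mismatchPenalty, wobblePenalty = wobblePenalty,
      gapOpenPenalty = gapOpenPenalty, gapExtendPenalty = gapExtendPenalty,
      seedStart = as.integer(seedStart), seedEnd = as.integer(seedEnd),
      seedMultiplier = seedMultiplier, maxExpectation = maxExpectation,
      maxBulges = as.integer(maxBulges))
}

#' DuplexAlignment: a scored sRNA:mRNA duplex
#'
#' Represents the optimal (minimum-expectation) antiparallel alignment of a
#' small RNA against a transcript window. Orientation: sRNA position 1 pairs
#' the site end, sRNA position n pairs toward the site start. The
#' per-column `states` vector uses `"pair"`, `"wobble"`, `"mismatch"`,
#' `"srna_bulge"` (sRNA base unopposed) and `"target_bulge"` (target base
#' unopposed). `srnaPositions`/`targetPositions` give, per column, the sRNA
#' index and the 1-based transcript coordinate (NA inside a gap).
#'
#' @slot srna sRNA sequence (5'->3').
#' @slot transcriptId target transcript identifier.
#' @slot siteStart,siteEnd 1-based inclusive transcript coordinates.
#' @slot states character vector of per-column states.
#' @slot srnaPositions,targetPositions integer vectors parallel to `states`.
#' @slot expectation numeric expectation score of the duplex.
#' @export
setClass("DuplexAlignment",
  representation(
    srna = "character", transcriptId = "character",
    siteStart = "integer", siteEnd = "integer",
    states = "character", srnaPositions = "integer",
    targetPositions = "integer", expectation = "numeric"
  )
)

setValidity("DuplexAlignment", function(object) {
  if (object@siteStart > object@siteEnd) return("siteStart must be <= siteEnd")
  nc <- length(object@states)
  if (length(object@srnaPositions) != nc || length(object@targetPositions) != nc)
    return("states, srnaPositions and targetPositions must have equal length")
  ok <- c("pair", "wobble", "mismatch", "srna_bulge", "target_bulge")
  if (!all(object@states %in% ok)) return("unknown alignment state")
  TRUE
})

#' HairpinCandidate: a miRNA precursor with structure and annotated arms
#'
#' @slot sequence precursor sequence.
#' @slot dotbracket balanced dot-bracket string, same length as `sequence`.
#' @slot mfe minimum folding free energy in kcal/mol (<= 0).
#' @slot matureStart,matureEnd,starStart,starEnd 1-based inclusive intervals
#'   of the annotated mature miRNA and miRNA* arms.
#' @slot approximateMfe logical; TRUE when `mfe` is a flagged pseudo-energy
#'   from [foldFallback()] rather than a thermodynamic value.
#' @export
setClass("HairpinCandidate",
  representation(
    sequence = "character", dotbracket = "character", mfe = "numeric",
    matureStart = "integer", matureEnd = "integer",
    starStart = "integer", starEnd = "integer",
    approximateMfe = "logical"
  ),
  prototype(approximateMfe = FALSE)
)

setValidity("HairpinCandidate", function(object) {
  n <- nchar(object@sequence)
  if (nchar(object@dotbracket) != n)
    return("dotbracket must have the same length as the sequence")
  ch <- strsplit(object@dotbracket, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    return("dotbracket may only contain '(', ')' and '.'")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0) || (length(depth) && depth[length(depth)] != 0))
    return("dotbracket is not balanced")
  if (object@mfe > 0) return("mfe must be <= 0")
  iv <- c(object@matureStart, object@matureEnd, object@starStart, object@starEnd)
  if (any(iv < 1L) || any(iv > n)) return("arm intervals must lie in the sequence")
  if (object@matureStart > object@matureEnd || object@starStart > object@starEnd)
    return("arm intervals must be non-empty")
  if (object@matureEnd >= object@starStart && object@starEnd >= object@matureStart)
    return("mature and star intervals must be disjoint")
  TRUE
})

#' Construct a hairpin precursor candidate
#'
#' @param sequence precursor sequence (A/C/G/T/U).
#' @param dotbracket balanced dot-bracket secondary structure.
#' @param mfe folding free energy, kcal/mol (<= 0).
#' @param matureStart,matureEnd,starStart,starEnd 1-based inclusive arm
#'   intervals.
#' @param approximateMfe set TRUE when `mfe` is a pseudo-energy.
#' @return a [HairpinCandidate-class] object.
#' @export
hairpinCandidate <- function(sequence, dotbracket, mfe,
                             matureStart, matureEnd, starStart, starEnd,
                             approximateMfe = FALSE) {
  checkNucleotides(sequence, "precursor sequence")
  new("HairpinCandidate", sequence = sequence, dotbracket = dotbracket,
      mfe = as.numeric(mfe),
      matureStart = as.integer(matureStart), matureEnd = as.integer(matureEnd),
      starStart = as.integer(starStart), starEnd = as.integer(starEnd),
      approximateMfe = approximateMfe)
}

#' CriteriaThresholds: cutoffs for the five precursor criteria
#'
#' Defaults encode the annotation criteria: (1) read support of more than two
#' reads (`minReads = 3`), (2) free energy strictly below -30 kcal/mol,
#' (3) 2-nt 3' overhangs on both duplex strands, (4) at most one asymmetric
#' bulge and at most four mismatched mature bases in the miRNA/miRNA* duplex,
#' and (5) MFEI of at least 0.85.
#'
#' @slot minReads integer minimum summed read count.
#' @slot maxMfe numeric strict upper bound on MFE (kcal/mol).
#' @slot minMfei numeric lower bound on MFEI.
#' @slot requiredOverhang integer required 3' overhang length (nt).
#' @slot maxAsymmetricBulges integer maximum asymmetric bulges in the duplex.
#' @slot maxMismatches integer maximum mismatched mature bases in the duplex.
#' @export
setClass("CriteriaThresholds",
  representation(
    minReads = "integer", maxMfe = "numeric", minMfei = "numeric",
    requiredOverhang = "integer", maxAsymmetricBulges = "integer",
    maxMismatches = "integer"
  ),
  prototype(minReads = 3L, maxMfe = -30, minMfei = 0.85,
            requiredOverhang = 2L, maxAsymmetricBulges = 1L,
            maxMismatches = 4L)
)

#' Construct precursor criteria thresholds
#'
#' @param minReads minimum summed read count ("more than two reads" = 3).
#' @param maxMfe strict MFE bound in kcal/mol (candidate passes if mfe <
#'   maxMfe).
#' @param minMfei minimum MFEI.
#' @param requiredOverhang required duplex 3' overhang (nt) on both strands.
#' @param maxAsymmetricBulges maximum asymmetric bulges ("less than two" = 1).
#' @param maxMismatches maximum mismatched mature bases ("less than five" =
#'   4).
#' @return a [CriteriaThresholds-class] object.
#' @examples
#' criteriaThresholds()
#' @export
criteriaThresholds <- function(minReads = 3L, maxMfe = -30, minMfei = 0.85,
                               requiredOverhang = 2L, maxAsymmetricBulges = 1L,
                               maxMismatches = 4L) {
  new("CriteriaThresholds", minReads = as.integer(minReads),
      maxMfe = maxMfe, minMfei = minMfei,
      requiredOverhang = as.integer(requiredOverhang),
      maxAsymmetricBulges = as.integer(maxAsymmetricBulges),
      maxMismatches = as.integer(maxMismatches))
}

#' PhasingConfig: parameters of the phasing-locus detector
#'
#' The detector slides a window of `cycles` periods along the transcript in
#' steps of one period and evaluates every phase register (residue class
#' modulo the period) for every candidate period in `scanPeriods`.
#'
#' @slot period integer phase period in nt (21 for the canonical plant
#'   phasiRNA class).
#' @slot cycles integer window size in periods.
#' @slot minCyclesOccupied integer minimum occupied cycles for a nonzero
#'   score.
#' @slot minScore numeric locus score threshold.
#' @slot maxPvalue numeric family-wise bound on the hypergeometric register
#'   p-value: a window is accepted only when `period * pvalue <= maxPvalue`
#'   (Bonferroni over the registers tested per window).
#' @slot antisenseOffset integer Dicer 2-nt 3' overhang offset applied to
#'   minus-strand registers.
#' @slot scanPeriods integer vector of candidate periods.
#' @export
setClass("PhasingConfig",
  representation(
    period = "integer", cycles = "integer", minCyclesOccupied = "integer",
    minScore = "numeric", maxPvalue = "numeric", antisenseOffset = "integer",
    scanPeriods = "integer"
  ),
  prototype(period = 21L, cycles = 9L, minCyclesOccupied = 3L,
            minScore = 3.0, maxPvalue = 0.05, antisenseOffset = 2L,
            scanPeriods = 18:25)
)

setValidity("PhasingConfig", function(object) {
  if (object@period < 15L) return("period must be >= 15 nt")
  if (object@cycles < 3L) return("cycles must be >= 3")
  if (object@minCyclesOccupied < 1L) return("minCyclesOccupied must be >= 1")
  if (object@antisenseOffset < 0L) return("antisenseOffset must be >= 0")
  TRUE
})

#' Construct a phasing configuration
#'
#' @param period phase period (nt).
#' @param cycles window size in periods.
#' @param minCyclesOccupied minimum occupied cycles for a nonzero score.
#' @param minScore score threshold for calling a locus.
#' @param maxPvalue family-wise (register-corrected) p-value bound for
#'   accepting a window.
#' @param antisenseOffset minus-strand register offset (nt).
#' @param scanPeriods candidate periods to scan.
#' @return a [PhasingConfig-class] object.
#' @examples
#' phasingConfig()
#' @export
phasingConfig <- function(period = 21L, cycles = 9L, minCyclesOccupied = 3L,
                          minScore = 3.0, maxPvalue = 0.05,
                          antisenseOffset = 2L, scanPeriods = 18:25) {
  new("PhasingConfig", period = as.integer(period), cycles = as.integer(cycles),
      minCyclesOccupied = as.integer(minCyclesOccupied), minScore = minScore,
      maxPvalue = maxPvalue, antisenseOffset = as.integer(antisenseOffset),
      scanPeriods = as.integer(scanPeriods))
}

#' PhaseStatistics: in-phase/out-of-phase summary of one window and register
#'
#' @slot k integer number of occupied in-phase cycle positions.
#' @slot P numeric summed abundance of in-phase reads.
#' @slot U numeric summed abundance of out-of-phase reads.
#' @slot score numeric phasing score.
#' @slot pvalue numeric hypergeometric register p-value (NA until computed).
#' @export
setClass("PhaseStatistics",
  representation(k = "integer", P = "numeric", U = "numeric",
                 score = "numeric", pvalue = "numeric"),
  prototype(k = 0L, P = 0, U = 0, score = 0, pvalue = NA_real_)
)

#' PhasingLocus: a detected phased-siRNA locus on a transcript
#'
#' @slot transcriptId transcript identifier.
#' @slot start,end 1-based inclusive locus interval; `start` equals
#'   `registerOrigin` (the start of sense register D1).
#' @slot period integer recovered phase period (nt).
#' @slot registerOrigin integer 1-based start of register D1.
#' @slot statistics a [PhaseStatistics-class] for the best-scoring window.
#' @slot trigger character id of the inferred trigger sRNA (NA if unset).
#' @export
setClass("PhasingLocus",
  representation(
    transcriptId = "character", start = "integer", end = "integer",
    period = "integer", registerOrigin = "integer",
    statistics = "PhaseStatistics", trigger = "character"
  ),
  prototype(trigger = NA_character_)
)

setValidity("PhasingLocus", function(object) {
  if (object@start > object@end) return("start must be <= end")
  if (object@registerOrigin != object@start)
    return("registerOrigin must equal the locus start (register D1)")
  TRUE
})

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Defaults describe the study conditions the generator emulates: a 22-nt
#' trigger cleaving a 2000-nt transcript at position 600, a downstream
#' 21-nt-periodic locus of 12 double-stranded registers with occupancy 0.8,
#' log-normal register abundances, 5 percent off-phase read mass, and a
#' degradome whose cleavage peak carries 90 percent of the tags over a
#' Poisson(0.2) background.
#'
#' @slot seed integer random seed.
#' @slot period integer phase period (nt).
#' @slot triggerLength integer trigger sRNA length (nt).
#' @slot transcriptLength integer transcript length (nt).
#' @slot cleavagePosition integer 1-based trigger cleavage position.
#' @slot nRegisters integer number of phased registers downstream of the
#'   cleavage site.
#' @slot occupancy numeric per-register, per-strand occupancy probability.
#' @slot readsPerRegister numeric mean register abundance (log scale mean of
#'   the log-normal).
#' @slot abundanceSdlog numeric log-normal sigma of register abundances.
#' @slot noiseFraction numeric proportion of off-phase read mass.
#' @slot degradomePeakFraction numeric proportion of degradome tags at the
#'   peak.
#' @slot backgroundRate numeric per-position Poisson background rate.
#' @slot antisenseOffset integer Dicer overhang offset (nt).
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", period = "integer", triggerLength = "integer",
    transcriptLength = "integer", cleavagePosition = "integer",
    nRegisters = "integer", occupancy = "numeric",
    readsPerRegister = "numeric", abundanceSdlog = "numeric",
    noiseFraction = "numeric", degradomePeakFraction = "numeric",
    backgroundRate = "numeric", antisenseOffset = "integer"
  ),
  prototype(
    seed = 1L, period = 21L, triggerLength = 22L,
    transcriptLength = 2000L, cleavagePosition = 600L, nRegisters = 12L,
    occupancy = 0.8, readsPerRegister = 20, abundanceSdlog = 0.8,
    noiseFraction = 0.05, degradomePeakFraction = 0.9,
    backgroundRate = 0.2, antisenseOffset = 2L
  )
)

setValidity("SimulationConfig", function(object) {
  pr <- c(object@occupancy, object@noiseFraction, object@degradomePeakFraction)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@cleavagePosition + object@nRegisters * object@period >
      object@transcriptLength)
    return("cleavage + nRegisters * period must fit in the transcript")
  TRUE
})

#' Construct a simulation configuration
#'
#' @param seed random seed.
#' @param period phase period (nt).
#' @param triggerLength trigger sRNA length (nt).
#' @param transcriptLength transcript length (nt).
#' @param cleavagePosition 1-based trigger cleavage position.
#' @param nRegisters number of phased registers.
#' @param occupancy per-register, per-strand occupancy probability.
#' @param readsPerRegister mean register abundance.
#' @param abundanceSdlog log-normal sigma of register abundances.
#' @param noiseFraction proportion of off-phase read mass.
#' @param degradomePeakFraction proportion of degradome tags at the peak.
#' @param backgroundRate per-position Poisson background rate.
#' @param antisenseOffset Dicer overhang offset (nt).
#' @return a [SimulationConfig-class] object.
#' @examples
#' simConfig(seed = 42)
#' @export
simConfig <- function(seed = 1L, period = 21L, triggerLength = 22L,
                      transcriptLength = 2000L, cleavagePosition = 600L,
                      nRegisters = 12L, occupancy = 0.8,
                      readsPerRegister = 20, abundanceSdlog = 0.8,
                      noiseFraction = 0.05, degradomePeakFraction = 0.9,
                      backgroundRate = 0.2, antisenseOffset = 2L) {
  new("SimulationConfig", seed = as.integer(seed), period = as.integer(period),
      triggerLength = as.integer(triggerLength),
      transcriptLength = as.integer(transcriptLength),
      cleavagePosition = as.integer(cleavagePosition),
      nRegisters = as.integer(nRegisters), occupancy = occupancy,
      readsPerRegister = readsPerRegister, abundanceSdlog = abundanceSdlog,
      noiseFraction = noiseFraction,
      degradomePeakFraction = degradomePeakFraction,
      backgroundRate = backgroundRate,
      antisenseOffset = as.integer(antisenseOffset))
}
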