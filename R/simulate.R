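## Seeded generators with recorded ground truth. Every generator draws all of
## its randomness from config@seed, so identical configurations give
## byte-identical outputs. The defaults describe the emulated study
## conditions: a 22-nt trigger, 21-nt phased registers downstream of the
## cleavage site with 2-nt antisense offset, log-normal register abundances,
## and degradome peaks dominating a sparse Poisson background.

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## a base that neither pairs nor wobbles with b
nonPairingBase <- function(b) {
  choices <- switch(b,
    A = c("A", "C", "G"), C = c("A", "C", "T"),
    G = c("A", "G"), T = c("C", "T"))
  sample(choices, 1)
}

#' Generate a hairpin precursor with an annotated miRNA/miRNA* duplex
#'
#' Builds `5'flank + mature + loop + star + 3'flank` where the star arm is
#' the reverse complement of the mature arm with `starMismatches`
#' substitutions placed away from the duplex termini, and the assigned
#' dot-bracket gives both strands of the annotated duplex 2-nt 3' overhangs
#' (the mature 3' dinucleotide is unpaired; the star 3' dinucleotide pairs
#' flanking bases outside the mature arm). The assigned energy is a
#' pseudo-MFE of `-2 kcal/mol` per pair, flagged approximate.
#'
#' @param mature mature miRNA sequence, 20-24 nt.
#' @param loopLength terminal loop length in nt (>= 1).
#' @param starMismatches substitutions in the star arm.
#' @param config a [SimulationConfig-class] (only the seed is used).
#' @param flankLength flanking stem length on each side (nt).
#' @return list with `hairpin` (a [HairpinCandidate-class]) and `truth`
#'   (mismatch positions, pair count, arm intervals).
#' @export
makePrecursor <- function(mature, loopLength = 15L, starMismatches = 2L,
                          config = simConfig(), flankLength = 20L) {
  checkNucleotides(mature, "mature sequence")
  L <- nchar(mature)
  if (L < 20L || L > 24L) stop("mature must be 20-24 nt", call. = FALSE)
  if (loopLength < 1L)
    stop("loopLength must be >= 1: a hairpin needs a terminal loop",
         call. = FALSE)
  f <- as.integer(flankLength)
  if (f < 4L) stop("flankLength must be >= 4", call. = FALSE)
  set.seed(config@seed)
  M <- strsplit(asDna(mature), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  ## star arm: S[j] pairs M[L-1-j] for j = 1..L-2; last two bases are the
  ## star 3' overhang
  S <- character(L)
  for (j in seq_len(L - 2L)) S[j] <- comp[[M[L - 1L - j]]]
  S[L - 1L] <- sample(c("A", "C", "G", "T"), 1)
  S[L] <- sample(c("A", "C", "G", "T"), 1)

  ## mismatches: interior duplex positions only
  avail <- 4:(L - 5L)
  if (starMismatches > length(avail))
    stop("too many star mismatches for this mature length", call. = FALSE)
  mmAt <- sort(sample(avail, starMismatches))
  for (i in mmAt) S[L - 1L - i] <- nonPairingBase(M[i])

  F1 <- strsplit(randomSeq(f), "", fixed = TRUE)[[1]]
  ## star 3' overhang pairs the last two flank bases (outside the mature arm)
  F1[f] <- comp[[S[L - 1L]]]
  F1[f - 1L] <- comp[[S[L]]]
  loop <- randomSeq(loopLength)
  F2 <- vapply((f - 2L):1L, function(t) comp[[F1[t]]], character(1))

  seq <- paste0(paste(F1, collapse = ""), paste(M, collapse = ""), loop,
                paste(S, collapse = ""), paste(F2, collapse = ""))
  N <- nchar(seq)
  db <- rep(".", N)
  absM <- function(i) f + i
  absS <- function(j) f + L + loopLength + j
  absF2 <- function(j) f + 2L * L + loopLength + j
  npairs <- 0L
  pairUp <- function(a, b) {
    db[a] <<- "("; db[b] <<- ")"; npairs <<- npairs + 1L
  }
  for (t in seq_len(f - 2L)) pairUp(t, absF2(f - 1L - t))
  pairUp(f - 1L, absS(L))
  pairUp(f, absS(L - 1L))
  for (i in seq_len(L - 2L)) {
    if (!(i %in% mmAt)) pairUp(absM(i), absS(L - 1L - i))
  }
  hp <- hairpinCandidate(
    sequence = seq, dotbracket = paste(db, collapse = ""),
    mfe = -2.0 * npairs,
    matureStart = f + 1L, matureEnd = f + L,
    starStart = absS(1L), starEnd = absS(L),
    approximateMfe = TRUE)
  list(hairpin = hp,
       truth = list(mismatch_positions = mmAt, pairs = npairs,
                    mature = c(f + 1L, f + L), star = c(absS(1L), absS(L))))
}

#' Simulate a phased siRNA locus with known ground truth
#'
#' Generates a random transcript carrying an embedded perfect target site of
#' a random 22-nt trigger whose predicted cleavage falls at
#' `config@cleavagePosition`; registers D1..n downstream of the cleavage are
#' occupied independently with probability `occupancy` on each strand and
#' emit reads of exactly one period at the register start (antisense shifted
#' upstream by the Dicer offset) with log-normal abundance; a fraction
#' `noiseFraction` of the total read mass is placed uniformly at random
#' positions and lengths 20-22.
#'
#' @param config a [SimulationConfig-class].
#' @param transcriptId id of the generated transcript.
#' @return list with `transcript` (named character), `reads` (data.frame
#'   `sequence`, `count`, `library`), `alignments` (ground-truth placements
#'   with an `is_noise` flag), `trigger` (named 22-nt sequence) and `truth`
#'   (origin, period, occupancy and abundance per register/strand, site
#'   coordinates).
#' @export
simulatePhasiRNALocus <- function(config = simConfig(),
                                  transcriptId = "TX1") {
  set.seed(config@seed)
  p <- config@period
  len <- config@transcriptLength
  cleavage <- config@cleavagePosition
  tx <- randomSeq(len)
  ## embed the trigger's perfect complement so that the base paired with
  ## trigger position 10 is the cleavage position
  trig <- randomSeq(config@triggerLength)
  siteEnd <- cleavage + 9L
  siteStart <- siteEnd - config@triggerLength + 1L
  if (siteStart < 1L) stop("cleavage position too close to the 5' end",
                           call. = FALSE)
  substr(tx, siteStart, siteEnd) <- revComp(trig)

  origin <- cleavage + 1L
  strands <- c("+", "-")
  occ <- matrix(runif(config@nRegisters * 2L) < config@occupancy,
                nrow = config@nRegisters, dimnames = list(NULL, strands))
  abund <- matrix(pmax(1, floor(rlnorm(config@nRegisters * 2L,
                                       meanlog = log(config@readsPerRegister),
                                       sdlog = config@abundanceSdlog))),
                  nrow = config@nRegisters, dimnames = list(NULL, strands))
  rows <- list()
  for (k in seq_len(config@nRegisters)) {
    sStart <- origin + (k - 1L) * p
    for (strand in strands) {
      if (!occ[k, strand]) next
      start <- if (strand == "+") sStart else sStart - config@antisenseOffset
      if (start < 1L) next
      end <- start + p - 1L
      seqk <- if (strand == "+") substr(tx, start, end) else
        revComp(substr(tx, start, end))
      rows[[length(rows) + 1L]] <- data.frame(
        read_sequence = seqk, transcript_id = transcriptId,
        start = start, end = end, strand = strand,
        count = as.integer(abund[k, strand]), is_noise = FALSE,
        register = k, stringsAsFactors = FALSE)
    }
  }
  phased <- if (length(rows)) do.call(rbind, rows) else NULL
  phasedMass <- if (is.null(phased)) 0L else sum(phased$count)
  noiseMass <- if (config@noiseFraction > 0 && phasedMass > 0)
    round(phasedMass * config@noiseFraction / (1 - config@noiseFraction)) else 0
  nrows <- list()
  for (i in seq_len(noiseMass)) {
    nl <- sample(20:22, 1)
    start <- sample.int(len - nl, 1)
    strand <- sample(strands, 1)
    end <- start + nl - 1L
    seqn <- if (strand == "+") substr(tx, start, end) else
      revComp(substr(tx, start, end))
    nrows[[i]] <- data.frame(
      read_sequence = seqn, transcript_id = transcriptId,
      start = start, end = end, strand = strand, count = 1L,
      is_noise = TRUE, register = NA_integer_, stringsAsFactors = FALSE)
  }
  alignments <- do.call(rbind, c(list(phased), nrows))
  if (is.null(alignments))
    alignments <- data.frame(read_sequence = character(),
                             transcript_id = character(), start = integer(),
                             end = integer(), strand = character(),
                             count = integer(), is_noise = logical(),
                             register = integer(), stringsAsFactors = FALSE)
  if (!nrow(alignments)) {
    return(list(transcript = setNames(tx, transcriptId),
                reads = data.frame(sequence = character(), count = integer(),
                                   library = character(),
                                   stringsAsFactors = FALSE),
                alignments = alignments, trigger = setNames(trig, "trigger"),
                truth = list(origin = origin, period = p, cleavage = cleavage,
                             occupancy = occ, abundance = abund,
                             site_start = siteStart, site_end = siteEnd,
                             phased_mass = 0L, noise_mass = 0L)))
  }
  reads <- stats::aggregate(count ~ sequence, data = data.frame(
    sequence = alignments$read_sequence, count = alignments$count,
    stringsAsFactors = FALSE), FUN = sum)
  reads$library <- "sim"
  reads <- reads[order(reads$sequence), c("sequence", "count", "library")]
  rownames(reads) <- NULL
  transcript <- setNames(tx, transcriptId)
  list(transcript = transcript, reads = reads, alignments = alignments,
       trigger = setNames(trig, "trigger"),
       truth = list(origin = origin, period = p, cleavage = cleavage,
                    occupancy = occ, abundance = abund,
                    site_start = siteStart, site_end = siteEnd,
                    phased_mass = phasedMass, noise_mass = noiseMass))
}

#' Simulate a degradome library
#'
#' Every transcript position draws a Poisson(`backgroundRate`) count; each
#' peak position additionally receives `degradomePeakFraction` of the total
#' tag mass (split equally among peaks; at least one tag per peak whenever
#' the fraction is positive).
#'
#' @param transcript named transcript sequence of length 1.
#' @param peaks integer vector of 1-based peak positions.
#' @param config a [SimulationConfig-class].
#' @return list with `signals` (data.frame `transcript_id`, `position`,
#'   `count`) and `truth` (peak positions and counts, background total).
#' @export
simulateDegradome <- function(transcript, peaks, config = simConfig()) {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  tid <- names(transcript)
  if (is.null(tid)) tid <- "transcript"
  len <- nchar(transcript)
  if (any(peaks < 1L | peaks > len))
    stop("peak positions outside the transcript", call. = FALSE)
  set.seed(config@seed)
  counts <- rpois(len, config@backgroundRate)
  f <- config@degradomePeakFraction
  peakEach <- 0L
  if (f > 0 && length(peaks)) {
    total <- round(f / (1 - f) * sum(counts))
    peakEach <- max(1L, as.integer(round(total / length(peaks))))
    counts[peaks] <- counts[peaks] + peakEach
  }
  pos <- which(counts > 0L)
  signals <- data.frame(transcript_id = rep(tid, length(pos)),
                        position = pos, count = counts[pos],
                        stringsAsFactors = FALSE)
  list(signals = signals,
       truth = list(peaks = peaks, peak_count = peakEach,
                    background_total = sum(counts) - peakEach * length(peaks)))
}

#' Simulate anticorrelated miRNA/target tissue profiles
#'
#' The miRNA is strictly ordered root > stem > flower > leaf; target means
#' are inversely proportional to the miRNA level with multiplicative
#' log-normal noise.
#'
#' @param nTargets number of target genes.
#' @param config a [SimulationConfig-class] (seed).
#' @param noiseSdlog log-normal sigma of the multiplicative noise (0 gives
#'   exactly reversed ranks).
#' @param tissues tissue names, ordered by decreasing miRNA abundance.
#' @return list with `mirna` (named counts per tissue), `targets` (matrix
#'   targets x tissues) and `truth` (the noise-free target means).
#' @export
simulateTissueProfiles <- function(nTargets, config = simConfig(),
                                   noiseSdlog = 0.25,
                                   tissues = c("root", "stem", "flower",
                                               "leaf")) {
  if (length(tissues) < 3L) stop("need at least 3 tissues", call. = FALSE)
  set.seed(config@seed)
  mirna <- setNames(round(1000 * 0.5^(seq_along(tissues) - 1L)), tissues)
  base <- 1e5 / mirna
  targets <- matrix(NA_real_, nrow = nTargets, ncol = length(tissues),
                    dimnames = list(paste0("target", seq_len(nTargets)),
                                    tissues))
  for (i in seq_len(nTargets)) {
    noise <- if (noiseSdlog > 0) rlnorm(length(tissues), 0, noiseSdlog) else 1
    targets[i, ] <- base * noise
  }
  list(mirna = mirna, targets = targets, truth = list(means = base))
}

#' Load a bundled locus preset
#'
#' Presets are JSON files under `inst/extdata/` that encode synthetic locus
#' geometries (period, register counts, occupancy) mirroring reported
#' phasiRNA-producing transcripts; the sequences they generate are synthetic.
#'
#' @param name preset name, e.g. `"smmterf33_synthetic"` or
#'   `"smmterf45_synthetic"`.
#' @param seed seed override (default: the preset's).
#' @return a [SimulationConfig-class].
#' @export
loadPreset <- function(name, seed = NULL) {
  path <- system.file("extdata", paste0(name, ".json"),
                      package = "phasiCascade")
  if (!nzchar(path)) stop("no such preset: ", name, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(seed)) cfg$seed <- seed
  do.call(simConfig, cfg[setdiff(names(cfg), c("name", "gene", "comment"))])
}
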