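## Phasing-locus detection. A read is in phase with register r (a residue
## class modulo the period) iff its length equals the period and its leftmost
## transcript coordinate is congruent to r (plus strand) or to r minus the
## Dicer antisense offset (minus strand); the offset folds sense and
## antisense reads of one duplex onto the same cycle.

## effective (sense-frame) start of each alignment
effectiveStart <- function(alignments, config) {
  ifelse(alignments$strand == "-",
         alignments$start + config@antisenseOffset,
         alignments$start)
}

#' Phase statistics of one window and register
#'
#' Counts, within the window `[windowStart, windowStart + period*cycles - 1]`,
#' the occupied in-phase cycle positions (`k`), the summed abundance of
#' in-phase reads (`P`), and the summed abundance of all other reads in the
#' window (`U`). A read is in phase iff its length equals the period and its
#' effective start is congruent to `register` modulo the period.
#'
#' @param alignments alignment data.frame from [mapReads()].
#' @param transcript named transcript sequence (used for bounds checking).
#' @param windowStart 1-based window start.
#' @param register integer residue class in `0..period-1` (sense frame).
#' @param config a [PhasingConfig-class].
#' @param period override of `config@period` (used by the period scan).
#' @return a [PhaseStatistics-class] (score and p-value unset).
#' @export
phaseStatistics <- function(alignments, transcript, windowStart, register,
                            config = phasingConfig(), period = config@period) {
  period <- as.integer(period)
  m <- period * config@cycles
  windowEnd <- windowStart + m - 1L
  if (windowStart < 1L || windowEnd > nchar(transcript))
    stop("window outside the transcript", call. = FALSE)
  if (!nrow(alignments))
    return(new("PhaseStatistics"))
  eff <- effectiveStart(alignments, config)
  len <- alignments$end - alignments$start + 1L
  inWin <- eff >= windowStart & eff <= windowEnd
  inPhase <- inWin & len == period & posMod(eff - register, period) == 0L
  cycles <- unique((eff[inPhase] - windowStart) %/% period)
  new("PhaseStatistics",
      k = length(cycles),
      P = sum(alignments$count[inPhase]),
      U = sum(alignments$count[inWin & !inPhase]))
}

#' Phasing score
#'
#' `score = ln[(1 + 10 P / (1 + U))^(k - 2)]` when at least
#' `minCyclesOccupied` cycles are occupied, else 0 (the PhaseTank/Howell
#' lineage of scores: abundance ratio of in-phase to out-of-phase reads,
#' amplified by the number of occupied cycles).
#'
#' @param stats a [PhaseStatistics-class].
#' @param config a [PhasingConfig-class].
#' @return numeric score (>= 0).
#' @examples
#' phasingScore(new("PhaseStatistics", k = 5L, P = 10, U = 0))  # 3 ln(101)
#' @export
phasingScore <- function(stats, config = phasingConfig()) {
  if (stats@k < config@minCyclesOccupied) return(0)
  max(0, (stats@k - 2) * log(1 + 10 * stats@P / (1 + stats@U)))
}

#' Hypergeometric register p-value
#'
#' Probability that at least `k` of `n` occupied 5'-end positions fall on the
#' `q = m / period` in-phase positions of a window of `m` positions, under
#' uniform placement without replacement.
#'
#' @param k observed in-phase occupied positions.
#' @param nOccupied total occupied positions in the window.
#' @param config a [PhasingConfig-class].
#' @param period,cycles overrides of the config values (the window has
#'   `m = period * cycles` positions, `q = cycles` of them in phase).
#' @return p-value in (0, 1].
#' @export
phasingPvalue <- function(k, nOccupied, config = phasingConfig(),
                          period = config@period, cycles = config@cycles) {
  m <- as.integer(period) * as.integer(cycles)
  q <- as.integer(cycles)
  if (nOccupied > m) stop("more occupied positions than window positions",
                          call. = FALSE)
  if (k > min(nOccupied, q)) stop("k cannot exceed min(nOccupied, q)",
                                  call. = FALSE)
  if (k == 0L) return(1.0)
  phyper(k - 1, q, m - q, nOccupied, lower.tail = FALSE)
}

#' Detect phased siRNA loci on a transcript
#'
#' Slides a window of `cycles` periods along the transcript in steps of one
#' period, for every candidate period in `config@scanPeriods` and every
#' register; windows whose best register scores at least `config@minScore`
#' are merged into loci when they overlap by at least one period. Because
#' each window tests one register per residue class, acceptance additionally
#' requires the hypergeometric register p-value to clear a Bonferroni bound
#' over the `period` registers tested (`period * pvalue <= maxPvalue`);
#' without this the score alone does not control the false-call rate on
#' unstructured libraries. Each locus
#' reports the period and register of its best-scoring window, the register
#' origin (start of sense register D1, the smallest occupied in-phase
#' effective start), and the statistics of the best window including the
#' hypergeometric p-value.
#'
#' @param alignments alignment data.frame from [mapReads()] (one transcript).
#' @param transcript named transcript sequence of length 1.
#' @param config a [PhasingConfig-class].
#' @return list of [PhasingLocus-class] objects, ordered by position.
#' @export
detectPhasingLoci <- function(alignments, transcript,
                              config = phasingConfig()) {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  tid <- names(transcript)
  if (is.null(tid)) tid <- "transcript"
  L <- nchar(transcript)
  if (!nrow(alignments)) return(list())
  eff <- effectiveStart(alignments, config)
  len <- alignments$end - alignments$start + 1L
  cnt <- alignments$count

  hits <- list()
  for (p in config@scanPeriods) {
    m <- p * config@cycles
    if (m > L) next
    isP <- len == p
    residue <- posMod(eff, p)
    for (ws in seq(1L, L - m + 1L, by = p)) {
      we <- ws + m - 1L
      inWin <- eff >= ws & eff <= we
      if (!any(inWin)) next
      totalMass <- sum(cnt[inWin])
      cand <- inWin & isP
      if (!any(cand)) next
      ## per-register aggregation in one pass
      regs <- sort(unique(residue[cand]))
      best <- NULL
      for (r in regs) {
        sel <- cand & residue == r
        k <- length(unique((eff[sel] - ws) %/% p))
        P <- sum(cnt[sel])
        st <- new("PhaseStatistics", k = as.integer(k), P = P,
                  U = totalMass - P)
        sc <- phasingScore(st, config)
        if (is.null(best) || sc > best$score ||
            (sc == best$score && (P > best$P ||
                                  (P == best$P && r < best$register)))) {
          best <- list(register = r, score = sc, stats = st, P = P)
        }
      }
      if (best$score >= config@minScore) {
        nOcc <- length(unique(eff[inWin]))
        pv <- phasingPvalue(best$stats@k, min(nOcc, m), config, period = p)
        ## Bonferroni over the p registers tested in this window: the score
        ## alone does not control the false-call rate on random reads
        if (pv * p <= config@maxPvalue) {
          hits[[length(hits) + 1L]] <- list(
            period = p, ws = ws, we = we, register = best$register,
            score = best$score, stats = best$stats, pvalue = pv,
            nOccupied = nOcc)
        }
      }
    }
  }
  if (!length(hits)) return(list())

  ## merge hit windows overlapping by >= one period (of the smaller window)
  ord <- order(vapply(hits, function(h) h$ws, integer(1)))
  hits <- hits[ord]
  groups <- list()
  cur <- list(hits[[1]])
  curEnd <- hits[[1]]$we
  for (h in hits[-1]) {
    minP <- min(h$period, vapply(cur, function(x) x$period, integer(1)))
    if (h$ws <= curEnd - minP + 1L) {
      cur[[length(cur) + 1L]] <- h
      curEnd <- max(curEnd, h$we)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- list(h)
      curEnd <- h$we
    }
  }
  groups[[length(groups) + 1L]] <- cur

  loci <- list()
  for (g in groups) {
    scores <- vapply(g, function(h) h$score, numeric(1))
    bh <- g[[which.max(scores)]]
    p <- bh$period
    ## register origin: smallest in-phase effective start across the merged
    ## windows for the best period/register
    gs <- min(vapply(g, function(h) h$ws, integer(1)))
    ge <- max(vapply(g, function(h) h$we, integer(1)))
    sel <- len == p & posMod(eff, p) == bh$register & eff >= gs & eff <= ge
    if (!any(sel)) next
    origin <- min(eff[sel])
    end <- max(eff[sel]) + p - 1L
    stats <- bh$stats
    stats@score <- bh$score
    stats@pvalue <- bh$pvalue
    loci[[length(loci) + 1L]] <- new("PhasingLocus",
      transcriptId = tid, start = as.integer(origin), end = as.integer(end),
      period = as.integer(p), registerOrigin = as.integer(origin),
      statistics = stats)
  }
  loci[order(vapply(loci, function(l) l@start, integer(1)))]
}

#' Enumerate and name the phasiRNA species of a locus
#'
#' Enumerates ALL registers D1..Dmax on both strands between the register
#' origin and the locus end (`Dmax = floor((end - origin + 1) / period)`),
#' whether or not a matching read was sequenced: registers absent from the
#' library are reported with abundance 0. Sense register k spans
#' `[origin + (k-1) period, origin + k period - 1]`; the antisense register
#' spans the same interval shifted upstream by the Dicer offset and its
#' sequence is the reverse complement. Names follow the
#' `{gene}-siRD{k}({+|-})` convention.
#'
#' @param locus a [PhasingLocus-class] with a register origin.
#' @param geneName gene name used in the species names.
#' @param alignments alignment data.frame used to attach observed abundances.
#' @param transcript named transcript sequence (for the species sequences).
#' @param config a [PhasingConfig-class] (for the antisense offset).
#' @return data.frame with columns `name`, `strand`, `register`, `start`,
#'   `end`, `abundance`, `sequence`.
#' @export
enumerateRegisters <- function(locus, geneName, alignments, transcript,
                               config = phasingConfig()) {
  stopifnot(is(locus, "PhasingLocus"))
  if (is.na(locus@registerOrigin))
    stop("locus has no register origin", call. = FALSE)
  p <- locus@period
  origin <- locus@registerOrigin
  dmax <- (locus@end - origin + 1L) %/% p
  if (dmax < 1L) stop("locus shorter than one period", call. = FALSE)
  tx <- unname(transcript[1])
  abundanceAt <- function(start, strand) {
    sel <- alignments$strand == strand & alignments$start == start &
      (alignments$end - alignments$start + 1L) == p
    sum(alignments$count[sel])
  }
  rows <- vector("list", 2L * dmax)
  for (k in seq_len(dmax)) {
    sStart <- origin + (k - 1L) * p
    sEnd <- sStart + p - 1L
    aStart <- sStart - config@antisenseOffset
    aEnd <- sEnd - config@antisenseOffset
    rows[[2L * k - 1L]] <- data.frame(
      name = sprintf("%s-siRD%d(+)", geneName, k), strand = "+",
      register = k, start = sStart, end = sEnd,
      abundance = abundanceAt(sStart, "+"),
      sequence = substr(tx, sStart, sEnd), stringsAsFactors = FALSE)
    rows[[2L * k]] <- data.frame(
      name = sprintf("%s-siRD%d(-)", geneName, k), strand = "-",
      register = k, start = aStart, end = aEnd,
      abundance = if (aStart >= 1L) abundanceAt(aStart, "-") else 0L,
      sequence = if (aStart >= 1L) revComp(substr(tx, aStart, aEnd)) else "",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
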