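## Expectation-scored target prediction. The scoring follows the penalty
## scheme used for plant miRNA target prediction: mismatch 1, G:U wobble 0.5,
## affine gap penalties, and all penalties doubled at sRNA positions 2-13
## (the seed region). Lower expectation = better complementarity; sites with
## expectation <= maxExpectation are reported.

schemeAsList <- function(scheme) {
  list(mismatch_penalty = scheme@mismatchPenalty,
       wobble_penalty = scheme@wobblePenalty,
       gap_open_penalty = scheme@gapOpenPenalty,
       gap_extend_penalty = scheme@gapExtendPenalty,
       seed_multiplier = scheme@seedMultiplier,
       seed_start = scheme@seedStart, seed_end = scheme@seedEnd,
       max_bulges = scheme@maxBulges)
}

stateLabels <- c("pair", "wobble", "mismatch", "srna_bulge", "target_bulge")

#' Score an sRNA against one target window
#'
#' Computes the optimal (minimum-expectation) antiparallel duplex alignment
#' of the small RNA (5'->3') against the transcript window. sRNA position 1
#' pairs the window's last base (the site end). G:U pairs count as wobbles;
#' penalties at seed positions are multiplied by the scheme's seed
#' multiplier; at most `maxBulges` bulge (gap) events are allowed.
#'
#' @param srna small RNA sequence (5'->3', A/C/G/T/U).
#' @param targetWindow transcript window sequence (sense strand); its length
#'   must be within `maxBulges` nt of the sRNA length and at least 10 nt.
#' @param scheme a [ScoringScheme-class].
#' @param transcriptId,siteStart optional annotation carried into the result;
#'   `siteStart` is the 1-based transcript coordinate of the window start.
#' @return a [DuplexAlignment-class].
#' @examples
#' s <- "UGGAGCUCCCUUCAUUCCAAU"
#' scoreDuplex(s, revComp(s))@expectation   # 0: perfect complement
#' @export
scoreDuplex <- function(srna, targetWindow, scheme = scoringScheme(),
                        transcriptId = "target", siteStart = 1L) {
  checkNucleotides(srna, "sRNA")
  checkNucleotides(targetWindow, "target window")
  if (nchar(targetWindow) < 10L)
    stop("target window shorter than 10 nt", call. = FALSE)
  if (abs(nchar(targetWindow) - nchar(srna)) > scheme@maxBulges)
    stop("window length must be within maxBulges (", scheme@maxBulges,
         ") nt of the sRNA length", call. = FALSE)
  r <- .duplex_align_cpp(asDna(srna), asDna(targetWindow), schemeAsList(scheme))
  siteStart <- as.integer(siteStart)
  tpos <- ifelse(is.na(r$window_pos), NA_integer_,
                 siteStart + r$window_pos - 1L)
  new("DuplexAlignment",
      srna = toupper(srna), transcriptId = transcriptId,
      siteStart = siteStart,
      siteEnd = siteStart + nchar(targetWindow) - 1L,
      states = stateLabels[r$state + 1L],
      srnaPositions = as.integer(r$srna_pos),
      targetPositions = as.integer(tpos),
      expectation = r$expectation)
}

#' Predict target sites of an sRNA on transcripts
#'
#' Scans every window whose length is within `maxBulges` nt of the sRNA
#' length, keeps windows with optimal expectation at most
#' `scheme@maxExpectation`, and collapses overlapping windows to the local
#' best (ties broken toward the smallest start coordinate). The predicted
#' cleavage position is the transcript base paired with sRNA position 10.
#'
#' @param srna small RNA sequence (5'->3'), optionally named (the name is
#'   used as `srna_id`).
#' @param transcripts named character vector of transcript sequences.
#' @param scheme a [ScoringScheme-class].
#' @return data.frame with columns `srna_id`, `transcript_id`, `start`,
#'   `end`, `expectation`, `predicted_cleavage`, `cleavage_flagged`, sorted
#'   by expectation then transcript and position. Zero rows when nothing
#'   scores below the threshold.
#' @export
predictTargets <- function(srna, transcripts, scheme = scoringScheme()) {
  srnaId <- if (!is.null(names(srna)) && nzchar(names(srna)[1])) names(srna)[1] else "sRNA"
  srna <- unname(srna)
  checkNucleotides(srna, "sRNA")
  stopifnot(is.character(transcripts), !is.null(names(transcripts)))
  empty <- data.frame(srna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), predicted_cleavage = integer(),
                      cleavage_flagged = logical(), stringsAsFactors = FALSE)
  rows <- list()
  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    if (nchar(tx) < 10L) next
    cand <- .duplex_scan_cpp(asDna(srna), asDna(tx), schemeAsList(scheme))
    cand <- cand[cand$expectation <= scheme@maxExpectation + 1e-9, , drop = FALSE]
    if (!nrow(cand)) next
    ## collapse overlapping windows to the local best; ties -> smallest start
    cand <- cand[order(cand$expectation, cand$start), , drop = FALSE]
    keep <- logical(nrow(cand))
    taken <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (nrow(taken) == 0 ||
          all(e < taken[, 1] | s > taken[, 2])) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(s, e))
      }
    }
    cand <- cand[keep, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      dup <- scoreDuplex(srna, substr(tx, cand$start[i], cand$end[i]), scheme,
                         transcriptId = tid, siteStart = cand$start[i])
      cl <- predictedCleavage(dup)
      rows[[length(rows) + 1L]] <- data.frame(
        srna_id = srnaId, transcript_id = tid,
        start = cand$start[i], end = cand$end[i],
        expectation = cand$expectation[i],
        predicted_cleavage = cl,
        cleavage_flagged = isTRUE(attr(cl, "flagged")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$expectation, res$transcript_id, res$start), ]
  rownames(res) <- NULL
  res
}

#' Predicted cleavage position of a duplex
#'
#' Plant miRNA-guided cleavage occurs between sRNA positions 10 and 11; the
#' reported position is the transcript base paired with sRNA position 10
#' (`siteEnd - 9` for a gap-free duplex), i.e. the expected 5' end of the 3'
#' cleavage fragment as seen in degradome data. If sRNA position 10 is bulged
#' the nearest paired target base is returned with attribute `flagged =
#' TRUE`.
#'
#' @param duplex a [DuplexAlignment-class].
#' @return integer transcript position (possibly with attribute `flagged`).
#' @export
predictedCleavage <- function(duplex) {
  stopifnot(is(duplex, "DuplexAlignment"))
  aligned <- !is.na(duplex@srnaPositions) &
    duplex@states %in% c("pair", "wobble", "mismatch")
  if (sum(aligned) < 10L)
    stop("duplex has fewer than 10 paired or mismatched sRNA positions",
         call. = FALSE)
  at10 <- which(!is.na(duplex@srnaPositions) & duplex@srnaPositions == 10L)
  if (!length(at10))
    stop("sRNA position 10 absent from the alignment", call. = FALSE)
  pos <- duplex@targetPositions[at10[1]]
  if (!is.na(pos)) return(as.integer(pos))
  ## sRNA position 10 is bulged: nearest paired target base, flagged
  paired <- which(!is.na(duplex@targetPositions) & aligned)
  nearest <- paired[which.min(abs(paired - at10[1]))]
  out <- as.integer(duplex@targetPositions[nearest])
  attr(out, "flagged") <- TRUE
  out
}
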