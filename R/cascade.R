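## Cascade inference: which sRNA triggered a phasing locus, and the
## miRNA -> phasiRNA -> target network.

#' Infer candidate triggers of a phasing locus
#'
#' For each sRNA in the pool with a predicted target site on the locus
#' transcript (expectation at most the scheme threshold), computes the
#' predicted cleavage position and tests whether register D1 of the locus
#' starts one base downstream of it: `register_match` is TRUE iff
#' `cleavage + 1` is congruent with the register origin modulo the locus
#' period within `tolerance` nt. Hypotheses are sorted by register match
#' (matches first), then ascending expectation.
#'
#' @param locus a [PhasingLocus-class].
#' @param srnaPool named character vector of candidate trigger sequences
#'   (miRNAs and enumerated phasiRNAs; names are ids).
#' @param transcripts named character vector including the locus transcript.
#' @param scheme a [ScoringScheme-class].
#' @param tolerance register-coincidence tolerance in nt (default 1).
#' @return data.frame with columns `srna_id`, `transcript_id`, `site_start`,
#'   `site_end`, `expectation`, `cleavage`, `register_offset`,
#'   `register_match`, `trigger_length`.
#' @export
inferTriggers <- function(locus, srnaPool, transcripts,
                          scheme = scoringScheme(), tolerance = 1L) {
  stopifnot(is(locus, "PhasingLocus"))
  empty <- data.frame(srna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), cleavage = integer(),
                      register_offset = integer(), register_match = logical(),
                      trigger_length = integer(), stringsAsFactors = FALSE)
  if (!length(srnaPool)) return(empty)
  tid <- locus@transcriptId
  if (!tid %in% names(transcripts))
    stop("locus transcript ", tid, " absent from transcripts", call. = FALSE)
  tx <- transcripts[tid]
  rows <- list()
  for (i in seq_along(srnaPool)) {
    id <- names(srnaPool)[i]
    sites <- predictTargets(setNames(srnaPool[[i]], id), tx, scheme)
    for (j in seq_len(nrow(sites))) {
      cl <- sites$predicted_cleavage[j]
      off <- modDistance(cl + 1L - locus@registerOrigin, locus@period)
      rows[[length(rows) + 1L]] <- data.frame(
        srna_id = id, transcript_id = tid,
        site_start = sites$start[j], site_end = sites$end[j],
        expectation = sites$expectation[j], cleavage = cl,
        register_offset = off, register_match = off <= tolerance,
        trigger_length = nchar(srnaPool[[i]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(!res$register_match, res$expectation, res$srna_id), ]
  rownames(res) <- NULL
  res
}

#' Assemble the cascade network
#'
#' Nodes are sRNAs (miRNAs and phasiRNAs) and transcripts. A `cleaves` edge
#' connects an sRNA to a transcript it targets (evidence `degradome` or
#' `race` when a validated cleavage record exists, else `predicted`); a
#' `produces` edge connects a transcript to each phasiRNA enumerated from a
#' locus on it. Self-cleavage (a transcript's own phasiRNA targeting it) is
#' permitted. Rows are ordered deterministically by (source, target, kind).
#'
#' @param sites target-site data.frame from [predictTargets()] (rows for all
#'   sRNAs, with `srna_id`).
#' @param evidences optional cleavage-evidence data.frame from
#'   [validateCleavage()] rows (needs `srna_id`, `transcript_id`,
#'   `validated`; an `evidence` column may name the library, e.g. `race`).
#' @param loci list of [PhasingLocus-class] objects.
#' @param phasiRNAs data.frame of enumerated species with a `name` column and
#'   a `transcript_id` column naming the source transcript.
#' @return data.frame with columns `source`, `target`, `kind`, `evidence`,
#'   `expectation`, `position`.
#' @export
buildCascadeNetwork <- function(sites, evidences = NULL, loci = list(),
                                phasiRNAs = NULL) {
  edges <- list()
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      ev <- "predicted"
      if (!is.null(evidences) && nrow(evidences)) {
        hit <- evidences$srna_id == sites$srna_id[i] &
          evidences$transcript_id == sites$transcript_id[i] &
          evidences$validated
        if (any(hit)) {
          ev <- if (!is.null(evidences$evidence))
            evidences$evidence[which(hit)[1]] else "degradome"
        }
      }
      edges[[length(edges) + 1L]] <- data.frame(
        source = sites$srna_id[i], target = sites$transcript_id[i],
        kind = "cleaves", evidence = ev,
        expectation = sites$expectation[i],
        position = sites$predicted_cleavage[i], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(phasiRNAs) && nrow(phasiRNAs)) {
    if (is.null(phasiRNAs$transcript_id))
      stop("phasiRNAs need a transcript_id column", call. = FALSE)
    lociTx <- vapply(loci, function(l) l@transcriptId, character(1))
    dangling <- setdiff(unique(phasiRNAs$transcript_id), lociTx)
    if (length(dangling))
      stop("phasiRNAs reference transcripts with no detected locus: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(phasiRNAs))) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = phasiRNAs$transcript_id[i], target = phasiRNAs$name[i],
        kind = "produces", evidence = "phasing",
        expectation = NA_real_, position = phasiRNAs$start[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(source = character(), target = character(),
                      kind = character(), evidence = character(),
                      expectation = numeric(), position = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, edges)
  res <- res[order(res$source, res$target, res$kind), ]
  rownames(res) <- NULL
  res
}
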