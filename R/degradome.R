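## Degradome (PARE) analysis: per-transcript t-plots, the standard five-level
## cleavage category scheme, and validation of predicted cleavage sites.

#' Build a per-transcript degradome t-plot
#'
#' @param signals data.frame with columns `transcript_id`, `position`,
#'   `count` (see [readDegradomeTable()]).
#' @param transcript a single named transcript sequence (named character of
#'   length 1), or an unnamed sequence plus `transcriptId`.
#' @param transcriptId transcript id; defaults to the name of `transcript`.
#' @return list with `transcript_id` and `counts`, an integer vector of 5'
#'   end counts indexed by 1-based transcript position.
#' @export
buildTplot <- function(signals, transcript, transcriptId = names(transcript)) {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  if (is.null(transcriptId)) stop("transcriptId is required", call. = FALSE)
  len <- nchar(transcript)
  counts <- integer(len)
  sig <- signals[signals$transcript_id == transcriptId, , drop = FALSE]
  if (nrow(sig)) {
    bad <- sig$position < 1L | sig$position > len
    if (any(bad))
      stop("degradome position out of range on ", transcriptId, ": ",
           paste(sig$position[bad], collapse = ", "), call. = FALSE)
    tab <- tapply(sig$count, sig$position, sum)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  list(transcript_id = transcriptId, counts = counts)
}

#' Assign the PARE cleavage category of a position
#'
#' Standard five-level scheme: category 0 - count > 1 and equal to the unique
#' transcript maximum; 1 - count > 1 and equal to a shared maximum; 2 -
#' count > 1, below the maximum but above the median of nonzero counts; 3 -
#' count > 1, at or below that median; 4 - count equal to 1.
#'
#' @param tplot a t-plot from [buildTplot()].
#' @param position 1-based transcript position with count >= 1.
#' @return integer category in 0..4.
#' @export
categorizePosition <- function(tplot, position) {
  counts <- tplot$counts
  stopifnot(position >= 1L, position <= length(counts))
  cnt <- counts[position]
  if (cnt == 0L) stop("no degradome signal at position ", position, call. = FALSE)
  if (cnt == 1L) return(4L)
  mx <- max(counts)
  if (cnt == mx) {
    if (sum(counts == mx) == 1L) return(0L) else return(1L)
  }
  med <- median(counts[counts > 0L])
  if (cnt > med) 2L else 3L
}

#' Validate a predicted cleavage site against the degradome
#'
#' Examines positions within `tolerance` nt of the predicted cleavage
#' position, picks the one with the highest count (ties broken toward the
#' predicted position), assigns its category, and calls the site validated
#' iff the category is at most `categoryMax`.
#'
#' @param site one row of a [predictTargets()] table (needs
#'   `predicted_cleavage`; `srna_id`/`transcript_id` are carried through), or
#'   a single integer position.
#' @param tplot a t-plot from [buildTplot()].
#' @param tolerance window half-width in nt (default 1).
#' @param categoryMax maximum category accepted as validated (default 2).
#' @return one-row data.frame with `predicted`, `observed`, `count`,
#'   `category`, `offset_from_predicted`, `validated` (plus `srna_id` and
#'   `transcript_id` when present in `site`).
#' @export
validateCleavage <- function(site, tplot, tolerance = 1L, categoryMax = 2L) {
  predicted <- if (is.numeric(site)) as.integer(site) else
    as.integer(site$predicted_cleavage)
  counts <- tplot$counts
  if (predicted < 1L || predicted > length(counts))
    stop("predicted cleavage position outside the transcript", call. = FALSE)
  win <- max(1L, predicted - tolerance):min(length(counts), predicted + tolerance)
  res <- data.frame(predicted = predicted, observed = NA_integer_,
                    count = 0L, category = NA_integer_,
                    offset_from_predicted = NA_integer_, validated = FALSE,
                    stringsAsFactors = FALSE)
  if (any(counts[win] > 0L)) {
    ## highest count; ties toward the smallest |offset|, then smallest position
    ord <- order(-counts[win], abs(win - predicted), win)
    best <- win[ord[1]]
    res$observed <- best
    res$count <- counts[best]
    res$category <- categorizePosition(tplot, best)
    res$offset_from_predicted <- best - predicted
    res$validated <- res$category <= categoryMax
  }
  if (is.data.frame(site)) {
    extras <- list()
    if (!is.null(site$srna_id)) extras$srna_id <- site$srna_id[1]
    if (!is.null(site$transcript_id))
      extras$transcript_id <- site$transcript_id[1]
    if (length(extras))
      res <- cbind(as.data.frame(extras, stringsAsFactors = FALSE), res)
  }
  rownames(res) <- NULL
  res
}
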