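## Abundance normalisation (RPM for small RNA, TPM for transcripts), relative
## qPCR quantification, and miRNA/target anticorrelation across tissues.

#' Reads per million
#'
#' @param counts named numeric vector of per-feature read counts for one
#'   library.
#' @return named numeric vector; values sum to 1e6.
#' @examples
#' rpm(c(a = 2, b = 8))
#' @export
rpm <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("library total must be > 0", call. = FALSE)
  counts / total * 1e6
}

#' Transcripts per million
#'
#' @param counts named numeric vector of per-gene counts.
#' @param lengthsKb gene lengths in kilobases (same names/order).
#' @return named numeric vector; values sum to 1e6.
#' @examples
#' tpm(c(a = 10, b = 10), c(a = 1, b = 2))
#' @export
tpm <- function(counts, lengthsKb) {
  stopifnot(length(counts) == length(lengthsKb))
  if (any(lengthsKb <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  rate <- counts / lengthsKb
  total <- sum(rate)
  if (total <= 0) stop("library total must be > 0", call. = FALSE)
  rate / total * 1e6
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (ctTargetSample - ctRefSample) - (ctTargetCalibrator -
#' ctRefCalibrator)`; the fold change is `2^-ddCt`.
#'
#' @param ctTargetSample,ctRefSample Ct of the target and reference gene in
#'   the sample.
#' @param ctTargetCalibrator,ctRefCalibrator Ct of the target and reference
#'   gene in the calibrator.
#' @return numeric fold change.
#' @examples
#' ddct(25, 20, 27, 20)  # 4
#' @export
ddct <- function(ctTargetSample, ctRefSample, ctTargetCalibrator,
                 ctRefCalibrator) {
  stopifnot(is.finite(c(ctTargetSample, ctRefSample, ctTargetCalibrator,
                        ctRefCalibrator)))
  dd <- (ctTargetSample - ctRefSample) - (ctTargetCalibrator - ctRefCalibrator)
  2^(-dd)
}

#' Rank anticorrelation of a miRNA with its targets across tissues
#'
#' Spearman rank correlation (average ranks for ties) of the miRNA profile
#' against each target profile. A negative correlation supports
#' miRNA-directed repression. Constant profiles yield NA and are flagged.
#'
#' @param mirnaProfile named numeric vector of miRNA abundance per tissue.
#' @param targetProfiles matrix or data.frame, targets x tissues (columns
#'   matching `mirnaProfile` names), or a single numeric vector.
#' @return data.frame with columns `target`, `rho`, `flagged_constant`.
#' @export
anticorrelation <- function(mirnaProfile, targetProfiles) {
  if (length(mirnaProfile) < 3L)
    stop("need at least 3 tissues", call. = FALSE)
  if (is.vector(targetProfiles))
    targetProfiles <- matrix(targetProfiles, nrow = 1,
                             dimnames = list("target", names(targetProfiles)))
  targetProfiles <- as.matrix(targetProfiles)
  if (!is.null(colnames(targetProfiles)) && !is.null(names(mirnaProfile)))
    targetProfiles <- targetProfiles[, names(mirnaProfile), drop = FALSE]
  res <- data.frame(
    target = if (!is.null(rownames(targetProfiles)))
      rownames(targetProfiles) else paste0("target", seq_len(nrow(targetProfiles))),
    rho = NA_real_, flagged_constant = FALSE, stringsAsFactors = FALSE)
  constantMi <- length(unique(mirnaProfile)) == 1L
  for (i in seq_len(nrow(targetProfiles))) {
    v <- targetProfiles[i, ]
    if (constantMi || length(unique(v)) == 1L) {
      res$flagged_constant[i] <- TRUE
    } else {
      res$rho[i] <- suppressWarnings(
        cor(mirnaProfile, v, method = "spearman"))
    }
  }
  res
}
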