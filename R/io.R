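## Readers and writers for the external formats, and transcript-level read
## mapping. Transcripts are represented as a named character vector (names =
## unique ids, values = uppercase nucleotide sequences); small RNA libraries,
## degradome libraries and alignments are plain data.frames. Coordinates are
## 1-based inclusive throughout.

#' Read transcript or precursor sequences from FASTA
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences; T/U are kept as
#'   given (matching elsewhere is T/U-agnostic).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGU"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence ids in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  checkNucleotides(seqs, "FASTA sequence")
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

readTsv <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table ", path, " lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

checkIntegerColumn <- function(x, col, what) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad))
    stop(what, ": non-integer ", col, " at row ", bad[1], call. = FALSE)
  as.integer(v)
}

#' Read a small RNA library table
#'
#' Expects a TSV with a header line and columns `sequence`, `count` and
#' optionally `library`. Duplicate sequences within a library are aggregated
#' by summing counts. Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sequence`, `count`, `library`.
#' @export
readSrnaTable <- function(path) {
  df <- readTsv(path, c("sequence", "count"), "small RNA")
  if (nrow(df) == 0L)
    return(data.frame(sequence = character(), count = integer(),
                      library = character(), stringsAsFactors = FALSE))
  df$count <- checkIntegerColumn(df$count, "count", "small RNA table")
  if (any(df$count < 0L)) stop("negative count in small RNA table", call. = FALSE)
  if (is.null(df$library)) df$library <- "default"
  checkNucleotides(df$sequence, "small RNA sequence")
  df$sequence <- toupper(df$sequence)
  agg <- stats::aggregate(count ~ sequence + library, data = df, FUN = sum)
  agg <- agg[order(agg$library, agg$sequence), c("sequence", "count", "library")]
  rownames(agg) <- NULL
  agg
}

#' Write a small RNA library table
#'
#' @param reads data.frame with columns `sequence`, `count`, `library`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSrnaTable <- function(reads, path) {
  write.table(reads[, c("sequence", "count", "library")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a degradome library table
#'
#' Expects a TSV with columns `transcript_id`, `position` (1-based 5' end of
#' the degradome tag) and `count`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `transcript_id`, `position`, `count`.
#' @export
readDegradomeTable <- function(path) {
  df <- readTsv(path, c("transcript_id", "position", "count"), "degradome")
  if (nrow(df) == 0L)
    return(data.frame(transcript_id = character(), position = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  df$position <- checkIntegerColumn(df$position, "position", "degradome table")
  df$count <- checkIntegerColumn(df$count, "count", "degradome table")
  if (any(df$position < 1L)) stop("degradome position must be >= 1", call. = FALSE)
  if (any(df$count < 1L)) stop("degradome count must be >= 1", call. = FALSE)
  df[, c("transcript_id", "position", "count")]
}

#' Write a degradome library table
#'
#' @param signals data.frame with columns `transcript_id`, `position`,
#'   `count`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDegradomeTable <- function(signals, path) {
  write.table(signals[, c("transcript_id", "position", "count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map small RNA reads to transcripts
#'
#' Reports every occurrence of each read on either strand of each transcript
#' (all placements of multi-mapping reads are kept). Matching is T/U-agnostic.
#' A minus-strand alignment means the read matches the reverse complement of
#' the transcript interval.
#'
#' @param reads data.frame with columns `sequence`, `count` (and optionally
#'   `library`), or a character vector of sequences (count 1 each).
#' @param transcripts named character vector of transcript sequences.
#' @param maxMismatches maximum number of mismatches (default 0, exact).
#' @return data.frame with columns `read_sequence`, `transcript_id`, `start`,
#'   `end`, `strand`, `count`. Coordinates 1-based inclusive; `end - start +
#'   1` equals the read length.
#' @examples
#' tx <- c(t1 = "AAAACGTACGTACGTAAAA")
#' mapReads(data.frame(sequence = "ACGTACGT", count = 3), tx)
#' @export
mapReads <- function(reads, transcripts, maxMismatches = 0L) {
  if (is.character(reads))
    reads <- data.frame(sequence = reads, count = 1L, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  empty <- data.frame(read_sequence = character(), transcript_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L || length(transcripts) == 0L) return(empty)
  subjects <- lapply(transcripts, function(s) Biostrings::DNAString(asDna(s)))
  out <- vector("list", nrow(reads) * length(transcripts) * 2L)
  n <- 0L
  for (r in seq_len(nrow(reads))) {
    seq <- reads$sequence[r]
    pat <- Biostrings::DNAString(asDna(seq))
    patRc <- Biostrings::reverseComplement(pat)
    for (t in seq_along(subjects)) {
      tid <- names(transcripts)[t]
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else patRc
        hits <- Biostrings::matchPattern(p, subjects[[t]],
                                         max.mismatch = maxMismatches)
        if (length(hits)) {
          n <- n + 1L
          out[[n]] <- data.frame(
            read_sequence = seq, transcript_id = tid,
            start = Biostrings::start(hits), end = Biostrings::end(hits),
            strand = strand, count = reads$count[r],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (n == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(n)])
  res <- res[order(res$transcript_id, res$start, res$strand, res$read_sequence), ]
  rownames(res) <- NULL
  res
}

#' Read hairpin candidates from an extended-FASTA triplet file
#'
#' Each record is three lines after the `>id` header: the sequence, the
#' dot-bracket structure, and a line `MFE=<float>`. Arm intervals are read
#' from the header as `mature=start-end star=start-end`.
#'
#' @param path path to the file.
#' @return named list of [HairpinCandidate-class] objects.
#' @export
readHairpinFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no records in hairpin file ", path, call. = FALSE)
  out <- list()
  for (h in heads) {
    if (h + 3L > length(lines))
      stop("truncated hairpin record at line ", h, call. = FALSE)
    header <- sub("^>", "", lines[h])
    id <- sub("\\s.*$", "", header)
    getIv <- function(key) {
      m <- regmatches(header, regexec(paste0(key, "=(\\d+)-(\\d+)"), header))[[1]]
      if (length(m) != 3L)
        stop("hairpin record '", id, "' lacks ", key, "=start-end", call. = FALSE)
      as.integer(m[2:3])
    }
    mat <- getIv("mature"); star <- getIv("star")
    mfeLine <- lines[h + 3L]
    if (!grepl("^MFE=", mfeLine))
      stop("hairpin record '", id, "' lacks an MFE= line", call. = FALSE)
    out[[id]] <- hairpinCandidate(
      sequence = lines[h + 1L], dotbracket = lines[h + 2L],
      mfe = as.numeric(sub("^MFE=", "", mfeLine)),
      matureStart = mat[1], matureEnd = mat[2],
      starStart = star[1], starEnd = star[2])
  }
  out
}

#' Convert detected loci to GRanges / export as GFF3
#'
#' `lociToGRanges()` builds a `GRanges` (type `phased_siRNA_locus`) from a
#' list of [PhasingLocus-class] objects; `exportLociGff3()` writes it as GFF3
#' (1-based inclusive, lossless round trip via `rtracklayer`).
#'
#' @param loci list of [PhasingLocus-class] objects.
#' @return a `GRanges` object.
#' @export
lociToGRanges <- function(loci) {
  if (!length(loci)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = vapply(loci, function(l) l@transcriptId, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(loci, function(l) l@start, integer(1)),
      end = vapply(loci, function(l) l@end, integer(1))),
    strand = "+",
    type = "phased_siRNA_locus",
    period = vapply(loci, function(l) l@period, integer(1)),
    register_origin = vapply(loci, function(l) l@registerOrigin, integer(1)),
    score = vapply(loci, function(l) l@statistics@score, numeric(1)))
}

#' @rdname lociToGRanges
#' @param path output GFF3 path.
#' @export
exportLociGff3 <- function(loci, path) {
  rtracklayer::export(lociToGRanges(loci), path, format = "gff3")
  invisible(path)
}

#' Convert a target-site table to GRanges / export as GFF3
#'
#' @param sites data.frame as returned by [predictTargets()].
#' @return a `GRanges` (type `sRNA_target_site`).
#' @export
sitesToGRanges <- function(sites) {
  if (!nrow(sites)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = sites$transcript_id,
    ranges = IRanges::IRanges(start = sites$start, end = sites$end),
    strand = "+",
    type = "sRNA_target_site",
    srna_id = sites$srna_id,
    expectation = sites$expectation,
    predicted_cleavage = sites$predicted_cleavage)
}

#' @rdname sitesToGRanges
#' @param path output GFF3 path.
#' @export
exportSitesGff3 <- function(sites, path) {
  rtracklayer::export(sitesToGRanges(sites), path, format = "gff3")
  invisible(path)
}
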