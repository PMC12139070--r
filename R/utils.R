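## Shared sequence helpers. Sequences are stored as the user supplied them
## (DNA or RNA alphabet); all comparisons are T/U-agnostic via asDna().

#' Reverse complement of a nucleotide string
#'
#' T and U are treated as the same base. The output uses the alphabet of the
#' input: if the input contains U (and no T) the complement is written with U.
#'
#' @param x character vector of nucleotide strings (A, C, G, T/U).
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGU")
#' revComp("acgt")
#' @export
revComp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    isRna <- grepl("U", toupper(s), fixed = TRUE) &&
      !grepl("T", toupper(s), fixed = TRUE)
    comp <- chartr("ACGTU", "TGCAA", toupper(s))
    out <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
    if (isRna) chartr("T", "U", out) else out
  }, character(1), USE.NAMES = FALSE)
}

## uppercase, U -> T: the canonical alphabet used for all matching
asDna <- function(x) chartr("U", "T", toupper(x))

checkNucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTUacgtu]", x)
  if (any(bad)) {
    stop(what, " contains non-nucleotide characters: ",
         paste(unique(substr(x[bad], 1, 30)), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

## mod that returns values in 0..(p-1) (R's %% already does, kept for clarity)
posMod <- function(x, p) ((x %% p) + p) %% p

## circular distance of residue x from 0 modulo p
modDistance <- function(x, p) {
  r <- posMod(x, p)
  pmin(r, p - r)
}
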