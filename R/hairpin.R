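## Precursor validation: MFEI/AMFE arithmetic, miRNA/miRNA* duplex geometry
## from the dot-bracket structure, the five annotation criteria, and an
## explicit approximate fold for structure-free test fixtures.

#' GC percentage, AMFE and MFEI of a precursor
#'
#' AMFE is the magnitude of the folding free energy per 100 nt; MFEI divides
#' AMFE by the GC percentage. MFEI >= 0.85 discriminates miRNA precursors
#' from other non-coding RNA hairpins.
#'
#' @param sequence precursor sequence.
#' @param mfe minimum folding free energy in kcal/mol (<= 0).
#' @return named list with `gc_percent` (0-100), `amfe` (kcal/mol per 100
#'   nt, magnitude) and `mfei` (dimensionless).
#' @examples
#' computeMfei(strrep("GC", 50), -50)  # mfei = 1
#' @export
computeMfei <- function(sequence, mfe) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  if (mfe > 0) stop("mfe must be <= 0", call. = FALSE)
  checkNucleotides(sequence)
  bases <- strsplit(asDna(sequence), "", fixed = TRUE)[[1]]
  gc <- 100 * sum(bases %in% c("G", "C")) / length(bases)
  if (gc == 0)
    stop("GC content is zero: MFEI is undefined", call. = FALSE)
  amfe <- abs(mfe) / length(bases) * 100
  list(gc_percent = gc, amfe = amfe, mfei = amfe / gc)
}

## pair partner for every position (0 = unpaired) from a dot-bracket string
pairTable <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  partner
}

#' Geometry of the annotated miRNA/miRNA* duplex
#'
#' Derives, solely from the dot-bracket pairing of the annotated mature and
#' star intervals: the 3' overhang of each strand (terminal 3' bases whose
#' partners lie outside the opposite arm or are unpaired), the number of
#' asymmetric bulges (a run of unpaired bases on one strand with no opposing
#' unpaired run), and the number of mismatched mature bases (unpaired mature
#' bases opposed by unpaired star bases).
#'
#' @param hairpin a [HairpinCandidate-class].
#' @return named list with `overhang_3p_mature`, `overhang_3p_star`,
#'   `asymmetric_bulges`, `mismatched_mature_bases`.
#' @export
extractDuplex <- function(hairpin) {
  stopifnot(is(hairpin, "HairpinCandidate"))
  partner <- pairTable(hairpin@dotbracket)
  mat <- hairpin@matureStart:hairpin@matureEnd
  star <- hairpin@starStart:hairpin@starEnd
  inStar <- function(p) p >= hairpin@starStart & p <= hairpin@starEnd
  inMat <- function(p) p >= hairpin@matureStart & p <= hairpin@matureEnd

  ## 3' end of each arm: mature 3' end is matureEnd; for the star arm the 3'
  ## end depends on which side of the loop it sits (5' arm ends run toward the
  ## loop). On a hairpin the arm further along the sequence has its 3' end at
  ## its interval end as well, since both arms are written 5'->3'.
  overhang <- function(idx, oppositeIn) {
    n <- 0L
    for (p in rev(idx)) {
      if (partner[p] != 0L && oppositeIn(partner[p])) break
      n <- n + 1L
    }
    n
  }
  oh_m <- overhang(mat, inStar)
  oh_s <- overhang(star, inMat)

  ## duplex pairs between the arms
  pairedMat <- mat[partner[mat] != 0L & inStar(partner[mat])]
  if (!length(pairedMat))
    stop("malformed duplex: mature and star arms share no base pairs",
         call. = FALSE)
  ## walk consecutive paired mature positions; classify interior gaps
  bulges <- 0L
  mism <- 0L
  for (i in seq_len(length(pairedMat) - 1L)) {
    i1 <- pairedMat[i]; i2 <- pairedMat[i + 1L]
    j1 <- partner[i1]; j2 <- partner[i2]
    gm <- i2 - i1 - 1L
    gs <- abs(j1 - j2) - 1L
    if (gm > 0L && gs == 0L) bulges <- bulges + 1L
    else if (gs > 0L && gm == 0L) bulges <- bulges + 1L
    else if (gm > 0L && gs > 0L) {
      mism <- mism + min(gm, gs)
      if (gm != gs) bulges <- bulges + 1L  # the excess is one-sided
    }
  }
  list(overhang_3p_mature = oh_m, overhang_3p_star = oh_s,
       asymmetric_bulges = bulges, mismatched_mature_bases = mism)
}

#' Validate a precursor against the five annotation criteria
#'
#' Checks (1) read support (summed count strictly more than two at default
#' thresholds), (2) folding free energy strictly below -30 kcal/mol, (3)
#' 2-nt 3' overhangs on both strands of the miRNA/miRNA* duplex, (4) at most
#' one asymmetric bulge and at most four mismatched mature bases in the
#' duplex, and (5) MFEI at least 0.85.
#'
#' @param hairpin a [HairpinCandidate-class].
#' @param readCount summed read count supporting the mature sRNA.
#' @param thresholds a [CriteriaThresholds-class].
#' @return one-row data.frame with `gc_percent`, `amfe`, `mfei`, the five
#'   per-criterion booleans (`reads_ok`, `mfe_ok`, `overhang_ok`,
#'   `duplex_ok`, `mfei_ok`) and `overall` (their AND).
#' @export
validatePrecursor <- function(hairpin, readCount,
                              thresholds = criteriaThresholds()) {
  stopifnot(is(hairpin, "HairpinCandidate"))
  m <- computeMfei(hairpin@sequence, hairpin@mfe)
  geom <- extractDuplex(hairpin)
  report <- data.frame(
    gc_percent = m$gc_percent, amfe = m$amfe, mfei = m$mfei,
    reads_ok = readCount >= thresholds@minReads,
    mfe_ok = hairpin@mfe < thresholds@maxMfe,
    overhang_ok = geom$overhang_3p_mature == thresholds@requiredOverhang &&
      geom$overhang_3p_star == thresholds@requiredOverhang,
    duplex_ok = geom$asymmetric_bulges <= thresholds@maxAsymmetricBulges &&
      geom$mismatched_mature_bases <= thresholds@maxMismatches,
    mfei_ok = m$mfei >= thresholds@minMfei,
    stringsAsFactors = FALSE
  )
  report$overall <- report$reads_ok & report$mfe_ok & report$overhang_ok &
    report$duplex_ok & report$mfei_ok
  report
}

#' Approximate fold for structure-free fixtures
#'
#' Maximum base-pairing (AU/GC/GU, minimum loop 3) via dynamic programming,
#' with a pseudo-energy of `-pairs * kcalPerPair`. The result is flagged
#' `approximate = TRUE` and is never a substitute for a thermodynamic MFE
#' where one is required; it exists so that structure-dependent code paths
#' can be exercised without an external folding step.
#'
#' @param sequence nucleotide sequence (at most 1000 nt).
#' @param kcalPerPair pseudo-energy per base pair (kcal/mol, default 2).
#' @return list with `dotbracket`, `pairs`, `pseudo_mfe` and `approximate =
#'   TRUE`.
#' @examples
#' foldFallback("GGGGAAAACCCC")$pairs  # 4
#' @export
foldFallback <- function(sequence, kcalPerPair = 2.0) {
  checkNucleotides(sequence)
  if (nchar(sequence) > 1000L)
    stop("foldFallback is limited to sequences of at most 1000 nt",
         call. = FALSE)
  r <- .nussinov_cpp(asDna(sequence), 3L)
  list(dotbracket = r$dotbracket, pairs = r$pairs,
       pseudo_mfe = -r$pairs * kcalPerPair, approximate = TRUE)
}
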