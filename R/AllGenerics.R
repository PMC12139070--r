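#' Accessors for phasiCascade S4 objects
#'
#' Small accessor generics: `expectation()` returns the expectation score of a
#' duplex; `siteStart()`/`siteEnd()` its transcript interval;
#' `pairingStates()` its per-column states; `locusPeriod()`,
#' `registerOrigin()` and `phaseStats()` the corresponding slots of a
#' [PhasingLocus-class]; `mfe()` and `dotBracket()` those of a
#' [HairpinCandidate-class].
#'
#' @param x the object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("expectation", function(x) standardGeneric("expectation"))
#' @rdname accessors
#' @export
setGeneric("siteStart", function(x) standardGeneric("siteStart"))
#' @rdname accessors
#' @export
setGeneric("siteEnd", function(x) standardGeneric("siteEnd"))
#' @rdname accessors
#' @export
setGeneric("pairingStates", function(x) standardGeneric("pairingStates"))
#' @rdname accessors
#' @export
setGeneric("locusPeriod", function(x) standardGeneric("locusPeriod"))
#' @rdname accessors
#' @export
setGeneric("registerOrigin", function(x) standardGeneric("registerOrigin"))
#' @rdname accessors
#' @export
setGeneric("phaseStats", function(x) standardGeneric("phaseStats"))
#' @rdname accessors
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))
#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname accessors
#' @export
setMethod("expectation", "DuplexAlignment", function(x) x@expectation)
#' @rdname accessors
#' @export
setMethod("siteStart", "DuplexAlignment", function(x) x@siteStart)
#' @rdname accessors
#' @export
setMethod("siteEnd", "DuplexAlignment", function(x) x@siteEnd)
#' @rdname accessors
#' @export
setMethod("pairingStates", "DuplexAlignment", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("locusPeriod", "PhasingLocus", function(x) x@period)
#' @rdname accessors
#' @export
setMethod("registerOrigin", "PhasingLocus", function(x) x@registerOrigin)
#' @rdname accessors
#' @export
setMethod("phaseStats", "PhasingLocus", function(x) x@statistics)
#' @rdname accessors
#' @export
setMethod("mfe", "HairpinCandidate", function(x) x@mfe)
#' @rdname accessors
#' @export
setMethod("dotBracket", "HairpinCandidate", function(x) x@dotbracket)

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme: mismatch", object@mismatchPenalty,
      "| wobble", object@wobblePenalty,
      "| gap", object@gapOpenPenalty, "/", object@gapExtendPenalty,
      "| seed", object@seedStart, "-", object@seedEnd,
      "x", object@seedMultiplier,
      "| E* <=", object@maxExpectation, "\n")
})

setMethod("show", "DuplexAlignment", function(object) {
  cat(sprintf("DuplexAlignment: %s -> %s [%d, %d], expectation %.2f\n",
              object@srna, object@transcriptId, object@siteStart,
              object@siteEnd, object@expectation))
  tab <- table(factor(object@states,
                      levels = c("pair", "wobble", "mismatch",
                                 "srna_bulge", "target_bulge")))
  cat("  columns:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "HairpinCandidate", function(object) {
  cat(sprintf(
    "HairpinCandidate: %d nt, MFE %.1f kcal/mol%s, mature [%d, %d], star [%d, %d]\n",
    nchar(object@sequence), object@mfe,
    if (object@approximateMfe) " (approximate)" else "",
    object@matureStart, object@matureEnd, object@starStart, object@starEnd))
})

setMethod("show", "PhaseStatistics", function(object) {
  cat(sprintf("PhaseStatistics: k=%d P=%g U=%g score=%.3f pvalue=%s\n",
              object@k, object@P, object@U, object@score,
              format(object@pvalue, digits = 3)))
})

setMethod("show", "PhasingLocus", function(object) {
  cat(sprintf(
    "PhasingLocus on %s: [%d, %d], period %d nt, register origin %d\n",
    object@transcriptId, object@start, object@end, object@period,
    object@registerOrigin))
  show(object@statistics)
  if (!is.na(object@trigger)) cat("  trigger:", object@trigger, "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: seed %d, %d nt transcript, cleavage %d, %d x %d-nt registers, occupancy %.2f, noise %.2f\n",
    object@seed, object@transcriptLength, object@cleavagePosition,
    object@nRegisters, object@period, object@occupancy, object@noiseFraction))
})
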