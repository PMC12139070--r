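## Orchestration of the full discovery chain. runConfig() validates the run
## configuration (unknown keys rejected, every threshold echoed into the run
## report); runDiscovery() executes the stages and writes all stage outputs
## plus a JSON summary.

runConfigKeys <- c(
  "transcripts", "srna", "mirnas", "precursors", "degradome",
  "outputDir", "seed", "scheme", "criteria", "phasing",
  "cleavageTolerance", "categoryMax", "registerTolerance",
  "maxMismatches", "geneNames")

#' Build and validate a run configuration
#'
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param srna small RNA library data.frame (`sequence`, `count`,
#'   `library`) or TSV path; may be empty.
#' @param mirnas named character vector of candidate miRNA sequences.
#' @param precursors optional named list of [HairpinCandidate-class] objects
#'   or a hairpin triplet file path.
#' @param degradome optional degradome data.frame or TSV path.
#' @param outputDir directory for stage outputs.
#' @param seed integer seed recorded in the report.
#' @param scheme a [ScoringScheme-class].
#' @param criteria a [CriteriaThresholds-class].
#' @param phasing a [PhasingConfig-class].
#' @param cleavageTolerance,categoryMax degradome validation settings.
#' @param registerTolerance trigger register-coincidence tolerance (nt).
#' @param maxMismatches read-mapping mismatch allowance.
#' @param geneNames named character vector mapping transcript ids to gene
#'   names used for phasiRNA naming (defaults to the transcript ids).
#' @param ... rejected; unknown keys are an error.
#' @return a validated run-configuration list of class `phasiCascadeRun`.
#' @export
runConfig <- function(transcripts, srna, mirnas, precursors = NULL,
                      degradome = NULL, outputDir = tempfile("phasiCascade"),
                      seed = 1L, scheme = scoringScheme(),
                      criteria = criteriaThresholds(),
                      phasing = phasingConfig(), cleavageTolerance = 1L,
                      categoryMax = 2L, registerTolerance = 1L,
                      maxMismatches = 0L, geneNames = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- readFasta(transcripts)
  if (is.character(srna) && length(srna) == 1L && file.exists(srna))
    srna <- readSrnaTable(srna)
  if (is.character(precursors) && length(precursors) == 1L)
    precursors <- readHairpinFile(precursors)
  if (is.character(degradome) && length(degradome) == 1L)
    degradome <- readDegradomeTable(degradome)
  if (is.null(geneNames))
    geneNames <- setNames(names(transcripts), names(transcripts))
  cfg <- list(transcripts = transcripts, srna = srna, mirnas = mirnas,
              precursors = precursors, degradome = degradome,
              outputDir = outputDir, seed = as.integer(seed),
              scheme = scheme, criteria = criteria, phasing = phasing,
              cleavageTolerance = as.integer(cleavageTolerance),
              categoryMax = as.integer(categoryMax),
              registerTolerance = as.integer(registerTolerance),
              maxMismatches = as.integer(maxMismatches),
              geneNames = geneNames)
  stopifnot(identical(sort(names(cfg)), sort(runConfigKeys)))
  class(cfg) <- "phasiCascadeRun"
  cfg
}

stageMessage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), "[", stage, "] ", ...)
}

thresholdsAsList <- function(cfg) {
  list(
    scheme = schemeAsList(cfg$scheme),
    max_expectation = cfg$scheme@maxExpectation,
    criteria = list(min_reads = cfg$criteria@minReads,
                    max_mfe = cfg$criteria@maxMfe,
                    min_mfei = cfg$criteria@minMfei,
                    required_overhang = cfg$criteria@requiredOverhang,
                    max_asymmetric_bulges = cfg$criteria@maxAsymmetricBulges,
                    max_mismatches = cfg$criteria@maxMismatches),
    phasing = list(period = cfg$phasing@period, cycles = cfg$phasing@cycles,
                   min_cycles_occupied = cfg$phasing@minCyclesOccupied,
                   min_score = cfg$phasing@minScore,
                   antisense_offset = cfg$phasing@antisenseOffset,
                   scan_periods = cfg$phasing@scanPeriods),
    cleavage_tolerance = cfg$cleavageTolerance,
    category_max = cfg$categoryMax,
    register_tolerance = cfg$registerTolerance,
    max_mismatches = cfg$maxMismatches,
    seed = cfg$seed)
}

#' Run the full discovery chain
#'
#' Executes, in order: target prediction for every candidate miRNA,
#' precursor validation (when precursors are supplied), read mapping,
#' degradome cleavage validation (when a degradome is supplied), phasing
#' locus detection, register enumeration, trigger inference, and cascade
#' network assembly. All stage tables are written as TSV (loci and sites
#' additionally as GFF3) under `outputDir`, along with `summary.json`
#' recording per-stage counts, every threshold, and the seed. Outputs are a
#' pure function of (inputs, configuration): re-running the same
#' configuration reproduces them byte for byte.
#'
#' @param config a configuration from [runConfig()].
#' @return invisibly, a list with all stage results and the summary.
#' @export
runDiscovery <- function(config) {
  stopifnot(inherits(config, "phasiCascadeRun"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  withStage <- function(stage, expr) {
    stageMessage(stage, "start")
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## 1. target prediction
  sites <- withStage("targets", {
    rows <- lapply(seq_along(config$mirnas), function(i)
      predictTargets(config$mirnas[i], config$transcripts, config$scheme))
    rows <- rows[vapply(rows, nrow, integer(1)) > 0L]
    if (length(rows)) do.call(rbind, rows) else
      data.frame(srna_id = character(), transcript_id = character(),
                 start = integer(), end = integer(), expectation = numeric(),
                 predicted_cleavage = integer(), cleavage_flagged = logical(),
                 stringsAsFactors = FALSE)
  })
  write.table(sites, out("target_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(sites)) exportSitesGff3(sites, out("target_sites.gff3"))

  ## 2. precursor validation
  criteria <- withStage("hairpin", {
    if (is.null(config$precursors)) NULL else {
      counts <- vapply(names(config$precursors), function(id) {
        hp <- config$precursors[[id]]
        mat <- substr(hp@sequence, hp@matureStart, hp@matureEnd)
        sel <- asDna(config$srna$sequence) == asDna(mat)
        as.integer(sum(config$srna$count[sel]))
      }, integer(1))
      reports <- Map(function(hp, n) validatePrecursor(hp, n, config$criteria),
                     config$precursors, counts)
      cbind(data.frame(precursor = names(config$precursors),
                       read_count = counts, stringsAsFactors = FALSE),
            do.call(rbind, reports))
    }
  })
  if (!is.null(criteria))
    write.table(criteria, out("precursor_criteria.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  ## 3. read mapping
  alignments <- withStage("mapping",
    mapReads(config$srna, config$transcripts, config$maxMismatches))
  write.table(alignments, out("alignments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## 4. degradome validation of predicted sites
  evidences <- withStage("degradome", {
    if (is.null(config$degradome) || !nrow(sites)) NULL else {
      rows <- lapply(seq_len(nrow(sites)), function(i) {
        tid <- sites$transcript_id[i]
        tp <- buildTplot(config$degradome, config$transcripts[tid])
        validateCleavage(sites[i, ], tp, config$cleavageTolerance,
                         config$categoryMax)
      })
      do.call(rbind, rows)
    }
  })
  if (!is.null(evidences))
    write.table(evidences, out("cleavage_evidence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  ## 5. phasing loci + 6. register enumeration
  loci <- list()
  phasi <- NULL
  withStage("phasing", {
    for (tid in names(config$transcripts)) {
      al <- alignments[alignments$transcript_id == tid, , drop = FALSE]
      if (!nrow(al)) next
      found <- detectPhasingLoci(al, config$transcripts[tid], config$phasing)
      loci <- c(loci, found)
      for (l in found) {
        sp <- enumerateRegisters(l, config$geneNames[[tid]], al,
                                 config$transcripts[tid], config$phasing)
        sp$transcript_id <- tid
        phasi <- rbind(phasi, sp)
      }
    }
  })
  if (length(loci)) exportLociGff3(loci, out("phasing_loci.gff3"))
  lociTab <- if (length(loci)) data.frame(
    transcript_id = vapply(loci, function(l) l@transcriptId, character(1)),
    start = vapply(loci, function(l) l@start, integer(1)),
    end = vapply(loci, function(l) l@end, integer(1)),
    period = vapply(loci, function(l) l@period, integer(1)),
    register_origin = vapply(loci, function(l) l@registerOrigin, integer(1)),
    k = vapply(loci, function(l) l@statistics@k, integer(1)),
    score = vapply(loci, function(l) l@statistics@score, numeric(1)),
    pvalue = vapply(loci, function(l) l@statistics@pvalue, numeric(1)),
    stringsAsFactors = FALSE) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), period = integer(),
               register_origin = integer(), k = integer(), score = numeric(),
               pvalue = numeric(), stringsAsFactors = FALSE)
  write.table(lociTab, out("phasing_loci.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(phasi))
    write.table(phasi, out("phasirnas.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

  ## 7. trigger inference
  triggers <- withStage("triggers", {
    if (!length(loci)) NULL else {
      pool <- config$mirnas
      if (!is.null(phasi)) {
        det <- phasi[phasi$abundance > 0 & nzchar(phasi$sequence), ]
        pool <- c(pool, setNames(det$sequence, det$name))
      }
      rows <- lapply(loci, function(l) {
        h <- inferTriggers(l, pool, config$transcripts, config$scheme,
                           config$registerTolerance)
        if (nrow(h)) cbind(locus = sprintf("%s:%d-%d", l@transcriptId,
                                           l@start, l@end), h) else NULL
      })
      do.call(rbind, rows)
    }
  })
  if (!is.null(triggers))
    write.table(triggers, out("trigger_hypotheses.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  ## 8. cascade network
  network <- withStage("cascade",
    buildCascadeNetwork(sites, evidences, loci, phasi))
  write.table(network, out("cascade_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  summary <- list(
    schema_version = "1.0",
    package_version = as.character(packageVersion("phasiCascade")),
    seed = config$seed,
    thresholds = thresholdsAsList(config),
    counts = list(
      transcripts = length(config$transcripts),
      srna_species = nrow(config$srna),
      target_sites = nrow(sites),
      precursors_pass = if (is.null(criteria)) 0L else sum(criteria$overall),
      alignments = nrow(alignments),
      validated_cleavages = if (is.null(evidences)) 0L else
        sum(evidences$validated),
      loci = length(loci),
      phasirna_species = if (is.null(phasi)) 0L else nrow(phasi),
      trigger_hypotheses = if (is.null(triggers)) 0L else nrow(triggers),
      cascade_edges = nrow(network)))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stageMessage("done", "outputs in ", config$outputDir)
  invisible(list(sites = sites, criteria = criteria, alignments = alignments,
                 evidences = evidences, loci = loci, phasiRNAs = phasi,
                 triggers = triggers, network = network, summary = summary))
}
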