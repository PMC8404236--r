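#' Simulate a cohort and write FASTQ plus truth sidecars
#'
#' Writes `cohort.fastq`, `individuals.tsv`, `genotypes.tsv` (long format)
#' and `frda_truth.tsv` into `outDir`, each with a provenance header
#' recording the package version and seed, plus `outputs.tsv` listing the
#' files written.  Byte-identical for identical configs.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param panel a [VariantPanel-class]; default: the packaged manifest
#'   restricted to the configured variants plus the repeat locus.
#' @return list with the cohort, amplicon panel and file paths, invisibly.
#' @export
runSimulate <- function(config, outDir, panel = NULL) {
  if (is.null(panel)) panel <- readPanelManifest(screeningFixture("manifest"))
  keep <- variantIds(panel) %in% names(config@alleleFreqs) |
    variantType(panel) == "expansion"
  amps <- buildAmpliconPanel(panel[keep])
  cohort <- simulateCohort(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenanceHeader(config@seed, n_families = config@nFamilies,
                           depth = config@depthPerAmplicon,
                           error_rate = config@errorRate)
  writeTsv <- function(df, file) {
    path <- file.path(outDir, file)
    writeLines(c(hdr, paste(colnames(df), collapse = "\t")), path)
    if (nrow(df))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, append = TRUE)
    path
  }
  ind <- writeTsv(individuals(cohort), "individuals.tsv")
  gt <- truthGenotypes(cohort)
  gtLong <- data.frame(
    sample_id = rep(individuals(cohort)$sample_id, ncol(gt)),
    variant_id = rep(colnames(gt), each = nrow(gt)),
    alt_copies = as.vector(gt), stringsAsFactors = FALSE)
  gtp <- writeTsv(gtLong, "genotypes.tsv")
  fa <- frdaAlleles(cohort)
  frp <- writeTsv(data.frame(sample_id = individuals(cohort)$sample_id,
                             allele1 = fa[, 1], allele2 = fa[, 2],
                             stringsAsFactors = FALSE), "frda_truth.tsv")
  reads <- simulateReads(cohort, amps, config)
  fq <- file.path(outDir, "cohort.fastq")
  writeFastq(reads, fq)
  files <- data.frame(file = basename(c(fq, ind, gtp, frp)),
                      records = c(length(reads), length(cohort),
                                  nrow(gtLong), length(cohort)))
  man <- writeTsv(files, "outputs.tsv")
  invisible(list(cohort = cohort, amplicons = amps,
                 files = c(fastq = fq, individuals = ind, genotypes = gtp,
                           frda_truth = frp, manifest = man)))
}

#' Screen a FASTQ through the full pipeline and write reports
#'
#' Reads the FASTQ (sample ids from the read-name prefix before `":"`),
#' runs assignment, alignment, genotyping and expansion calling, and
#' writes `genotypes.tsv`, `genotypes.vcf` and `frda_report.tsv` plus a
#' `screening_report.json` with per-variant estimated carrier frequencies
#' and the any-carrier rate.
#'
#' @param fastq path to the FASTQ file.
#' @param outDir output directory.
#' @param panel a [VariantPanel-class] or manifest path; default: the
#'   packaged manifest.
#' @param frdaThreshold,minDepth,hetBand pipeline thresholds (echoed into
#'   every report header).
#' @param seed recorded for provenance.
#' @return the [CarrierScreenExperiment-class], invisibly.
#' @export
runScreen <- function(fastq, outDir, panel = NULL, frdaThreshold = 35L,
                      minDepth = 20L, hetBand = c(0.20, 0.80), seed = NA) {
  if (is.null(panel)) panel <- readPanelManifest(screeningFixture("manifest"))
  if (is.character(panel)) panel <- readPanelManifest(panel)
  amps <- buildAmpliconPanel(panel)
  reads <- readFastq(fastq)
  cse <- screenReads(reads, amps = amps, panel = panel,
                     minDepth = minDepth, hetBand = hetBand,
                     frdaThreshold = frdaThreshold, seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypeCalls(cse, file.path(outDir, "genotypes.tsv"))
  writeMinimalVcf(cse, panel, file.path(outDir, "genotypes.vcf"))
  frdaFinalReport(cse, file.path(outDir, "frda_report.tsv"))
  est <- estimateCarrierFrequencies(cse)
  jsonlite::write_json(
    list(seed = seed, frda_threshold = frdaThreshold, min_depth = minDepth,
         n_samples = ncol(cse), estimates = est,
         any_carrier_rate = anyCarrierRate(cse)),
    file.path(outDir, "screening_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(cse)
}

#' Cohort statistics from screening results
#'
#' Aggregates a screening result into the published-report quantities:
#' per-variant frequencies with Wilson CIs, per-gene combined fractions,
#' the at-risk couple probability, the screening-panel filter and the
#' any-carrier rate.
#'
#' @param x a [CarrierScreenExperiment-class].
#' @param panelThresholdPercent screening-panel retention threshold.
#' @param path optional JSON output path.
#' @return list of the above quantities.
#' @export
runStats <- function(x, panelThresholdPercent = 0.6, path = NULL) {
  est <- estimateCarrierFrequencies(x)
  est$phenotype <- est$variant_id      # phenotype strings live in the panel;
  p <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))
  if ("phenotype" %in% colnames(p)) est$phenotype <- p$phenotype
  gf <- aggregateByGene(est)
  out <- list(estimates = est, gene_fractions = as.list(gf),
              couple_risk = coupleAtRiskProbability(gf),
              panel_filter = filterScreeningPanel(est, panelThresholdPercent)[
                c("n_variants", "n_phenotypes")],
              any_carrier_rate = anyCarrierRate(x))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  out
}
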