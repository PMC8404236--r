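#' Assign reads to amplicons by shared k-mers
#'
#' Each read is compared against every amplicon reference: the score for
#' an amplicon is the number of read k-mer positions whose k-mer occurs in
#' that amplicon.  The read is assigned to the unique best-scoring
#' amplicon; reads whose best score is below `minShared` or tied between
#' amplicons are unassigned.
#'
#' @param reads character vector of read sequences.
#' @param amps an [AmpliconPanel-class] (or named character vector of
#'   amplicon sequences).
#' @param k k-mer length (>= 11).
#' @param minShared minimum shared k-mer count for assignment.
#' @return character vector of amplicon ids (`NA` = unassigned).
#' @export
assignReadToAmplicon <- function(reads, amps, k = 15L, minShared = 3L) {
  if (k < 11) .stopf("k must be >= 11")
  seqs <- if (methods::is(amps, "AmpliconPanel")) as.character(amps@targets)
          else as.character(amps)
  idx <- cpp_assign_reads(as.character(reads), unname(seqs),
                          as.integer(k), as.integer(minShared))
  names(seqs)[idx]
}

#' Align a read to an amplicon reference
#'
#' Fit alignment: the read is aligned end-to-end against a free-floating
#' window of the reference (match +1, mismatch -1, gap open -3, gap extend
#' -1; ties resolved toward the leftmost reference offset).  Alignments
#' scoring below `-0.2 * nchar(read)` are discarded from the pileup.
#'
#' @param reads character vector of reads (vectorised).
#' @param target amplicon reference sequence (character or `DNAString`).
#' @param scoreFloorFrac discard threshold as a fraction of read length.
#' @return data.frame with columns `score`, `ref_start` (0-based), `cigar`
#'   (`M`/`I`/`D` ops, read-relative) and `discarded`.
#' @export
alignRead <- function(reads, target, scoreFloorFrac = 0.2) {
  target <- as.character(target)
  out <- lapply(as.character(reads), function(r) cpp_fit_align(r, target))
  data.frame(score = vapply(out, `[[`, numeric(1), "score"),
             ref_start = vapply(out, `[[`, numeric(1), "ref_start"),
             cigar = vapply(out, `[[`, character(1), "cigar"),
             discarded = vapply(out, `[[`, numeric(1), "score") <
               -scoreFloorFrac * nchar(as.character(reads)),
             stringsAsFactors = FALSE)
}

#' Diploid genotype from ref/alt allele depths
#'
#' The threshold rule used throughout the package: with
#' `af = alt / (ref + alt)`, a site is `hom_ref` below the het band,
#' `het` inside `[hetBand[1], hetBand[2]]`, `hom_alt` above it, and
#' `no_call` when `ref + alt < minDepth`.
#'
#' @param refDepth,altDepth integer vectors of allele-supporting depths.
#' @param minDepth minimum informative depth for a call.
#' @param hetBand inclusive alt-fraction interval called heterozygous.
#' @return data.frame with `genotype` (factor `hom_ref`/`het`/`hom_alt`/
#'   `no_call`) and `alt_fraction` (`NA` when depth is 0).
#' @examples
#' callFromDepths(c(50, 52, 5), c(0, 48, 4))
#' @export
callFromDepths <- function(refDepth, altDepth, minDepth = 20L,
                           hetBand = c(0.20, 0.80)) {
  tot <- refDepth + altDepth
  af <- ifelse(tot > 0, altDepth / tot, NA_real_)
  g <- ifelse(tot < minDepth, "no_call",
       ifelse(af < hetBand[1], "hom_ref",
       ifelse(af <= hetBand[2], "het", "hom_alt")))
  data.frame(genotype = factor(g, levels = c("hom_ref", "het", "hom_alt",
                                             "no_call")),
             alt_fraction = af)
}

#' Pile up aligned reads over one panel site and call the genotype
#'
#' Reads are classified as ref-supporting, alt-supporting or other by
#' exact comparison of the read subsequence spanning the variant (plus
#' `pad` anchor bases each side) with the ref and alt haplotype windows;
#' for indels this requires the full printed alt allele within the aligned
#' read, and partial overlaps count as other.  Depths then pass through
#' [callFromDepths()].
#'
#' @param reads character vector of reads assigned to this amplicon.
#' @param alignments data.frame from [alignRead()] for these reads.
#' @param target amplicon reference sequence.
#' @param offset 0-based offset of the variant ref allele in `target`.
#' @param ref,alt the variant alleles.
#' @param minDepth,hetBand see [callFromDepths()].
#' @param pad anchor bases required on each side of the allele.
#' @return list with `genotype`, `alt_fraction`, `ref_depth`, `alt_depth`,
#'   `other_depth`.
#' @export
pileupAndCall <- function(reads, alignments, target, offset, ref, alt,
                          minDepth = 20L, hetBand = c(0.20, 0.80), pad = 10L) {
  target <- as.character(target)
  keep <- !alignments$discarded
  a <- offset - pad
  b <- offset + nchar(ref) - 1L + pad
  refWin <- substr(target, a + 1L, b + 1L)
  altWin <- paste0(substr(target, a + 1L, offset), alt,
                   substr(target, offset + nchar(ref) + 1L, b + 1L))
  cls <- if (any(keep))
    cpp_classify_reads(as.character(reads)[keep],
                       as.integer(alignments$ref_start[keep]),
                       alignments$cigar[keep], as.integer(a), as.integer(b),
                       refWin, altWin)
  else integer(0)
  depths <- c(ref = sum(cls == 0L), alt = sum(cls == 1L), other = sum(cls == 2L))
  call <- callFromDepths(depths[["ref"]], depths[["alt"]], minDepth, hetBand)
  list(genotype = as.character(call$genotype),
       alt_fraction = call$alt_fraction,
       ref_depth = unname(depths[["ref"]]), alt_depth = unname(depths[["alt"]]),
       other_depth = unname(depths[["other"]]))
}

# --- cohort-scale driver -----------------------------------------------

# run the C++ batch screen over one set of reads; returns depth matrices
# (samples x variants) and FXN per-read repeat counts
.screenBatch <- function(reads, sampleIdx, nSamples, amps, windows,
                         k = 15L, minShared = 3L, maxFastMismatch = 4L,
                         scoreFloorFrac = 0.2, minRepeats = 4L) {
  fxn <- if (is.na(amps@fxnAmplicon)) -1L
         else match(amps@fxnAmplicon, names(amps@targets))
  cpp_screen_batch(as.character(reads), as.integer(sampleIdx),
                   as.integer(nSamples),
                   unname(as.character(amps@targets)),
                   as.integer(k), as.integer(minShared),
                   as.integer(windows$amp), as.integer(windows$winStart),
                   as.integer(windows$winEnd), windows$refWin, windows$altWin,
                   as.integer(fxn), as.integer(maxFastMismatch),
                   scoreFloorFrac, as.integer(minRepeats))
}

.genotypeCode <- function(g) {
  unname(c(hom_ref = 0L, het = 1L, hom_alt = 2L, no_call = NA_integer_)[g])
}

# assemble the result container from accumulated depths + repeat evidence
.buildCSE <- function(refD, altD, othD, frdaBySample, sampleIds, amps, panel,
                      minDepth, hetBand, frdaThreshold, minRepeats, seed) {
  vids <- amps@variants$variant_id
  call <- callFromDepths(as.vector(refD), as.vector(altD), minDepth, hetBand)
  gt <- matrix(.genotypeCode(as.character(call$genotype)),
               nrow = length(sampleIds),
               dimnames = list(sampleIds, vids))
  stats <- lapply(frdaBySample, function(x)
    methods::new("RepeatReadStats", sampleId = "s", perReadRepeats = x))
  calls <- lapply(seq_along(stats), function(i)
    callFrda(stats[[i]], threshold = frdaThreshold))
  hasFxn <- !is.na(amps@fxnAmplicon)
  rowIds <- c(vids, if (hasFxn) "FXN:GAA expansion")
  gtAll <- t(cbind(gt, if (hasFxn)
    matrix(as.integer(vapply(calls, isCarrier, logical(1))),
           ncol = 1, dimnames = list(NULL, "FXN:GAA expansion"))))
  pad0 <- function(m) {
    if (!hasFxn) return(t(m))
    t(cbind(m, matrix(0L, nrow(m), 1)))
  }
  top3 <- t(vapply(stats, function(s) {
    x <- top3Rprf(s); c(x, rep(NA_integer_, 3 - length(x)))
  }, integer(3)))
  cd <- S4Vectors::DataFrame(
    sample_id = sampleIds,
    frda_repeat_reads = vapply(stats, repeatReadCount, integer(1)),
    frda_total_repeats = vapply(stats, totalRepeats, integer(1)),
    rprf_1 = top3[, 1], rprf_2 = top3[, 2], rprf_3 = top3[, 3],
    frda_carrier = vapply(calls, isCarrier, logical(1)),
    row.names = sampleIds)
  rr <- if (methods::is(panel, "VariantPanel") &&
            all(rowIds %in% variantIds(panel))) {
    gr <- panel[match(rowIds, variantIds(panel))]
    methods::as(gr, "GRanges")
  } else {
    GenomicRanges::GRanges(rep("unknown", length(rowIds)),
                           IRanges::IRanges(seq_along(rowIds), width = 1),
                           variant_id = rowIds,
                           gene = sub(":.*$", "", rowIds))
  }
  names(rr) <- rowIds
  dimn <- list(rowIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = matrix(gtAll, dimnames = dimn,
                                    nrow = length(rowIds)),
                  refDepth = matrix(pad0(refD), dimnames = dimn,
                                    nrow = length(rowIds)),
                  altDepth = matrix(pad0(altD), dimnames = dimn,
                                    nrow = length(rowIds)),
                  otherDepth = matrix(pad0(othD), dimnames = dimn,
                                      nrow = length(rowIds))),
    rowRanges = rr, colData = cd,
    metadata = list(min_depth = minDepth, het_band = hetBand,
                    frda_threshold = frdaThreshold,
                    min_repeats = minRepeats, seed = seed))
  methods::new("CarrierScreenExperiment", se)
}

#' Screen a set of reads: assignment, alignment, genotyping, repeat calling
#'
#' The full per-read pipeline over an in-memory read set: k-mer assignment
#' to amplicons, alignment (ungapped at the voted diagonal when the read
#' fits with few mismatches, Gotoh fit alignment otherwise), windowed
#' ref/alt classification at every panel site, depth-threshold diploid
#' calls, and GAA repeat counting plus the top-2-RPRF expansion call for
#' reads on the repeat-locus amplicon.  Results are independent of read
#' order.
#'
#' @param reads character vector of read sequences.
#' @param sampleIds sample id per read (defaults to the `"<sample>:<n>"`
#'   prefix of read names).
#' @param amps an [AmpliconPanel-class].
#' @param panel optional [VariantPanel-class] supplying row coordinates.
#' @param sampleLevels sample ids defining result columns (defaults to the
#'   sorted unique `sampleIds`); samples without reads yield no-calls.
#' @param minDepth,hetBand genotype thresholds, see [callFromDepths()].
#' @param frdaThreshold GAA triplet threshold of the expansion caller.
#' @param minRepeats minimum GAA run for a repeat-bearing read.
#' @param k,minShared read-assignment parameters.
#' @param seed recorded in the result metadata (provenance only).
#' @return a [CarrierScreenExperiment-class].
#' @export
screenReads <- function(reads, sampleIds = NULL, amps, panel = NULL,
                        sampleLevels = NULL, minDepth = 20L,
                        hetBand = c(0.20, 0.80), frdaThreshold = 35L,
                        minRepeats = 4L, k = 15L, minShared = 3L, seed = NA) {
  if (is.null(sampleIds)) {
    if (is.null(names(reads))) .stopf("sampleIds or read names required")
    sampleIds <- sub(":.*$", "", names(reads))
  }
  if (is.null(sampleLevels)) sampleLevels <- sort(unique(sampleIds))
  if (!length(sampleLevels)) sampleLevels <- "sample1"
  sidx <- match(sampleIds, sampleLevels)
  if (anyNA(sidx)) .stopf("read sample ids outside sampleLevels")
  windows <- .variantWindows(amps)
  res <- .screenBatch(reads, sidx, length(sampleLevels), amps, windows,
                      k = k, minShared = minShared)
  frdaBySample <- lapply(seq_along(sampleLevels), function(s)
    as.integer(res$fxn_repeats[res$fxn_sample == s]))
  .buildCSE(res$ref, res$alt, res$other, frdaBySample, sampleLevels, amps,
            panel, minDepth, hetBand, frdaThreshold, minRepeats, seed)
}

#' Simulate and screen a cohort end to end
#'
#' Runs the whole pipeline at cohort scale while streaming reads in
#' per-sample chunks: simulate amplicon reads for a chunk, push them
#' through assignment / alignment / genotyping / repeat counting, and
#' accumulate depths, so the full read set never needs to be held in
#' memory.  Deterministic for a given config, seed and chunk size.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param amps an [AmpliconPanel-class].
#' @param config a [SimConfig-class] (sequencing parameters).
#' @param panel optional [VariantPanel-class] for result row coordinates.
#' @param chunkSize samples per streamed chunk.
#' @param seed RNG seed for read generation (default `config@seed + 1`).
#' @param ... genotyping/expansion thresholds passed to [screenReads()]'s
#'   internals: `minDepth`, `hetBand`, `frdaThreshold`, `minRepeats`,
#'   `k`, `minShared`.
#' @return a [CarrierScreenExperiment-class].
#' @export
screenCohort <- function(cohort, amps, config, panel = NULL, chunkSize = 256L,
                         seed = config@seed + 1L, minDepth = 20L,
                         hetBand = c(0.20, 0.80), frdaThreshold = 35L,
                         minRepeats = 4L, k = 15L, minShared = 3L) {
  n <- length(cohort)
  sampleIds <- cohort@individuals$sample_id
  windows <- .variantWindows(amps)
  nVar <- nrow(amps@variants)
  refD <- altD <- othD <- matrix(0L, n, nVar)
  frdaBySample <- rep(list(integer(0)), n)
  withr::with_seed(seed, {
    starts <- seq(1L, max(n, 1L), by = chunkSize)
    if (n == 0) starts <- integer(0)
    for (s0 in starts) {
      rows <- s0:min(s0 + chunkSize - 1L, n)
      sim <- .simulateReadsBulk(cohort, amps, config, rows)
      res <- .screenBatch(sim$reads, sim$sampleIdx, length(rows), amps,
                          windows, k = k, minShared = minShared)
      refD[rows, ] <- refD[rows, ] + res$ref
      altD[rows, ] <- altD[rows, ] + res$alt
      othD[rows, ] <- othD[rows, ] + res$other
      if (length(res$fxn_sample)) {
        tab <- split(as.integer(res$fxn_repeats), res$fxn_sample)
        for (nm in names(tab)) {
          g <- rows[as.integer(nm)]
          frdaBySample[[g]] <- c(frdaBySample[[g]], tab[[nm]])
        }
      }
    }
  })
  .buildCSE(refD, altD, othD, frdaBySample, sampleIds, amps, panel,
            minDepth, hetBand, frdaThreshold, minRepeats, seed)
}

#' Estimate per-variant carrier frequencies from screening calls
#'
#' A sample is a carrier of a variant when called het or hom-alt (for the
#' FXN expansion row, when the repeat caller flags it).  The denominator
#' counts samples with a call at that site.
#'
#' @param x a [CarrierScreenExperiment-class].
#' @return data.frame in [carrierFrequency()] format, one row per variant,
#'   with a `gene` column.
#' @export
estimateCarrierFrequencies <- function(x) {
  stopifnot(methods::is(x, "CarrierScreenExperiment"))
  gt <- genotypeCalls(x)
  carriers <- rowSums(gt >= 1L, na.rm = TRUE)
  n <- rowSums(!is.na(gt))
  est <- carrierFrequency(carriers, pmax(n, 1L),
                          variant_id = rownames(gt))
  est$n[n == 0] <- 0L
  est$gene <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$gene
  est
}

#' Write per-sample genotype calls as TSV
#'
#' @param x a [CarrierScreenExperiment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypeCalls <- function(x, path) {
  gt <- genotypeCalls(x)
  lv <- c("hom_ref", "het", "hom_alt")
  long <- data.frame(
    sample_id = rep(colnames(gt), each = nrow(gt)),
    variant_id = rep(rownames(gt), ncol(gt)),
    genotype = ifelse(is.na(as.vector(gt)), "no_call", lv[as.vector(gt) + 1L]),
    ref_depth = as.vector(SummarizedExperiment::assay(x, "refDepth")),
    alt_depth = as.vector(SummarizedExperiment::assay(x, "altDepth")),
    other_depth = as.vector(SummarizedExperiment::assay(x, "otherDepth")),
    stringsAsFactors = FALSE)
  md <- S4Vectors::metadata(x)
  writeLines(c(.provenanceHeader(md$seed, min_depth = md$min_depth,
                                 frda_threshold = md$frda_threshold),
               paste(colnames(long), collapse = "\t")), path)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write calls as a minimal VCF
#'
#' Fixed-header VCF v4.2 with `GT` and `AD` fields over the SNV/indel
#' panel rows (region and expansion records are omitted; the expansion
#' call is reported by [frdaFinalReport()]).
#'
#' @param x a [CarrierScreenExperiment-class].
#' @param panel the [VariantPanel-class] providing coordinates and alleles.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMinimalVcf <- function(x, panel, path) {
  keep <- intersect(rownames(x), variantIds(panel)[isGenotypable(panel)])
  p <- panel[match(keep, variantIds(panel))]
  mc <- S4Vectors::mcols(p)
  gt <- genotypeCalls(x)[keep, , drop = FALSE]
  ad <- paste(SummarizedExperiment::assay(x, "refDepth")[keep, , drop = FALSE],
              SummarizedExperiment::assay(x, "altDepth")[keep, , drop = FALSE],
              sep = ",")
  gts <- c("0/0", "0/1", "1/1")
  gtStr <- ifelse(is.na(as.vector(gt)), "./.", gts[as.vector(gt) + 1L])
  field <- matrix(paste(gtStr, ad, sep = ":"), nrow = nrow(gt))
  md <- S4Vectors::metadata(x)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=ampliscreen_%s",
                   utils::packageVersion("ampliscreen")),
           sprintf("##ampliscreen_seed=%s", md$seed),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- paste(as.character(GenomicRanges::seqnames(p)),
                GenomicRanges::start(p), mc$variant_id, mc$ref, mc$alt,
                ".", "PASS", ".", "GT:AD",
                apply(field, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
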