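#' Count GAA repeats in a read
#'
#' Returns the length, in triplets, of the longest tandem run of the GAA
#' motif in each read, scanning every phase offset (rotations GAA / AAG /
#' AGA), or 0 when no run is present.  This per-read count is the
#' repeat-per-read frequency (RPRF) on which expansion carrier calling is
#' based: a read that enters an expanded tract from the flank, or lies
#' wholly inside it, carries a long uninterrupted run, while reads from
#' normal alleles are capped by the normal tract length.
#'
#' @param reads character vector of reads (uppercase ACGTN).
#' @return integer vector of longest-run lengths in triplets.
#' @examples
#' countGaaRepeats(c("GAAGAAGAA", paste0(strrep("GAA", 10), "T",
#'                                       strrep("GAA", 25))))
#' @export
countGaaRepeats <- function(reads) {
  cpp_gaa_runs(as.character(reads))
}

#' Classify a read against the decoy reference
#'
#' Emulates split-read extraction against a GAA decoy "chromosome" plus
#' the repeat-free locus flank: a read is a `split_read` when it carries a
#' GAA run of at least `minRepeats` triplets AND an exact-or-1-mismatch
#' match of at least `anchorLen` bases of the flank sequence (it spans the
#' flank-repeat junction); a `pure_repeat` read carries the run without a
#' flank anchor (it lies inside an expanded tract); anything else is
#' `non_repeat`.
#'
#' @param reads character vector of reads.
#' @param ref a [DecoyReference-class].
#' @param minRepeats minimum GAA run (triplets) to count as repeat-bearing.
#' @return character vector in `split_read`, `pure_repeat`, `non_repeat`.
#' @export
classifyRepeatRead <- function(reads, ref, minRepeats = 4L) {
  stopifnot(methods::is(ref, "DecoyReference"))
  runs <- countGaaRepeats(reads)
  out <- rep("non_repeat", length(runs))
  rep_ <- runs >= minRepeats
  if (any(rep_)) {
    hit <- cpp_anchor_hits(as.character(reads)[rep_],
                           as.character(ref@flankSeq),
                           as.integer(ref@anchorLen), 1L)
    out[rep_] <- ifelse(hit, "split_read", "pure_repeat")
  }
  out
}

#' Collect per-sample GAA repeat evidence
#'
#' Scans one sample's repeat-locus reads: every read classified
#' `split_read` or `pure_repeat` contributes its GAA triplet count to the
#' per-read repeat list, from which the repeat-bearing read count, the
#' total repeats and the top-3 repeat-per-read frequencies derive.  The
#' result is invariant to read order.
#'
#' @param reads character vector (or named FASTQ import) of one sample's
#'   repeat-locus reads.
#' @param ref a [DecoyReference-class].
#' @param sampleId sample identifier stored in the result.
#' @param minRepeats minimum GAA run (triplets) for a repeat-bearing read.
#' @return a [RepeatReadStats-class].
#' @examples
#' ref <- DecoyReference()
#' stats <- collectRepeatStats(strrep("GAA", c(44, 41, 38, 12, 9)), ref)
#' top3Rprf(stats)
#' @export
collectRepeatStats <- function(reads, ref, sampleId = "sample", minRepeats = 4L) {
  runs <- countGaaRepeats(reads)
  methods::new("RepeatReadStats", sampleId = as.character(sampleId),
               perReadRepeats = as.integer(runs[runs >= minRepeats]))
}

#' Call FRDA expansion carrier status
#'
#' The decision rule: a sample is a carrier when at least two of its top-3
#' repeat-per-read frequencies strictly exceed the threshold (default 35
#' GAA triplets); samples with fewer than two such reads are non-carriers.
#' The boundary value (a count equal to the threshold) does not qualify.
#'
#' @param stats a [RepeatReadStats-class].
#' @param threshold GAA triplet threshold.
#' @return a [FrdaCall-class].
#' @examples
#' ref <- DecoyReference()
#' isCarrier(callFrda(collectRepeatStats(strrep("GAA", c(44, 41, 38)), ref)))
#' isCarrier(callFrda(collectRepeatStats(strrep("GAA", c(36, 30, 28)), ref)))
#' @export
callFrda <- function(stats, threshold = 35L) {
  stopifnot(methods::is(stats, "RepeatReadStats"))
  t3 <- top3Rprf(stats)
  methods::new("FrdaCall", sampleId = stats@sampleId,
               carrier = sum(t3 > threshold) >= 2,
               top3Rprf = as.integer(t3), threshold = as.integer(threshold))
}

#' Per-sample expansion-screen final report
#'
#' One row per sample: repeat-bearing read count, total GAA triplets, the
#' three highest repeat-per-read frequencies and the carrier call.
#'
#' @param x a [CarrierScreenExperiment-class], or a list of
#'   [FrdaCall-class] objects paired with [RepeatReadStats-class] via
#'   `stats`.
#' @param path optional output TSV; when given, a provenance header and the
#'   threshold are written above the table.
#' @return the report data.frame (invisibly when `path` is given).
#' @export
frdaFinalReport <- function(x, path = NULL) {
  stopifnot(methods::is(x, "CarrierScreenExperiment"))
  df <- frdaCalls(x)
  names(df)[names(df) == "frda_repeat_reads"] <- "repeat_read_count"
  names(df)[names(df) == "frda_total_repeats"] <- "total_repeats"
  names(df)[names(df) == "frda_carrier"] <- "carrier_call"
  rownames(df) <- NULL
  if (!is.null(path)) {
    md <- S4Vectors::metadata(x)
    writeLines(c(.provenanceHeader(md$seed, frda_threshold = md$frda_threshold),
                 paste(colnames(df), collapse = "\t")), path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE, na = "")
    return(invisible(df))
  }
  df
}
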