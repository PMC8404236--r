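#' VariantPanel: the screening panel of disease-causing variants
#'
#' A `VariantPanel` is a [GenomicRanges::GRanges] (hg38 coordinates, 1-based
#' as printed in the source tables) carrying one range per screened variant
#' with metadata columns `variant_id`, `ref`, `alt`, `gene`, `omim`,
#' `hgvs_c`, `hgvs_p`, `phenotype`, `category` (integer 1-5 or `NA`) and a
#' derived `type` (`snv`, `del`, `ins`, `mnv`, `expansion`, `cnv`).
#' Region-level records (the TRPM1 exon 2-7 deletion) and the FXN GAA
#' expansion are representable but excluded from read-level genotyping;
#' `isGenotypable()` flags the SNV/small-indel subset.
#'
#' @slot .  inherits all slots from `GRanges`.
#' @aliases variantIds variantType isGenotypable
#' @seealso [readPanelManifest()], [buildAmpliconPanel()]
#' @export
setClass("VariantPanel", contains = "GRanges")

.PANEL_MCOLS <- c("variant_id", "ref", "alt", "gene", "omim", "hgvs_c",
                  "hgvs_p", "phenotype", "category", "type")

setValidity("VariantPanel", function(object) {
  mc <- S4Vectors::mcols(object)
  miss <- setdiff(.PANEL_MCOLS, colnames(mc))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(mc$variant_id))
    return("duplicate variant_id")
  seqv <- mc$type %in% c("snv", "del", "ins", "mnv")
  if (any(seqv & (mc$ref == mc$alt)))
    return("ref and alt alleles must differ")
  if (length(object) && any(GenomicRanges::start(object) <= 0))
    return("positions must be positive")
  bad <- !is.na(mc$category) & !(mc$category %in% 1:5)
  if (any(bad)) return("category must be in 1..5 when present")
  TRUE
})

#' @describeIn VariantPanel-class variant identifiers.
#' @export
setMethod("variantIds", "VariantPanel", function(x) S4Vectors::mcols(x)$variant_id)

#' @describeIn VariantPanel-class variant type labels.
#' @export
setMethod("variantType", "VariantPanel", function(x) S4Vectors::mcols(x)$type)

#' @describeIn VariantPanel-class logical; `TRUE` for SNV/small-indel
#'   records amenable to read-level genotyping.
#' @export
setMethod("isGenotypable", "VariantPanel", function(x)
  S4Vectors::mcols(x)$type %in% c("snv", "del", "ins", "mnv"))

setMethod("show", "VariantPanel", function(object) {
  cat("VariantPanel with", length(object), "variants in",
      length(unique(S4Vectors::mcols(object)$gene)), "genes;",
      sum(isGenotypable(object)), "genotypable\n")
  methods::callNextMethod()
})

#' DecoyReference: the GAA decoy plus repeat-free flank
#'
#' Detection of repeat-expanded reads works against two artificial
#' references: a pure `(GAA)n` decoy sequence and the repeat-free FXN
#' intron-1 amplicon flank (the amplicon with the GAA tract removed).  A
#' read evidences the repeat-tract junction when it carries both a GAA run
#' and an anchor match of at least `anchorLen` bases of the flank (one
#' mismatch tolerated).  The packaged flank is a synthetic stand-in
#' sequence: the caller's behaviour depends only on the flank containing no
#' GAA run of 4 or more triplets, which the validity method enforces.
#'
#' @slot decoySeq `DNAString`, a pure tandem GAA tract.
#' @slot flankSeq `DNAString`, repeat-free flank sequence.
#' @slot anchorLen integer, minimum anchor match length in bases.
#' @seealso [classifyRepeatRead()], [collectRepeatStats()]
#' @export
setClass("DecoyReference",
         representation(decoySeq = "DNAString", flankSeq = "DNAString",
                        anchorLen = "integer"))

setValidity("DecoyReference", function(object) {
  d <- as.character(object@decoySeq)
  if (nchar(d) < 3 || gsub("GAA", "", d) != "")
    return("decoySeq must be a pure (GAA)n tract")
  if (countGaaRepeats(as.character(object@flankSeq)) >= 4)
    return("flankSeq must not contain a GAA run of >= 4 triplets")
  if (length(object@anchorLen) != 1 || object@anchorLen < 1)
    return("anchorLen must be a positive scalar")
  TRUE
})

#' Construct a DecoyReference
#'
#' @param flankSeq flank sequence (character or `DNAString`); when `NULL` a
#'   deterministic synthetic repeat-free flank of 350 bp is generated.
#' @param decoyUnits number of GAA units in the decoy tract.
#' @param anchorLen minimum flank anchor length (bases).
#' @return a [DecoyReference-class] object.
#' @export
DecoyReference <- function(flankSeq = NULL, decoyUnits = 83L, anchorLen = 20L) {
  if (is.null(flankSeq))
    flankSeq <- withr::with_seed(604610, .noGaaDna(350))
  methods::new("DecoyReference",
               decoySeq = Biostrings::DNAString(strrep("GAA", decoyUnits)),
               flankSeq = Biostrings::DNAString(as.character(flankSeq)),
               anchorLen = as.integer(anchorLen))
}

setMethod("show", "DecoyReference", function(object) {
  cat("DecoyReference: decoy", length(object@decoySeq) %/% 3, "GAA units;",
      "flank", length(object@flankSeq), "bp; anchor", object@anchorLen, "bp\n")
})

#' AmpliconPanel: per-variant amplicon reference sequences
#'
#' Holds the local reference sequence of every amplicon in the multiplex
#' assay (a `DNAStringSet`), the 0-based offset of each panel variant
#' within its amplicon, and the repeat-locus (FXN) amplicon together with
#' its [DecoyReference-class].  Amplicon sequences are synthetic stand-ins
#' generated deterministically from a seed; the screening algorithms are
#' independent of the actual flank content.
#'
#' @slot targets named `DNAStringSet` of amplicon reference sequences.
#' @slot variants data.frame with columns `variant_id`, `amplicon_id`,
#'   `offset` (0-based), `ref`, `alt`.
#' @slot fxnAmplicon id of the FXN repeat-locus amplicon (`NA` if absent).
#' @slot decoy a [DecoyReference-class].
#' @aliases ampliconSeqs decoyReference
#' @seealso [buildAmpliconPanel()]
#' @export
setClass("AmpliconPanel",
         representation(targets = "DNAStringSet", variants = "data.frame",
                        fxnAmplicon = "character", decoy = "DecoyReference"))

setValidity("AmpliconPanel", function(object) {
  v <- object@variants
  need <- c("variant_id", "amplicon_id", "offset", "ref", "alt")
  if (!all(need %in% colnames(v)))
    return(paste("variants table needs columns:", paste(need, collapse = ", ")))
  if (!all(v$amplicon_id %in% names(object@targets)))
    return("every variant must map to an amplicon")
  w <- Biostrings::width(object@targets)[match(v$amplicon_id, names(object@targets))]
  if (any(v$offset < 0 | v$offset + nchar(v$ref) > w))
    return("variant offset outside amplicon")
  seqs <- as.character(object@targets)
  if (any(grepl("[^ACGT]", seqs)))
    return("amplicon sequences must be uppercase ACGT")
  ok <- substr(seqs[match(v$amplicon_id, names(object@targets))],
               v$offset + 1, v$offset + nchar(v$ref)) == v$ref
  if (!all(ok))
    return("amplicon sequence does not carry the ref allele at the stated offset")
  TRUE
})

#' @describeIn AmpliconPanel-class the amplicon reference sequences.
#' @export
setMethod("ampliconSeqs", "AmpliconPanel", function(x) x@targets)

#' @describeIn AmpliconPanel-class variant ids mapped on this panel.
#' @export
setMethod("variantIds", "AmpliconPanel", function(x) x@variants$variant_id)

#' @describeIn AmpliconPanel-class the repeat-locus decoy reference.
#' @export
setMethod("decoyReference", "AmpliconPanel", function(x) x@decoy)

setMethod("show", "AmpliconPanel", function(object) {
  cat("AmpliconPanel:", length(object@targets), "amplicons covering",
      nrow(object@variants), "variants",
      if (!is.na(object@fxnAmplicon)) sprintf("(+ repeat locus '%s')", object@fxnAmplicon)
      else "", "\n")
})

#' SimConfig: simulation parameters for a screening cohort
#'
#' Bundles everything the synthetic cohort and read generators need:
#' family structure, grandparental ancestry patterns, per-variant carrier
#' frequencies, the FXN GAA allele-length model, and sequencing parameters.
#' Carrier frequencies are converted to allele frequencies by the exact
#' Hardy-Weinberg inversion q = 1 - sqrt(1 - cf).
#'
#' The read length must allow a single read to span more than 35 GAA
#' triplets plus two flank anchors (>= 3*36 + 2*20 = 148 bases), otherwise
#' the expansion caller's decision statistic could never exceed its
#' threshold.
#'
#' @slot nFamilies number of families to simulate.
#' @slot sibProbs probability vector for 1, 2, ... siblings per family.
#' @slot ancestryPatterns list of 4-long grandparental ancestry vectors
#'   (values among `syrian`, `iranian`, `ashkenazi`, `other`).
#' @slot patternProbs sampling weights over `ancestryPatterns` (per family).
#' @slot alleleFreqs named numeric, per-variant carrier frequency.
#' @slot frdaNormalRange integer range of normal GAA allele lengths.
#' @slot frdaExpandedRange integer range of expanded GAA allele lengths.
#' @slot expansionCarrierProb carrier frequency of the GAA expansion.
#' @slot readLength single-end read length (bases).
#' @slot depthPerAmplicon mean (Poisson) read depth per amplicon.
#' @slot errorRate per-base substitution error rate.
#' @slot seed mandatory RNG seed.
#' @seealso [SimConfig()], [simulateCohort()], [simulateReads()]
#' @export
setClass("SimConfig",
         representation(nFamilies = "integer", sibProbs = "numeric",
                        ancestryPatterns = "list", patternProbs = "numeric",
                        alleleFreqs = "numeric", frdaNormalRange = "integer",
                        frdaExpandedRange = "integer",
                        expansionCarrierProb = "numeric",
                        readLength = "integer", depthPerAmplicon = "numeric",
                        errorRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  probs <- c(object@sibProbs, object@patternProbs, object@alleleFreqs,
             object@expansionCarrierProb, object@errorRate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    return("all probabilities must lie in [0, 1]")
  if (object@nFamilies < 0) return("nFamilies must be >= 0")
  if (!all(vapply(object@ancestryPatterns, length, 1L) == 4))
    return("each ancestry pattern must list exactly 4 grandparents")
  if (length(object@patternProbs) != length(object@ancestryPatterns))
    return("patternProbs must match ancestryPatterns")
  if (object@readLength < 3L * 36L + 2L * 20L)
    return("readLength must be >= 148 (35+ countable triplets plus anchors)")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("a scalar seed is mandatory")
  if (diff(object@frdaNormalRange) < 0 || diff(object@frdaExpandedRange) < 0 ||
      any(c(object@frdaNormalRange, object@frdaExpandedRange) < 1))
    return("FRDA allele ranges must be increasing and >= 1")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFamilies, "families,",
      length(object@alleleFreqs), "panel variants, depth",
      object@depthPerAmplicon, "x, read length", object@readLength,
      "bp, error", object@errorRate, ", seed", object@seed, "\n")
})

#' SimulatedCohort: ground truth for a simulated screening cohort
#'
#' @slot individuals data.frame: `sample_id`, `family_id`, `gp1`..`gp4`
#'   (grandparental ancestries).
#' @slot genotypes integer matrix (samples x variants) of alt-allele copies.
#' @slot frdaAlleles integer matrix (samples x 2) of GAA repeat lengths.
#' @aliases individuals truthGenotypes frdaAlleles
#' @seealso [simulateCohort()]
#' @export
setClass("SimulatedCohort",
         representation(individuals = "data.frame", genotypes = "matrix",
                        frdaAlleles = "matrix"))

setValidity("SimulatedCohort", function(object) {
  n <- nrow(object@individuals)
  if (nrow(object@genotypes) != n || nrow(object@frdaAlleles) != n)
    return("truth matrices must have one row per individual")
  if (n && any(object@frdaAlleles < 1))
    return("GAA allele lengths must be >= 1")
  if (!all(c("sample_id", "family_id", paste0("gp", 1:4)) %in%
           colnames(object@individuals)))
    return("individuals must have sample_id, family_id, gp1..gp4")
  TRUE
})

#' @describeIn SimulatedCohort-class the individual table.
#' @export
setMethod("individuals", "SimulatedCohort", function(x) x@individuals)

#' @describeIn SimulatedCohort-class samples x variants matrix of alt copies.
#' @export
setMethod("truthGenotypes", "SimulatedCohort", function(x) x@genotypes)

#' @describeIn SimulatedCohort-class samples x 2 matrix of GAA allele lengths.
#' @export
setMethod("frdaAlleles", "SimulatedCohort", function(x) x@frdaAlleles)

#' @describeIn SimulatedCohort-class number of individuals.
#' @param x a `SimulatedCohort`.
#' @export
setMethod("length", "SimulatedCohort", function(x) nrow(x@individuals))

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort:", nrow(object@individuals), "individuals in",
      length(unique(object@individuals$family_id)), "families;",
      ncol(object@genotypes), "panel variants\n")
})

#' RepeatReadStats: per-sample GAA repeat evidence
#'
#' Collected over the repeat-bearing reads of one sample: the GAA triplet
#' count of each such read (its repeat-per-read frequency, RPRF).  The
#' summary statistics are derived on access so they can never disagree with
#' the per-read counts: `repeatReadCount()` is the number of repeat-bearing
#' reads, `totalRepeats()` their summed triplet counts, and `top3Rprf()`
#' the three largest per-read counts in descending order.
#'
#' @slot sampleId sample identifier.
#' @slot perReadRepeats integer vector of per-read GAA triplet counts.
#' @aliases perReadRepeats repeatReadCount totalRepeats top3Rprf
#' @seealso [collectRepeatStats()], [callFrda()]
#' @export
setClass("RepeatReadStats",
         representation(sampleId = "character", perReadRepeats = "integer"))

setValidity("RepeatReadStats", function(object) {
  if (length(object@sampleId) != 1) return("sampleId must be a scalar")
  if (length(object@perReadRepeats) && any(object@perReadRepeats < 1))
    return("per-read repeat counts must be positive")
  TRUE
})

#' @describeIn RepeatReadStats-class per-read GAA triplet counts.
#' @export
setMethod("perReadRepeats", "RepeatReadStats", function(x) x@perReadRepeats)

#' @describeIn RepeatReadStats-class number of repeat-bearing reads.
#' @export
setMethod("repeatReadCount", "RepeatReadStats", function(x) length(x@perReadRepeats))

#' @describeIn RepeatReadStats-class summed GAA triplets over repeat reads.
#' @export
setMethod("totalRepeats", "RepeatReadStats", function(x) sum(x@perReadRepeats))

#' @describeIn RepeatReadStats-class the up-to-3 largest per-read counts,
#'   descending.
#' @export
setMethod("top3Rprf", "RepeatReadStats", function(x) {
  s <- sort(x@perReadRepeats, decreasing = TRUE)
  s[seq_len(min(3L, length(s)))]
})

setMethod("show", "RepeatReadStats", function(object) {
  cat("RepeatReadStats for", object@sampleId, ":",
      repeatReadCount(object), "repeat reads,",
      totalRepeats(object), "total GAA triplets, top3 RPRF [",
      paste(top3Rprf(object), collapse = ", "), "]\n")
})

#' FrdaCall: carrier decision for the FXN GAA expansion
#'
#' A sample is called a carrier when at least two of its top-3
#' repeat-per-read frequencies strictly exceed the threshold (default 35
#' GAA triplets); anything with fewer than two such reads is a non-carrier.
#'
#' @slot sampleId sample identifier.
#' @slot carrier logical carrier decision.
#' @slot top3Rprf the top-3 per-read repeat counts used.
#' @slot threshold the GAA triplet threshold applied.
#' @aliases isCarrier
#' @seealso [callFrda()]
#' @export
setClass("FrdaCall",
         representation(sampleId = "character", carrier = "logical",
                        top3Rprf = "integer", threshold = "integer"))

setValidity("FrdaCall", function(object) {
  expect <- sum(object@top3Rprf > object@threshold) >= 2
  if (!identical(expect, object@carrier))
    return("carrier flag inconsistent with the top-2 RPRF rule")
  TRUE
})

#' @describeIn FrdaCall-class logical carrier decision.
#' @export
setMethod("isCarrier", "FrdaCall", function(x) x@carrier)

#' @describeIn FrdaCall-class per-read repeat counts behind the call.
#' @export
setMethod("top3Rprf", "FrdaCall", function(x) x@top3Rprf)

setMethod("show", "FrdaCall", function(object) {
  cat("FrdaCall", object@sampleId, ":",
      if (object@carrier) "CARRIER" else "non-carrier",
      "(top3 RPRF [", paste(object@top3Rprf, collapse = ", "),
      "], threshold", object@threshold, ")\n")
})

#' CarrierScreenExperiment: cohort genotyping results
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one row per
#' panel variant (including the FXN expansion row) and one column per
#' sample.  Assays: `genotype` (alt-allele copies 0/1/2, `NA` = no call),
#' `refDepth`, `altDepth`, `otherDepth`.  Per-sample repeat-expansion
#' evidence (repeat read count, total repeats, top-3 RPRF, carrier call)
#' lives in `colData`; genotyping thresholds and the seed are recorded in
#' `metadata`.
#'
#' @aliases genotypeCalls frdaCalls
#' @seealso [screenReads()], [screenCohort()], [estimateCarrierFrequencies()]
#' @export
setClass("CarrierScreenExperiment", contains = "RangedSummarizedExperiment")

setValidity("CarrierScreenExperiment", function(object) {
  need <- c("genotype", "refDepth", "altDepth", "otherDepth")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss)) return(paste("missing assays:", paste(miss, collapse = ", ")))
  TRUE
})

#' @describeIn CarrierScreenExperiment-class variants x samples matrix of
#'   called alt-allele copies (`NA` = no call).
#' @export
setMethod("genotypeCalls", "CarrierScreenExperiment", function(x)
  SummarizedExperiment::assay(x, "genotype"))

#' @describeIn CarrierScreenExperiment-class per-sample FXN expansion
#'   evidence and carrier decisions (data.frame).
#' @export
setMethod("frdaCalls", "CarrierScreenExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  as.data.frame(cd[, grep("^(sample_id$|frda_|rprf_)", colnames(cd))])
})

setMethod("show", "CarrierScreenExperiment", function(object) {
  cat("CarrierScreenExperiment:", nrow(object), "variants x",
      ncol(object), "samples\n")
  methods::callNextMethod()
})
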