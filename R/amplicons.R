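#' Build synthetic amplicon references for a variant panel
#'
#' Multiplex PCR amplifies one short target region per panel variant.  The
#' true hg38 amplicon sequences are not shipped; instead each genotypable
#' variant receives a synthetic amplicon: `flankLen` random bases on either
#' side of the embedded ref allele, generated deterministically from
#' `seed`.  The screening algorithms (k-mer assignment, alignment,
#' windowed allele classification, GAA run counting) depend only on
#' sequence-content invariants that the generator enforces: flanks carry no
#' GAA run of four or more triplets, so only the repeat-locus amplicon
#' shares k-mers with GAA-bearing reads.
#'
#' If the panel contains the FXN GAA expansion record, a repeat-locus
#' amplicon `left-flank + (GAA)x`fxnTractUnits` + right-flank` is added and
#' its flanks (tract removed) become the [DecoyReference-class] flank.
#'
#' @param panel a [VariantPanel-class]; non-genotypable records (CNV,
#'   expansion) get no SNV/indel amplicon.
#' @param flankLen bases of synthetic flank on each side of the variant.
#' @param fxnTractUnits GAA units embedded in the repeat-locus reference.
#' @param anchorLen flank anchor length for split-read classification.
#' @param seed RNG seed for flank generation (fixed default so every
#'   session builds byte-identical references).
#' @return an [AmpliconPanel-class].
#' @examples
#' panel <- readPanelManifest(screeningFixture("manifest"))
#' amps <- buildAmpliconPanel(panel)
#' amps
#' @export
buildAmpliconPanel <- function(panel, flankLen = 180L, fxnTractUnits = 30L,
                               anchorLen = 20L, seed = 20210720L) {
  stopifnot(methods::is(panel, "VariantPanel"))
  mc <- S4Vectors::mcols(panel)
  geno <- isGenotypable(panel)
  withr::with_seed(seed, {
    ids <- mc$variant_id[geno]
    refs <- mc$ref[geno]
    alts <- mc$alt[geno]
    ampIds <- sprintf("amp_%03d", seq_along(ids))
    seqs <- character(length(ids))
    for (i in seq_along(ids)) {
      seqs[i] <- paste0(.noGaaDna(flankLen), refs[i], .noGaaDna(flankLen))
    }
    vdf <- data.frame(variant_id = ids, amplicon_id = ampIds,
                      offset = rep(as.integer(flankLen), length(ids)),
                      ref = refs, alt = alts, stringsAsFactors = FALSE)
    fxn <- NA_character_
    if (any(mc$type == "expansion")) {
      fxn <- "amp_FXN"
      left <- .noGaaDna(flankLen)
      right <- .noGaaDna(flankLen)
      seqs <- c(seqs, paste0(left, strrep("GAA", fxnTractUnits), right))
      ampIds <- c(ampIds, fxn)
      decoy <- methods::new("DecoyReference",
                            decoySeq = Biostrings::DNAString(strrep("GAA", 83L)),
                            flankSeq = Biostrings::DNAString(paste0(left, right)),
                            anchorLen = as.integer(anchorLen))
    } else {
      decoy <- DecoyReference(anchorLen = anchorLen)
    }
  })
  targets <- Biostrings::DNAStringSet(seqs)
  names(targets) <- ampIds
  methods::new("AmpliconPanel", targets = targets, variants = vdf,
               fxnAmplicon = fxn, decoy = decoy)
}

# classification windows around each panel site: the read subsequence
# spanning [offset - pad, offset + nchar(ref) - 1 + pad] must equal the
# ref or the alt haplotype exactly.  Window equality is invariant to
# equivalent gap placements within the window.
.variantWindows <- function(amps, pad = 10L) {
  v <- amps@variants
  seqs <- as.character(amps@targets)
  ampIdx <- match(v$amplicon_id, names(amps@targets))
  a <- v$offset - pad
  b <- v$offset + nchar(v$ref) - 1L + pad
  w <- nchar(seqs)[ampIdx]
  if (any(a < 0 | b >= w))
    .stopf("classification window exceeds amplicon bounds; increase flankLen")
  s <- seqs[ampIdx]
  refWin <- substr(s, a + 1L, b + 1L)
  altWin <- paste0(substr(s, a + 1L, v$offset),
                   v$alt,
                   substr(s, v$offset + nchar(v$ref) + 1L, b + 1L))
  data.frame(variant_id = v$variant_id, amp = ampIdx, winStart = a,
             winEnd = b, refWin = refWin, altWin = altWin,
             stringsAsFactors = FALSE)
}
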