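test_that("the shipped manifest loads with printed coordinates and categories", {
  panel <- fullPanel()
  expect_s4_class(panel, "VariantPanel")
  expect_length(panel, 40)
  expect_false(anyDuplicated(variantIds(panel)) > 0)
  col6a2 <- panel[variantIds(panel) == "COL6A2:c.1402C>T"]
  expect_equal(as.character(GenomicRanges::seqnames(col6a2)), "chr21")
  expect_equal(GenomicRanges::start(col6a2), 46121067)
  expect_equal(S4Vectors::mcols(col6a2)$ref, "C")
  expect_equal(S4Vectors::mcols(col6a2)$category, 1L)
  # variant typing drives which records are genotypable
  type <- variantType(panel)
  expect_equal(sum(type == "expansion"), 1)
  expect_equal(sum(type == "cnv"), 1)
  expect_equal(sum(isGenotypable(panel)), 38)
  # region record spans its printed interval
  trpm1 <- panel[variantIds(panel) == "TRPM1:36.8KB DEL"]
  expect_equal(GenomicRanges::end(trpm1) - GenomicRanges::start(trpm1) + 1L,
               36447L)
  # the 22 categorised variants use only categories 1-5
  cat <- S4Vectors::mcols(panel)$category
  expect_equal(sum(!is.na(cat)), 22)
  expect_true(all(cat[!is.na(cat)] %in% 1:5))
})

test_that("manifest parsing normalises chromosomes and rejects bad input", {
  hdr <- paste(c("variant_id", "chrom", "pos_hg38", "end_hg38", "ref", "alt",
                 "gene", "omim", "hgvs_c", "hgvs_p", "phenotype", "category"),
               collapse = "\t")
  row <- function(id, chrom = "21", pos = "100") paste(
    id, chrom, pos, "", "C", "T", "GENE", "1", "c.1C>T", "p.X", "PHENO", "1",
    sep = "\t")
  tmp <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c(hdr, row("V1", chrom = "21")), tmp)
  p <- readPanelManifest(tmp)
  expect_equal(as.character(GenomicRanges::seqnames(p)), "chr21")

  writeLines(hdr, tmp)                         # header only -> empty panel
  expect_length(readPanelManifest(tmp), 0)

  writeLines(c(hdr, row("V1"), row("V1")), tmp)
  expect_error(readPanelManifest(tmp), "duplicate variant_id")

  writeLines(c(hdr, "V1\tchr1"), tmp)          # truncated row
  expect_error(readPanelManifest(tmp), "line 2")

  writeLines(c(hdr, row("V1", pos = "zero")), tmp)
  expect_error(readPanelManifest(tmp), "position|line")
})

test_that("a manifest written and re-read is identical", {
  panel <- fullPanel()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writePanelManifest(panel, tmp)
  back <- readPanelManifest(tmp)
  expect_equal(variantIds(back), variantIds(panel))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(panel))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(panel))
  expect_equal(as.data.frame(S4Vectors::mcols(back)),
               as.data.frame(S4Vectors::mcols(panel)))
})

test_that("cohort tables parse k/n counts, ND entries, and validate", {
  t1 <- readCohortTable(screeningFixture("table1"),
                        c("syrian_full", "ashkenazi"))
  col6a2 <- t1[t1$variant_id == "COL6A2:c.1402C>T" &
               t1$population == "syrian_full", ]
  expect_equal(col6a2$carriers, 13)
  expect_equal(col6a2$n, 331)
  expect_equal(col6a2$percent_printed, 3.93)

  t3 <- readCohortTable(screeningFixture("table3"),
                        c("syrian_mixed", "iranian_mixed"))
  nd <- t3[t3$variant_id == "COL6A2:c.1402C>T" &
           t3$population == "iranian_mixed", ]
  expect_true(is.na(nd$carriers) && is.na(nd$n))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tgene\tphenotype\tpop\tpop_pct",
               "V1\tG\tP\t5/4\t125.00"), tmp)
  expect_error(readCohortTable(tmp, "pop"), "exceed")
  writeLines(c("variant_id\tgene\tphenotype\tpop\tpop_pct",
               "V1\tG\tP\t1/100\t9.99"), tmp)
  expect_warning(readCohortTable(tmp, "pop"), "deviates")
})

test_that("shipped frequency tables match the published table dimensions", {
  t1 <- readCohortTable(screeningFixture("table1"), "syrian_full")
  expect_equal(nrow(t1), 33)
  expect_equal(length(unique(t1$phenotype)), 25)
  t3 <- readCohortTable(screeningFixture("table3"), "syrian_mixed")
  expect_equal(nrow(t3), 22)
  expect_true(all(!is.na(t3$carriers)))        # mixed-Syrian column complete
  # both tables agree on the alleles of shared variants via the manifest
  panel <- fullPanel()
  expect_true(all(t1$variant_id %in% variantIds(panel)))
  expect_true(all(t3$variant_id %in% variantIds(panel)))
})
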