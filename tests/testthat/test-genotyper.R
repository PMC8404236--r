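test_that("reads assign to the amplicon sharing the most k-mers", {
  amps <- buildAmpliconPanel(subPanel(c("COL6A2:c.1402C>T", "GJB2:c.167del",
                                        "AGXT:c.731T>C")))
  seqs <- as.character(ampliconSeqs(amps))

  # exact prefix of an amplicon
  expect_equal(assignReadToAmplicon(substr(seqs[["amp_002"]], 1, 100), amps),
               "amp_002")

  # random sequence shares no k-mers
  withr::with_seed(1, {
    expect_true(is.na(assignReadToAmplicon(rdna(100), amps)))
  })

  # reads with 2 substitutions still assign, agreeing with a brute-force
  # shared-k-mer count against every amplicon
  withr::with_seed(42, {
    for (rep in 1:10) {
      src <- sample(names(seqs), 1)
      start <- sample(100, 1)
      read <- substr(seqs[[src]], start, start + 99)
      pos <- sample(100, 2)
      for (p in pos)
        substr(read, p, p) <- setdiff(c("A", "C", "G", "T"),
                                      substr(read, p, p))[sample(3, 1)]
      shared <- vapply(seqs, oracleKmerShared, integer(1), read = read, k = 15)
      best <- names(shared)[which.max(shared)]
      expect_equal(assignReadToAmplicon(read, amps, k = 15), best)
      expect_gte(max(shared), 3)
    }
  })

  expect_error(assignReadToAmplicon("ACGT", amps, k = 5), "k must be")
})

test_that("fit alignment scores match an independent affine aligner", {
  amps <- buildAmpliconPanel(subPanel("COL6A2:c.1402C>T"))
  ref <- as.character(ampliconSeqs(amps))[["amp_001"]]

  # identical window: all-match alignment at the right offset
  aln <- alignRead(substr(ref, 51, 110), ref)
  expect_equal(aln$score, 60)
  expect_equal(aln$ref_start, 50)
  expect_equal(aln$cigar, "60M")
  expect_false(aln$discarded)

  # one deleted base: cigar contains a 1-base deletion
  del <- paste0(substr(ref, 51, 80), substr(ref, 82, 111))
  aln <- alignRead(del, ref)
  expect_match(aln$cigar, "1D")
  expect_equal(aln$score, 60 - 3)

  # all-N reads score below the floor and are discarded
  expect_true(alignRead(strrep("N", 50), ref)$discarded)

  # random mutated reads: optimal score equals the Biostrings dynamic
  # programme under the same scoring scheme
  withr::with_seed(7, {
    for (rep in 1:20) {
      start <- sample(200, 1)
      read <- substr(ref, start, start + 59)
      # plant 0-2 substitutions and possibly a small indel
      for (p in sample(60, sample(0:2, 1)))
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      if (runif(1) < 0.5) {
        cut <- sample(20:40, 1)
        read <- if (runif(1) < 0.5)
          paste0(substr(read, 1, cut), substr(read, cut + sample(3, 1) + 1, 60))
        else paste0(substr(read, 1, cut), rdna(sample(3, 1)),
                    substr(read, cut + 1, 60))
      }
      expect_equal(alignRead(read, ref)$score, oracleAlignScore(read, ref))
    }
  })
})

test_that("pileup classification applies the depth and het-band thresholds", {
  # direct threshold rule
  calls <- callFromDepths(c(50, 52, 5, 2, 0), c(0, 48, 4, 48, 0))
  expect_equal(as.character(calls$genotype),
               c("hom_ref", "het", "no_call", "hom_alt", "no_call"))
  expect_equal(calls$alt_fraction[2], 0.48)
  expect_true(is.na(calls$alt_fraction[5]))
  expect_equal(as.character(callFromDepths(19, 62)$genotype), "het")
  expect_equal(as.character(callFromDepths(10, 40)$genotype), "het")  # 0.80
  expect_equal(as.character(callFromDepths(40, 10)$genotype), "het")  # 0.20

  # pileup over simulated reads at a deletion site (full alt string match)
  amps <- buildAmpliconPanel(subPanel(c("GJB2:c.167del", "FXN:GAA expansion")))
  ref <- as.character(ampliconSeqs(amps))[["amp_001"]]
  v <- amps@variants
  altHap <- paste0(substr(ref, 1, v$offset), v$alt,
                   substr(ref, v$offset + nchar(v$ref) + 1, nchar(ref)))
  withr::with_seed(11, {
    starts <- sample(30, 60, replace = TRUE) + 60   # all spanning the site
    reads <- c(substring(ref, starts[1:30], starts[1:30] + 249),
               substring(altHap, starts[31:60], starts[31:60] + 249))
  })
  aln <- alignRead(reads, ref)
  out <- pileupAndCall(reads, aln, ref, v$offset, v$ref, v$alt)
  expect_equal(out$genotype, "het")
  expect_equal(out$ref_depth, 30)
  expect_equal(out$alt_depth, 30)
  expect_equal(out$other_depth, 0)

  # informative depth below the minimum -> no call
  few <- pileupAndCall(reads[1:5], aln[1:5, ], ref, v$offset, v$ref, v$alt)
  expect_equal(few$genotype, "no_call")
})

test_that("error-free reads at moderate depth recover truth exactly", {
  # every indel representation in the panel plus two SNVs
  ids <- c("GJB2:c.167del", "CFTR:c.1521_1523del", "SMPD1:c.1826_1828GCC",
           "MMACHC:c.271dup", "USH2A:c.236_239dup", "DSE:c.387delC",
           "COL6A2:c.1402C>T", "AGXT:c.731T>C")
  sub <- subPanel(c(ids, "FXN:GAA expansion"))
  cfg <- quickConfig(setNames(rep(0.5, length(ids)), ids), seed = 31,
                     nFamilies = 25, depth = 35, error = 0)
  cohort <- simulateCohort(cfg)
  amps <- buildAmpliconPanel(sub)
  cse <- screenCohort(cohort, amps, cfg, panel = sub)
  gt <- t(genotypeCalls(cse))
  truth <- truthGenotypes(cohort)[, colnames(gt)[colnames(gt) %in% ids]]
  expect_equal(unname(gt[, colnames(truth)]), unname(truth))
  # FXN row agrees with allele-length truth
  expect_equal(unname(gt[, "FXN:GAA expansion"]),
               as.integer(rowSums(frdaAlleles(cohort) > 35) >= 1))
})

test_that("calls are invariant to read order", {
  ids <- c("COL6A2:c.1402C>T", "GJB2:c.167del")
  sub <- subPanel(c(ids, "FXN:GAA expansion"))
  cfg <- quickConfig(setNames(c(0.4, 0.4), ids), seed = 17, nFamilies = 10,
                     depth = 40, error = 0.003)
  cohort <- simulateCohort(cfg)
  amps <- buildAmpliconPanel(sub)
  reads <- simulateReads(cohort, amps, cfg)
  cse1 <- screenReads(reads, amps = amps, panel = sub)
  perm <- withr::with_seed(1, sample(length(reads)))
  cse2 <- screenReads(reads[perm], amps = amps, panel = sub)
  expect_identical(genotypeCalls(cse1), genotypeCalls(cse2))
  expect_identical(frdaCalls(cse1), frdaCalls(cse2))
})
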