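test_that("genotypes follow Hardy-Weinberg at the configured carrier frequency", {
  # zero carrier frequency -> nobody carries anything
  cfg0 <- quickConfig(c("COL6A2:c.1402C>T" = 0), seed = 3, nFamilies = 50)
  expect_true(all(truthGenotypes(simulateCohort(cfg0)) == 0L))

  # cf = 4%: het fraction within 3 binomial SDs of 2q(1-q), q = 1-sqrt(1-cf)
  cfg <- quickConfig(c("COL6A2:c.1402C>T" = 0.04), seed = 4,
                     nFamilies = 10000L, sibProbs = 1)
  gt <- truthGenotypes(simulateCohort(cfg))
  q <- 1 - sqrt(1 - 0.04)
  pHet <- 2 * q * (1 - q)
  expect_lt(abs(mean(gt == 1L) - pHet), 3 * sqrt(pHet * (1 - pHet) / nrow(gt)))
  pHom <- q^2
  expect_lt(abs(mean(gt == 2L) - pHom), 4 * sqrt(pHom * (1 - pHom) / nrow(gt)))
})

test_that("cohorts are deterministic and siblings share family structure", {
  cfg <- quickConfig(c("GJB2:c.167del" = 0.1), seed = 9, nFamilies = 200L,
                     sibProbs = c(0.5, 0.3, 0.2))
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(individuals(c1), individuals(c2))
  expect_identical(truthGenotypes(c1), truthGenotypes(c2))
  expect_identical(frdaAlleles(c1), frdaAlleles(c2))
  # all siblings of a family carry the same four grandparental ancestries
  ind <- individuals(c1)
  gpKey <- paste(ind$gp1, ind$gp2, ind$gp3, ind$gp4)
  expect_true(all(tapply(gpKey, ind$family_id,
                         function(x) length(unique(x))) == 1))
})

test_that("expansion-carrier truth is binomially consistent with the config", {
  p <- 0.1
  cfg <- quickConfig(c("COL6A2:c.1402C>T" = 0), seed = 21,
                     nFamilies = 5000L, sibProbs = 1, expansionProb = p)
  fa <- frdaAlleles(simulateCohort(cfg))
  isCarrierTruth <- rowSums(fa > 35) >= 1
  # individual-level carrier prob = 1-(1-qe)^2 = p by the HWE inversion
  expect_lt(abs(mean(isCarrierTruth) - p), 3 * sqrt(p * (1 - p) / nrow(fa)))
  expect_true(all(fa >= 1))
})

test_that("simulated reads carry the configured allele content", {
  ids <- c("COL6A2:c.1402C>T")
  amps <- buildAmpliconPanel(subPanel(c(ids, "FXN:GAA expansion")))
  ampSeq <- as.character(ampliconSeqs(amps))[["amp_001"]]

  # hom-ref everywhere, no errors -> every read is an exact substring
  cfg <- quickConfig(c("COL6A2:c.1402C>T" = 0), seed = 5, nFamilies = 3,
                     depth = 30)
  cohort <- simulateCohort(cfg)
  reads <- simulateReads(cohort, amps, cfg)
  onAmp <- assignReadToAmplicon(reads, amps) == "amp_001"
  expect_gt(sum(onAmp, na.rm = TRUE), 0)
  expect_true(all(vapply(reads[which(onAmp)], grepl, logical(1), x = ampSeq,
                         fixed = TRUE)))

  # a forced het: alt reads at expected fraction 0.5
  cohort@genotypes[, 1] <- 1L
  reads <- simulateReads(cohort, amps, cfg, samples = 1)
  alt <- paste0(substr(ampSeq, 171, 180), "T", substr(ampSeq, 182, 191))
  ref <- substr(ampSeq, 171, 191)
  nAlt <- sum(grepl(alt, reads, fixed = TRUE))
  nRef <- sum(grepl(ref, reads, fixed = TRUE))
  expect_gt(nAlt + nRef, 10)
  expect_lt(abs(nAlt / (nAlt + nRef) - 0.5),
            3 * sqrt(0.25 / (nAlt + nRef)) + 1e-9)

  # depth 0 -> no reads at all
  cfg0 <- quickConfig(c("COL6A2:c.1402C>T" = 0.5), seed = 6, nFamilies = 2,
                      depth = 0)
  expect_length(simulateReads(simulateCohort(cfg0), amps, cfg0), 0)
})

test_that("only expanded alleles yield GAA runs beyond the decision threshold", {
  amps <- buildAmpliconPanel(subPanel("FXN:GAA expansion"))
  cfg <- quickConfig(c("COL6A2:c.1402C>T" = 0), seed = 8, nFamilies = 1,
                     depth = 80)
  carrier <- frdaCohort(cbind(20, 300))
  runs <- countGaaRepeats(simulateReads(carrier, amps, cfg))
  expect_gt(max(runs), 35)                  # interior reads are pure repeat
  nonCarrier <- frdaCohort(cbind(20, 21))
  runs0 <- countGaaRepeats(simulateReads(nonCarrier, amps, cfg))
  expect_lte(max(runs0), 21)                # capped by the tract itself
  expect_gt(max(runs0), 0)
})
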