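test_that("ancestry classification follows the grandparent-count rule", {
  expect_equal(classifyAncestry(rep("syrian", 4), "syrian"), "full")
  expect_equal(classifyAncestry(c("syrian", "ashkenazi", "ashkenazi",
                                  "ashkenazi"), "syrian"), "mixed")
  expect_equal(classifyAncestry(rep("ashkenazi", 4), "syrian"), "ineligible")
  m <- rbind(rep("iranian", 4), c("iranian", "other", "other", "other"))
  expect_equal(classifyAncestry(m, "iranian"), c("full", "mixed"))
  expect_error(classifyAncestry(c("syrian", "syrian"), "syrian"), "exactly 4")
})

test_that("sibling deduplication keeps exactly one random sibling per family", {
  ind <- data.frame(sample_id = paste0("s", 1:6),
                    family_id = c("f1", "f1", "f1", "f2", "f3", "f3"),
                    stringsAsFactors = FALSE)
  sel <- selectUnrelated(ind, seed = 1)
  expect_equal(nrow(sel), 3)
  expect_equal(sort(unique(sel$family_id)), c("f1", "f2", "f3"))
  expect_true("s4" %in% sel$sample_id)               # singleton always kept
  expect_identical(sel, selectUnrelated(ind, seed = 1))

  # property: never two rows from one family, across random structures
  withr::with_seed(202, {
    for (i in 1:50) {
      fam <- sample(sprintf("f%02d", 1:12), 40, replace = TRUE)
      d <- data.frame(sample_id = paste0("x", 1:40), family_id = fam)
      out <- selectUnrelated(d, seed = i)
      expect_false(any(duplicated(out$family_id)))
      expect_equal(nrow(out), length(unique(fam)))
    }
  })

  # cohort objects are subset together with their truth
  cfg <- quickConfig(c("COL6A2:c.1402C>T" = 0.3), seed = 2, nFamilies = 30,
                     sibProbs = c(0.4, 0.4, 0.2))
  cohort <- simulateCohort(cfg)
  one <- selectUnrelated(cohort, seed = 3)
  expect_s4_class(one, "SimulatedCohort")
  expect_equal(length(one), 30)
  i <- match(individuals(one)$sample_id, individuals(cohort)$sample_id)
  expect_equal(truthGenotypes(one), truthGenotypes(cohort)[i, , drop = FALSE])
})

test_that("carrier frequencies reproduce printed percents and Wilson CIs", {
  expect_equal(carrierFrequency(13, 331)$percent, 3.93)
  expect_equal(carrierFrequency(0, 3401)$percent, 0.00)
  expect_equal(carrierFrequency(120, 3147)$percent, 3.81)
  one <- carrierFrequency(1, 1)
  expect_equal(one$percent, 100)
  expect_equal(one$ci_hi, 1)
  expect_error(carrierFrequency(1, 0), "positive")
  expect_error(carrierFrequency(5, 4), "carriers")

  # closed-form Wilson interval agrees with prop.test without correction
  for (k in c(0, 1, 13, 120)) {
    for (n in c(50, 331, 3147)) {
      if (k > n) next
      est <- carrierFrequency(k, n)
      ref <- stats::prop.test(k, n, correct = FALSE)$conf.int
      expect_equal(c(est$ci_lo, est$ci_hi), as.numeric(ref), tolerance = 1e-6)
      expect_true(est$ci_lo <= est$fraction && est$fraction <= est$ci_hi)
    }
  }

  # half-up rounding, as every printed table value requires
  expect_equal(roundHalfUp(c(0.005, 0.015, 0.0153, 0.00994), 2),
               c(0.01, 0.02, 0.02, 0.01))
})

test_that("gene aggregation and couple risk are order- and split-invariant", {
  t3 <- readCohortTable(screeningFixture("table3"), "syrian_mixed")
  est <- carrierFrequency(t3$carriers, t3$n, t3$variant_id)
  est$gene <- t3$gene
  gf <- aggregateByGene(est)
  expect_equal(unname(gf["ARSA"]), 2 / 3401)          # two variant rows summed
  expect_equal(unname(gf["GNE"]), 24 / 3401)          # single-variant gene
  expect_equal(unname(gf["DSE"]), 0)                  # zero-carrier gene

  expect_equal(coupleAtRiskProbability(c(G = 0.1)), 0.01)
  expect_equal(coupleAtRiskProbability(numeric(0)), 0)

  risk <- coupleAtRiskProbability(gf)
  perm <- withr::with_seed(4, sample(nrow(est)))
  expect_equal(coupleAtRiskProbability(aggregateByGene(est[perm, ])), risk)

  # splitting one gene's carriers across rows changes nothing
  split2 <- rbind(est, est[est$gene == "GNE", ])
  split2$fraction[split2$gene == "GNE"] <-
    est$fraction[est$gene == "GNE"] * c(0.25, 0.75)
  expect_equal(coupleAtRiskProbability(aggregateByGene(split2)), risk)

  # two-draw Monte-Carlo oracle on a small synthetic table
  gfSmall <- c(A = 0.2, B = 0.1)
  withr::with_seed(9, {
    nC <- 2e5
    p1a <- stats::runif(nC) < 0.2; p2a <- stats::runif(nC) < 0.2
    p1b <- stats::runif(nC) < 0.1; p2b <- stats::runif(nC) < 0.1
    mc <- mean((p1a & p2a) | (p1b & p2b))
  })
  exact <- coupleAtRiskProbability(gfSmall)
  # the sum-of-squares form ignores the tiny both-genes overlap (f_A^2*f_B^2)
  expect_lt(abs(mc - exact), 0.2^2 * 0.1^2 + 3 * sqrt(exact / nC))
})

test_that("any-carrier rate matches the independence prediction", {
  expect_equal(anyCarrierRate(matrix(0L, 5, 3)), 0)
  expect_equal(anyCarrierRate(diag(1L, 4)), 1)
  expect_equal(anyCarrierRate(matrix(integer(0), 0, 3)), 0)

  cfs <- c("COL6A2:c.1402C>T" = 0.05, "GJB2:c.167del" = 0.03,
           "AGXT:c.731T>C" = 0.02)
  cfg <- quickConfig(cfs, seed = 303, nFamilies = 8000L, sibProbs = 1)
  gt <- truthGenotypes(simulateCohort(cfg))
  pred <- 1 - prod(1 - cfs)
  expect_lt(abs(anyCarrierRate(gt) - pred),
            3 * sqrt(pred * (1 - pred) / nrow(gt)))
})

test_that("panel and sharing filters count variants and conditions", {
  t1 <- readCohortTable(screeningFixture("table1"),
                        c("syrian_full", "ashkenazi"))
  syr <- t1[t1$population == "syrian_full", ]
  est <- carrierFrequency(syr$carriers, syr$n, syr$variant_id)
  est$phenotype <- syr$phenotype

  f06 <- filterScreeningPanel(est, 0.6)
  expect_equal(f06$n_variants, 20)
  expect_equal(f06$n_phenotypes, 17)
  expect_equal(filterScreeningPanel(est, 100)$n_variants, 0)
  expect_equal(filterScreeningPanel(est, 0)$n_variants, 33)

  sh <- sharedWithPopulation(t1, "ashkenazi")
  expect_equal(sh$n_variants, 16)
  expect_equal(sh$n_phenotypes, 13)
  # raw nonzero counts are deliberately larger than the printed-percent rule
  expect_equal(sharedWithPopulation(t1, "ashkenazi", mode = "raw")$n_variants,
               19)
  zero <- t1[t1$population == "ashkenazi", ]
  zero$carriers <- 0L
  zero$population <- "z"
  expect_equal(sharedWithPopulation(zero, "z")$n_variants, 0)
})
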