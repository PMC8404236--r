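test_that("GAA run counting matches a brute-force scanner", {
  expect_equal(countGaaRepeats("GAAGAAGAA"), 3)
  expect_equal(countGaaRepeats(paste0("TT", strrep("GAA", 40), "CC")), 40)
  expect_equal(countGaaRepeats(paste0(strrep("GAA", 10), "T",
                                      strrep("GAA", 25))), 25)
  expect_equal(countGaaRepeats(c("", "T", "GA", "AAG", "AGA", "AAA")),
               c(0, 0, 0, 1, 1, 0))
  # phase offsets: a run entered mid-motif still counts its full triplets
  expect_equal(countGaaRepeats(paste0("AAG", strrep("GAA", 5))), 5)

  # property: random reads with planted runs, all phases and interruptions
  withr::with_seed(123, {
    for (i in 1:200) {
      parts <- c(rdna(sample(0:12, 1)),
                 substr(strrep("GAA", 15), sample(3, 1), 40 + sample(5, 1)),
                 rdna(sample(0:8, 1)),
                 strrep("GAA", sample(0:6, 1)),
                 rdna(sample(0:10, 1)))
      s <- paste(parts, collapse = "")
      expect_equal(countGaaRepeats(s), oracleGaaRun(s), info = s)
    }
  })
})

test_that("repeat reads classify as split, pure, or non-repeat", {
  ref <- DecoyReference()
  flank <- as.character(ref@flankSeq)
  anchor <- substr(flank, nchar(flank) - 29, nchar(flank))   # 30 bp of flank

  expect_equal(classifyRepeatRead(paste0(anchor, strrep("GAA", 50)), ref),
               "split_read")
  expect_equal(classifyRepeatRead(strrep("GAA", 83), ref), "pure_repeat")
  withr::with_seed(5, expect_equal(classifyRepeatRead(rdna(249), ref),
                                   "non_repeat"))

  # one mismatch inside the anchor is tolerated, two are not
  mis1 <- anchor
  substr(mis1, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mis1, 15, 15))[1]
  expect_equal(classifyRepeatRead(paste0(mis1, strrep("GAA", 50)), ref),
               "split_read")
  # a GAA run below the minimum is not repeat-bearing even with an anchor
  expect_equal(classifyRepeatRead(paste0(anchor, strrep("GAA", 3)), ref),
               "non_repeat")
  expect_equal(classifyRepeatRead(paste0(anchor, strrep("GAA", 4)), ref,
                                  minRepeats = 4), "split_read")
})

test_that("repeat statistics aggregate per-read counts deterministically", {
  ref <- DecoyReference()
  reads <- strrep("GAA", c(44, 41, 38, 12, 9))
  stats <- collectRepeatStats(reads, ref, sampleId = "S1")
  expect_equal(top3Rprf(stats), c(44, 41, 38))
  expect_equal(repeatReadCount(stats), 5)
  expect_equal(totalRepeats(stats), sum(c(44, 41, 38, 12, 9)))

  # read order never matters
  shuf <- collectRepeatStats(rev(reads), ref)
  expect_equal(top3Rprf(shuf), top3Rprf(stats))
  expect_equal(totalRepeats(shuf), totalRepeats(stats))

  # non-repeat reads contribute nothing
  expect_equal(repeatReadCount(collectRepeatStats(c("ACGT", ""), ref)), 0)
  expect_length(top3Rprf(collectRepeatStats(character(0), ref)), 0)
  expect_equal(top3Rprf(collectRepeatStats(strrep("GAA", 36), ref)), 36)
})

test_that("the carrier rule requires two reads strictly above the threshold", {
  ref <- DecoyReference()
  callFor <- function(counts) callFrda(collectRepeatStats(
    strrep("GAA", counts), ref, sampleId = "S"))
  expect_true(isCarrier(callFor(c(44, 41, 38))))
  expect_false(isCarrier(callFor(c(36, 30, 28))))
  expect_false(isCarrier(callFor(c(35, 35, 35))))   # boundary is non-carrier
  expect_true(isCarrier(callFor(c(36, 36, 10))))
  expect_false(isCarrier(callFor(integer(0))))      # no repeat reads at all

  # monotonicity: raising the threshold never converts non-carrier to carrier
  withr::with_seed(99, {
    for (i in 1:50) {
      stats <- collectRepeatStats(strrep("GAA", sample(4:80, 6, TRUE)), ref)
      carriers <- vapply(30:60, function(th)
        isCarrier(callFrda(stats, threshold = th)), logical(1))
      expect_true(all(diff(as.integer(carriers)) <= 0))
    }
  })
})

test_that("simulated expansions are detected through the read-level pipeline", {
  amps <- buildAmpliconPanel(subPanel("FXN:GAA expansion"))
  cfg <- quickConfig(c("COL6A2:c.1402C>T" = 0), seed = 77, nFamilies = 1,
                     depth = 50, error = 0.003)
  withr::with_seed(50, {
    carriers <- frdaCohort(cbind(sample(8:30, 10, TRUE),
                                 sample(70:1000, 10, TRUE)))
    normals <- frdaCohort(cbind(sample(8:30, 20, TRUE),
                                sample(8:30, 20, TRUE)))
  })
  cseC <- screenCohort(carriers, amps, cfg)
  cseN <- screenCohort(normals, amps, cfg)
  expect_true(all(frdaCalls(cseC)$frda_carrier))
  expect_false(any(frdaCalls(cseN)$frda_carrier))
  # evidence fields are consistent
  fc <- frdaCalls(cseC)
  expect_true(all(fc$rprf_1 >= fc$rprf_2, na.rm = TRUE))
  expect_true(all(fc$rprf_1 > 35))
})
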