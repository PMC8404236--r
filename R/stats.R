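#' Classify ancestry from the four grandparents
#'
#' Study eligibility follows grandparental origin: an individual is
#' `full` for the target ancestry when all four grandparents have it,
#' `mixed` when one to three do, and `ineligible` when none does.
#'
#' @param grandparents character vector of 4 ancestries, or an `n x 4`
#'   matrix / the `individuals()` table of a cohort.
#' @param target ancestry of interest (e.g. `"syrian"`).
#' @return character vector of `full` / `mixed` / `ineligible`.
#' @examples
#' classifyAncestry(c("syrian", "syrian", "syrian", "syrian"), "syrian")
#' classifyAncestry(c("syrian", "ashkenazi", "ashkenazi", "ashkenazi"), "syrian")
#' @export
classifyAncestry <- function(grandparents, target) {
  if (is.data.frame(grandparents))
    grandparents <- as.matrix(grandparents[, paste0("gp", 1:4)])
  if (!is.matrix(grandparents))
    grandparents <- matrix(grandparents, nrow = 1)
  if (ncol(grandparents) != 4)
    .stopf("exactly 4 grandparental ancestries are required")
  k <- rowSums(grandparents == target)
  c("ineligible", "mixed", "mixed", "mixed", "full")[k + 1L]
}

#' Select one sibling per family
#'
#' For families with two or more screened siblings, one is chosen
#' uniformly at random so the analysis cohort contains only unrelated
#' individuals; singletons are always retained.  Deterministic under the
#' seed.
#'
#' @param individuals data.frame with a `family_id` column (e.g.
#'   [individuals()] of a simulated cohort), or a
#'   [SimulatedCohort-class] (subset with its truth matrices).
#' @param seed RNG seed for the within-family draw.
#' @return the selected rows (same class as the input), one individual per
#'   family, in input order.
#' @export
selectUnrelated <- function(individuals, seed) {
  isCohort <- methods::is(individuals, "SimulatedCohort")
  ind <- if (isCohort) individuals(individuals) else individuals
  stopifnot("family_id" %in% colnames(ind))
  withr::with_seed(seed, {
    fam <- split(seq_len(nrow(ind)), ind$family_id)
    pick <- vapply(fam, function(i)
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)], integer(1))
  })
  rows <- sort(unname(pick))
  if (!isCohort) return(ind[rows, , drop = FALSE])
  methods::new("SimulatedCohort",
               individuals = ind[rows, , drop = FALSE],
               genotypes = individuals@genotypes[rows, , drop = FALSE],
               frdaAlleles = individuals@frdaAlleles[rows, , drop = FALSE])
}

.Z95 <- stats::qnorm(0.975)

# Wilson score interval, no continuity correction; bounds pinned exactly
# at the boundary counts so the interval always contains k/n
.wilson <- function(k, n, z = .Z95) {
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- (z / den) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  lo <- pmax(0, ctr - half)
  hi <- pmin(1, ctr + half)
  lo[k == 0] <- 0
  hi[k == n] <- 1
  cbind(lo = lo, hi = hi)
}

#' Carrier frequency point estimate with Wilson 95% CI
#'
#' @param carriers,n non-negative carrier count and positive cohort size
#'   (vectorised).
#' @param variant_id,population optional labels carried into the result.
#' @return data.frame with `variant_id`, `population`, `carriers`, `n`,
#'   `fraction`, `percent` (2 decimals, half-up, as the published tables
#'   print), `ci_lo`, `ci_hi`.
#' @examples
#' carrierFrequency(13, 331)$percent      # 3.93
#' carrierFrequency(120, 3147)$percent    # 3.81
#' @export
carrierFrequency <- function(carriers, n, variant_id = NA_character_,
                             population = NA_character_) {
  if (any(n <= 0)) .stopf("cohort size n must be positive")
  if (any(carriers < 0 | carriers > n)) .stopf("need 0 <= carriers <= n")
  ci <- .wilson(carriers, n)
  data.frame(variant_id = variant_id, population = population,
             carriers = carriers, n = n, fraction = carriers / n,
             percent = roundHalfUp(100 * carriers / n, 2),
             ci_lo = ci[, "lo"], ci_hi = ci[, "hi"],
             stringsAsFactors = FALSE)
}

#' Combine variant carrier fractions within genes
#'
#' Couples are at risk when both partners carry a pathogenic variant in
#' the same gene, so per-variant fractions are summed within each gene
#' (rare-variant approximation; missing entries count 0).
#'
#' @param estimates data.frame with `gene` and `fraction` columns
#'   ([carrierFrequency()] output rows for one population table).
#' @return named numeric vector of per-gene combined carrier fractions.
#' @export
aggregateByGene <- function(estimates) {
  stopifnot(all(c("gene", "fraction") %in% colnames(estimates)))
  f <- estimates$fraction
  f[is.na(f)] <- 0
  vapply(split(f, estimates$gene), sum, numeric(1))
}

#' At-risk couple probability
#'
#' Under random mating, the probability that both partners carry a
#' variant in the same screened gene is `sum_g f_g^2` over the per-gene
#' carrier fractions `f_g`.
#'
#' @param geneFractions named numeric vector (see [aggregateByGene()]).
#' @return the probability (multiply by 1e4 for couples per 10,000).
#' @examples
#' couplesAtRisk <- coupleAtRiskProbability(c(GENE1 = 0.1))  # 0.01
#' @export
coupleAtRiskProbability <- function(geneFractions) {
  if (!length(geneFractions)) return(0)
  if (any(geneFractions < 0 | geneFractions > 1))
    .stopf("gene fractions must lie in [0, 1]")
  sum(geneFractions^2)
}

#' Fraction of individuals carrying at least one panel variant
#'
#' @param x a samples x variants genotype matrix (alt copies, `NA` = no
#'   call) or a [CarrierScreenExperiment-class].
#' @return fraction of individuals with >= 1 het or hom-alt call.
#' @export
anyCarrierRate <- function(x) {
  if (methods::is(x, "CarrierScreenExperiment")) x <- t(genotypeCalls(x))
  if (!nrow(x)) return(0)
  mean(rowSums(x >= 1L, na.rm = TRUE) > 0)
}

#' Filter a frequency table to the recommended screening panel
#'
#' Retains variants whose carrier percent strictly exceeds the threshold
#' (default 0.6%), the frequency bar above which premarital screening is
#' recommended, and counts the variants and the distinct phenotype strings
#' (conditions) they underlie.
#'
#' @param estimates data.frame with `percent`, `phenotype` and
#'   `variant_id` columns.
#' @param thresholdPercent retention threshold in percent.
#' @return list with `n_variants`, `n_phenotypes` and the retained
#'   `subset`.
#' @export
filterScreeningPanel <- function(estimates, thresholdPercent = 0.6) {
  stopifnot(thresholdPercent >= 0,
            all(c("percent", "phenotype") %in% colnames(estimates)))
  keep <- !is.na(estimates$percent) & estimates$percent > thresholdPercent
  sub <- estimates[keep, , drop = FALSE]
  list(n_variants = nrow(sub),
       n_phenotypes = length(unique(sub$phenotype)),
       subset = sub)
}

#' Variants shared with a comparison population
#'
#' Counts panel variants "present" in a comparison population.  The
#' default mode mirrors the published tables: a variant counts when its
#' carrier frequency, rounded half-up to two decimals as a percent,
#' exceeds 0.00 (so singleton carriers in very large cohorts, printing as
#' 0.00%, do not count).  `mode = "raw"` instead counts any nonzero
#' carrier count.
#'
#' @param table long cohort table ([readCohortTable()] output).
#' @param population population column to test.
#' @param mode `"rounded"` (printed-percent filter) or `"raw"`.
#' @return list with `n_variants` and `n_phenotypes` of the shared subset.
#' @export
sharedWithPopulation <- function(table, population, mode = c("rounded", "raw")) {
  mode <- match.arg(mode)
  rows <- table[table$population == population & !is.na(table$carriers), ,
                drop = FALSE]
  pct <- roundHalfUp(100 * rows$carriers / rows$n, 2)
  keep <- if (mode == "rounded") pct > 0 else rows$carriers > 0
  list(n_variants = sum(keep),
       n_phenotypes = length(unique(rows$phenotype[keep])))
}

#' Screening report for one population column of a cohort table
#'
#' Recomputes per-variant frequencies (with Wilson CIs), per-gene combined
#' fractions, the at-risk couple probability, the screening-panel filter
#' and, optionally, sharing with a comparison population, from one
#' population column of a published-style cohort table.
#'
#' @param table long cohort table ([readCohortTable()] output).
#' @param population population column to report on.
#' @param panelThresholdPercent screening-panel retention threshold.
#' @param comparePopulation optional population for the sharing filter.
#' @return list: `population`, `estimates`, `gene_fractions`,
#'   `couple_risk` (probability), `couple_risk_percent` (2 dp),
#'   `panel_filter`, `sharing` (or `NULL`).
#' @export
screeningReport <- function(table, population, panelThresholdPercent = 0.6,
                            comparePopulation = NULL) {
  rows <- table[table$population == population & !is.na(table$carriers), ,
                drop = FALSE]
  est <- carrierFrequency(rows$carriers, rows$n, rows$variant_id, population)
  est$gene <- rows$gene
  est$phenotype <- rows$phenotype
  gf <- aggregateByGene(est)
  risk <- coupleAtRiskProbability(gf)
  list(population = population,
       estimates = est,
       gene_fractions = gf,
       couple_risk = risk,
       couple_risk_percent = roundHalfUp(100 * risk, 2),
       panel_filter = filterScreeningPanel(est, panelThresholdPercent),
       sharing = if (!is.null(comparePopulation))
         sharedWithPopulation(table, comparePopulation))
}

.checkFixtures <- function(fixtureDir = NULL) {
  for (nm in names(.FIXTURE_MD5)) {
    path <- if (is.null(fixtureDir))
      system.file("extdata", nm, package = "ampliscreen")
    else file.path(fixtureDir, nm)
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.FIXTURE_MD5[[nm]])))
      .stopf("fixture checksum mismatch for %s (got %s)", nm, got)
  }
  invisible(TRUE)
}

#' Recompute the published panel statistics from the shipped fixtures
#'
#' Re-derives, from the packaged frequency tables, every published
#' statistic the fixtures determine: all printed carrier percentages, the
#' 100%-Syrian table size (33 variants, 25 conditions), the >0.6%
#' screening-panel filter (20 variants, 17 conditions), the
#' Ashkenazi-sharing filter (16 variants, 13 conditions) and the mixed
#' Syrian at-risk couple probability (0.06%).  The full-Syrian couple
#' risk is reported without an expectation: its published aggregation over
#' heterogeneous per-variant denominators is not recoverable from the
#' table, so the package states its own value under the
#' [aggregateByGene()] rule.  Fixture checksums are verified first.
#'
#' @param path optional JSON output path.
#' @param table `"both"`, `"1"` or `"3"`: which fixture tables to
#'   recompute.
#' @param fixtureDir override directory holding the fixture TSVs (for
#'   checksum-verified copies; default: the installed package fixtures).
#' @return a list of named checks, each with `value`, `expected` (`NA`
#'   when the package reports without asserting) and `pass`; plus the
#'   underlying reports.  Written as JSON when `path` is given.
#' @export
reproducePanelReport <- function(path = NULL, table = c("both", "1", "3"),
                                 fixtureDir = NULL) {
  table <- match.arg(table)
  .checkFixtures(fixtureDir)
  fixture <- function(name)
    if (is.null(fixtureDir)) screeningFixture(name)
    else file.path(fixtureDir, paste0(if (name == "manifest")
      "panel_manifest" else name, ".tsv"))
  checks <- list()
  add <- function(name, value, expected = NA_real_) {
    checks[[name]] <<- list(value = value, expected = expected,
                            pass = if (is.na(expected)) NA else
                              isTRUE(all.equal(value, expected)))
  }
  out <- list()
  if (table %in% c("both", "1")) {
    t1 <- readCohortTable(fixture("table1"),
                          c("syrian_full", "ashkenazi"))
    live <- !is.na(t1$carriers)
    add("table1_percent_mismatches",
        sum(roundHalfUp(100 * t1$carriers[live] / t1$n[live], 2) !=
            t1$percent_printed[live]), 0)
    syr <- screeningReport(t1, "syrian_full", comparePopulation = "ashkenazi")
    add("table1_n_variants", sum(t1$population == "syrian_full"), 33)
    add("table1_n_phenotypes",
        length(unique(t1$phenotype[t1$population == "syrian_full"])), 25)
    add("panel_filter_variants", syr$panel_filter$n_variants, 20)
    add("panel_filter_phenotypes", syr$panel_filter$n_phenotypes, 17)
    add("ashkenazi_shared_variants", syr$sharing$n_variants, 16)
    add("ashkenazi_shared_phenotypes", syr$sharing$n_phenotypes, 13)
    add("full_syrian_couple_risk_percent", syr$couple_risk_percent)
    out$table1 <- syr
  }
  if (table %in% c("both", "3")) {
    t3 <- readCohortTable(fixture("table3"),
                          c("syrian_mixed", "iranian_mixed", "ashkenazi"))
    live <- !is.na(t3$carriers)
    add("table3_percent_mismatches",
        sum(roundHalfUp(100 * t3$carriers[live] / t3$n[live], 2) !=
            t3$percent_printed[live]), 0)
    add("table3_n_variants", sum(t3$population == "syrian_mixed"), 22)
    mix <- screeningReport(t3, "syrian_mixed")
    add("mixed_syrian_couple_risk_percent", mix$couple_risk_percent, 0.06)
    out$table3 <- mix
  }
  out$checks <- checks
  hard <- vapply(checks, function(x) isFALSE(x$pass), logical(1))
  out$all_pass <- !any(hard)
  if (!is.null(path)) {
    jsonlite::write_json(
      list(checks = checks, all_pass = out$all_pass), path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    return(invisible(out))
  }
  out
}
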