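#' Construct a simulation configuration
#'
#' Defaults reflect the screening setting the package models: a cohort of
#' families with mostly one or two screened siblings, predominantly mixed
#' Syrian grandparental ancestry, per-variant carrier frequencies taken
#' from the mixed-Syrian column of the packaged frequency table, normal
#' GAA alleles uniform on 8-30 triplets, expanded carrier alleles uniform
#' on 70-1000 triplets, 250 bp single-end reads at 100x mean amplicon
#' depth and a 0.3% substitution error rate.
#'
#' @param nFamilies number of families.
#' @param sibProbs probabilities of 1, 2, ... screened siblings per family.
#' @param ancestryPatterns list of 4-long grandparental ancestry vectors.
#' @param patternProbs per-family sampling weights over the patterns.
#' @param alleleFreqs named per-variant carrier frequencies; default: the
#'   mixed-Syrian frequencies of the packaged table (genotypable variants).
#' @param frdaNormalRange,frdaExpandedRange GAA allele length ranges
#'   (triplets) for normal and expanded alleles.
#' @param expansionCarrierProb carrier frequency of the GAA expansion;
#'   default: the mixed-Syrian value of the packaged table.
#' @param readLength,depthPerAmplicon,errorRate sequencing model.
#' @param seed mandatory RNG seed.
#' @return a [SimConfig-class].
#' @examples
#' cfg <- SimConfig(nFamilies = 50, seed = 1)
#' cfg
#' @export
SimConfig <- function(nFamilies = 100L,
                      sibProbs = c(0.70, 0.20, 0.07, 0.03),
                      ancestryPatterns = list(
                        full_syrian = rep("syrian", 4),
                        mixed_syrian_half = c("syrian", "syrian", "ashkenazi", "other"),
                        mixed_syrian_quarter = c("syrian", "other", "other", "other"),
                        mixed_iranian = c("iranian", "iranian", "other", "other"),
                        other = rep("other", 4)),
                      patternProbs = c(0.10, 0.35, 0.25, 0.20, 0.10),
                      alleleFreqs = NULL,
                      frdaNormalRange = c(8L, 30L),
                      frdaExpandedRange = c(70L, 1000L),
                      expansionCarrierProb = NULL,
                      readLength = 250L, depthPerAmplicon = 100,
                      errorRate = 0.003, seed) {
  if (missing(seed)) .stopf("SimConfig requires an explicit seed")
  if (is.null(alleleFreqs) || is.null(expansionCarrierProb)) {
    t3 <- readCohortTable(screeningFixture("table3"), "syrian_mixed")
    cf <- t3$carriers / t3$n
    names(cf) <- t3$variant_id
    if (is.null(expansionCarrierProb))
      expansionCarrierProb <- unname(cf["FXN:GAA expansion"])
    if (is.null(alleleFreqs))
      alleleFreqs <- cf[names(cf) != "FXN:GAA expansion"]
  }
  methods::new("SimConfig",
               nFamilies = as.integer(nFamilies), sibProbs = sibProbs,
               ancestryPatterns = ancestryPatterns, patternProbs = patternProbs,
               alleleFreqs = alleleFreqs,
               frdaNormalRange = as.integer(frdaNormalRange),
               frdaExpandedRange = as.integer(frdaExpandedRange),
               expansionCarrierProb = expansionCarrierProb,
               readLength = as.integer(readLength),
               depthPerAmplicon = depthPerAmplicon,
               errorRate = errorRate, seed = as.integer(seed))
}

# carrier frequency -> allele frequency under Hardy-Weinberg:
# cf = 1 - (1-q)^2  =>  q = 1 - sqrt(1 - cf)
.alleleFreq <- function(cf) 1 - sqrt(1 - cf)

#' Simulate a screening cohort with ground truth
#'
#' Families receive a shared grandparental ancestry pattern and 1+
#' siblings; each individual draws an independent Hardy-Weinberg genotype
#' at every panel variant (`P(het) = 2q(1-q)`, `P(hom alt) = q^2` with
#' `q = 1 - sqrt(1 - cf)`), and two FXN GAA allele lengths (each allele
#' expanded with probability `1 - sqrt(1 - expansionCarrierProb)`).
#' Deterministic under the config seed.
#'
#' @param config a [SimConfig-class].
#' @return a [SimulatedCohort-class].
#' @examples
#' cohort <- simulateCohort(SimConfig(nFamilies = 20, seed = 7))
#' head(individuals(cohort))
#' @export
simulateCohort <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  withr::with_seed(config@seed, {
    nf <- config@nFamilies
    sibs <- if (nf) sample.int(length(config@sibProbs), nf, replace = TRUE,
                               prob = config@sibProbs) else integer(0)
    famOf <- rep(seq_len(nf), sibs)
    n <- length(famOf)
    sibNo <- sequence(sibs)
    pat <- if (nf) sample.int(length(config@ancestryPatterns), nf,
                              replace = TRUE, prob = config@patternProbs)
           else integer(0)
    gp <- do.call(rbind, c(list(matrix(character(0), 0, 4)),
                           config@ancestryPatterns[pat[famOf]]))
    ind <- data.frame(
      sample_id = sprintf("F%05d_S%d", famOf, sibNo),
      family_id = sprintf("F%05d", famOf),
      gp1 = gp[, 1], gp2 = gp[, 2], gp3 = gp[, 3], gp4 = gp[, 4],
      stringsAsFactors = FALSE)
    q <- .alleleFreq(config@alleleFreqs)
    gt <- vapply(q, function(qi)
      sample(0:2, n, replace = TRUE,
             prob = c((1 - qi)^2, 2 * qi * (1 - qi), qi^2)),
      integer(n))
    if (n == 0) gt <- matrix(integer(0), 0, length(q))
    colnames(gt) <- names(config@alleleFreqs)
    qe <- .alleleFreq(config@expansionCarrierProb)
    expanded <- matrix(stats::runif(2 * n) < qe, n, 2)
    lenNorm <- function(k) sample(seq(config@frdaNormalRange[1],
                                      config@frdaNormalRange[2]), k, replace = TRUE)
    lenExp <- function(k) sample(seq(config@frdaExpandedRange[1],
                                     config@frdaExpandedRange[2]), k, replace = TRUE)
    frda <- matrix(0L, n, 2, dimnames = list(NULL, c("allele1", "allele2")))
    frda[!expanded] <- lenNorm(sum(!expanded))
    frda[expanded] <- lenExp(sum(expanded))
    methods::new("SimulatedCohort", individuals = ind, genotypes = gt,
                 frdaAlleles = frda)
  })
}

# reads for a set of cohort rows over the amplicons of `amps` whose
# variants appear in the cohort truth (plus the repeat locus).  Single
# RNG stream, amplicon-major then sample-major order; caller seeds.
.simulateReadsBulk <- function(cohort, amps, config, rows) {
  R <- config@readLength
  e <- config@errorRate
  gt <- cohort@genotypes
  frda <- cohort@frdaAlleles
  sampleIds <- cohort@individuals$sample_id[rows]
  v <- amps@variants[amps@variants$variant_id %in% colnames(gt), , drop = FALSE]
  seqs <- as.character(amps@targets)
  outReads <- list()
  outSample <- list()
  part <- 0L
  emit <- function(reads, smp) {
    part <<- part + 1L
    outReads[[part]] <<- reads
    outSample[[part]] <<- smp
  }
  sampleWindows <- function(hapSeqs, who) {
    # who: index into `rows`-local samples, one entry per read
    L <- nchar(hapSeqs)
    maxStart <- pmax(L - R, 0L)
    start <- floor(stats::runif(length(hapSeqs)) * (maxStart + 1L))
    reads <- substr(hapSeqs, start + 1L, pmin(start + R, L))
    .injectErrors(reads, e)
  }
  for (j in seq_len(nrow(v))) {
    amp <- seqs[[match(v$amplicon_id[j], names(amps@targets))]]
    altAmp <- paste0(substr(amp, 1, v$offset[j]), v$alt[j],
                     substr(amp, v$offset[j] + nchar(v$ref[j]) + 1L, nchar(amp)))
    g <- gt[rows, v$variant_id[j]]
    d <- stats::rpois(length(rows), config@depthPerAmplicon)
    who <- rep(seq_along(rows), d)
    if (!length(who)) next
    isAlt <- stats::runif(length(who)) < (g[who] / 2)
    hap <- ifelse(isAlt, altAmp, amp)
    emit(sampleWindows(hap, who), who)
  }
  if (!is.na(amps@fxnAmplicon)) {
    fl <- as.character(amps@decoy@flankSeq)
    half <- nchar(fl) %/% 2
    left <- substr(fl, 1, half)
    right <- substr(fl, half + 1, nchar(fl))
    d <- stats::rpois(length(rows), config@depthPerAmplicon)
    who <- rep(seq_along(rows), d)
    if (length(who)) {                  # paste0 recycles length-0 to ""
      alleleNo <- 1L + (stats::runif(length(who)) < 0.5)
      units <- frda[rows, , drop = FALSE][cbind(who, alleleNo)]
      hap <- paste0(left, strrep("GAA", units), right)
      emit(sampleWindows(hap, who), who)
    }
  }
  reads <- unlist(outReads, use.names = FALSE)
  who <- unlist(outSample, use.names = FALSE)
  if (is.null(reads)) { reads <- character(0); who <- integer(0) }
  names(reads) <- sprintf("%s:%06d", sampleIds[who], seq_along(reads))
  list(reads = reads, sampleIdx = who)
}

# per-read substitution errors: number of errors ~ Binomial(len, rate),
# each error replaces the base by one of the three others (a cyclic shift
# by 1..3 over ACGT is uniform on the non-identical bases)
.injectErrors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  len <- nchar(reads)
  nerr <- stats::rbinom(length(reads), len, rate)
  bases <- c("A", "C", "G", "T")
  one <- which(nerr == 1L)                     # vectorised common case
  if (length(one)) {
    pos <- 1L + floor(stats::runif(length(one)) * len[one])
    cur <- substr(reads[one], pos, pos)
    shift <- sample.int(3L, length(one), replace = TRUE)
    substr(reads[one], pos, pos) <-
      bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
  }
  for (i in which(nerr >= 2L)) {
    pos <- sample.int(len[i], nerr[i])
    cur <- substring(reads[i], pos, pos)
    shift <- sample.int(3L, nerr[i], replace = TRUE)
    new <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
    for (t in seq_along(pos))
      substr(reads[i], pos[t], pos[t]) <- new[t]
  }
  reads
}

#' Simulate amplicon reads for cohort samples
#'
#' Generates single-end reads over every amplicon whose variant has a
#' truth genotype in the cohort, plus the FXN repeat-locus amplicon: per
#' amplicon and sample the depth is Poisson(`depthPerAmplicon`), each read
#' picks a haplotype (alt with probability `genotype/2`; for the repeat
#' locus, one of the two GAA alleles uniformly), is cut uniformly at
#' random from the haplotype sequence at the configured read length, and
#' receives independent substitution errors.  Read names encode the sample
#' id (`<sample_id>:<serial>`).
#'
#' @param cohort a [SimulatedCohort-class].
#' @param amps an [AmpliconPanel-class].
#' @param config a [SimConfig-class].
#' @param samples sample ids (or indices) to simulate; default all.
#' @param seed RNG seed for read generation; defaults to `config@seed + 1`
#'   so cohort and reads come from distinct, reproducible streams.
#' @return named character vector of read sequences.
#' @examples
#' cfg <- SimConfig(nFamilies = 2, depthPerAmplicon = 5, seed = 1,
#'                  alleleFreqs = c("COL6A2:c.1402C>T" = 0.5))
#' cohort <- simulateCohort(cfg)
#' panel <- readPanelManifest(screeningFixture("manifest"))
#' amps <- buildAmpliconPanel(panel[variantIds(panel) %in%
#'                            c("COL6A2:c.1402C>T", "FXN:GAA expansion")])
#' reads <- simulateReads(cohort, amps, cfg, samples = 1)
#' length(reads)
#' @export
simulateReads <- function(cohort, amps, config, samples = NULL,
                          seed = config@seed + 1L) {
  stopifnot(methods::is(cohort, "SimulatedCohort"),
            methods::is(amps, "AmpliconPanel"))
  rows <- if (is.null(samples)) seq_len(length(cohort))
          else if (is.numeric(samples)) as.integer(samples)
          else match(samples, cohort@individuals$sample_id)
  if (anyNA(rows)) .stopf("unknown sample id(s)")
  withr::with_seed(seed, .simulateReadsBulk(cohort, amps, config, rows))$reads
}
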