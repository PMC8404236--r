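# shared helpers: tiny panels and configs built in code

fullPanel <- function() readPanelManifest(screeningFixture("manifest"))

subPanel <- function(ids) {
  p <- fullPanel()
  p[variantIds(p) %in% ids]
}

# a small config over named carrier frequencies; FRDA always simulated
quickConfig <- function(alleleFreqs, seed, nFamilies = 30L, depth = 50,
                        error = 0, expansionProb = 0.1, sibProbs = 1, ...) {
  SimConfig(nFamilies = nFamilies, sibProbs = sibProbs,
            alleleFreqs = alleleFreqs, depthPerAmplicon = depth,
            errorRate = error, expansionCarrierProb = expansionProb,
            seed = seed, ...)
}

# brute-force longest tandem GAA run (triplets): tries every start and
# every rotation of the motif, extending while the periodic match holds
oracleGaaRun <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  best <- 0L
  rot <- c("GAA", "AAG", "AGA")
  for (start in seq_len(max(n - 2, 0))) {
    motif <- paste(ch[start:(start + 2)], collapse = "")
    if (!(motif %in% rot)) next
    len <- 3L
    while (start + len <= n && ch[start + len] == ch[start + len - 3])
      len <- len + 1L
    best <- max(best, len %/% 3L)
  }
  best
}

# brute-force k-mer sharing: positions of read k-mers occurring in amp
oracleKmerShared <- function(read, amp, k) {
  if (nchar(read) < k) return(0L)
  rk <- substring(read, 1:(nchar(read) - k + 1), k:nchar(read))
  ak <- unique(substring(amp, 1:(nchar(amp) - k + 1), k:nchar(amp)))
  sum(rk %in% ak)
}

# independent affine alignment score (fit: read global, reference local)
oracleAlignScore <- function(read, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = read, subject = ref, type = "global-local",
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 1))
}

# random DNA string helper for tests
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# cohort with hand-picked FXN allele lengths and no SNV truth
frdaCohort <- function(alleles, prefix = "S") {
  n <- nrow(alleles)
  new("SimulatedCohort",
      individuals = data.frame(
        sample_id = sprintf("%s%04d_S1", prefix, seq_len(n)),
        family_id = sprintf("%s%04d", prefix, seq_len(n)),
        gp1 = "syrian", gp2 = "syrian", gp3 = "other", gp4 = "other",
        stringsAsFactors = FALSE),
      genotypes = matrix(integer(0), n, 0),
      frdaAlleles = cbind(allele1 = as.integer(alleles[, 1]),
                          allele2 = as.integer(alleles[, 2])))
}
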