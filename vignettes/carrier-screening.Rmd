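---
title: "Carrier screening from amplicon reads: models, thresholds, and design choices"
author: "ampliscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier screening from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscreen)
```

# The screening problem

Founder populations accumulate recessive disease alleles at frequencies
far above the general population, and premarital carrier screening —
testing prospective partners for a panel of known pathogenic variants —
is an effective way to reduce recessive disease incidence.  `ampliscreen`
implements the computational side of such a programme for a 40-variant
panel assayed by multiplex PCR amplicon sequencing: genotyping SNVs and
small indels from reads, detecting carriers of the Friedreich ataxia
(FRDA) GAA repeat expansion in intron 1 of *FXN*, and turning cohort
genotypes into the statistics a screening recommendation rests on.

The package ships the panel manifest and two cohort frequency tables as
plain-text fixtures (`screeningFixture()`): a 33-variant table for a
cohort of individuals with four grandparents from the target community,
with a large comparison cohort, and a 22-variant table for three larger
"mixed"-ancestry cohorts.  All published percentages and derived counts
are recomputed from the raw carrier counts — never copied — by
`reproducePanelReport()`.

# Cohort construction rules

Eligibility and relatedness follow grandparental ancestry:

* `classifyAncestry()` labels an individual `full` (all four grandparents
  from the target group), `mixed` (one to three) or `ineligible` (none).
* `selectUnrelated()` keeps one randomly chosen sibling per family, so
  frequency denominators count unrelated individuals only.

# The FRDA expansion caller

Normal *FXN* alleles carry a short GAA tract; carrier alleles carry far
longer ones.  Ordinary alignment collapses such reads, so the caller
works on per-read repeat content instead, emulating a decoy-reference /
split-read strategy:

1. `countGaaRepeats()` finds the longest tandem GAA run in a read, in
   triplets, scanning all three phases (rotations GAA/AAG/AGA).  This
   count is the read's repeat-per-read frequency (RPRF).
2. `classifyRepeatRead()` labels a read `split_read` when it has a run of
   at least 4 triplets *and* an exact-or-1-mismatch match of at least 20
   bases of the repeat-free locus flank (it spans the flank-repeat
   junction), `pure_repeat` when the run lacks a flank anchor (interior
   of an expanded tract), or `non_repeat`.
3. `collectRepeatStats()` gathers the RPRF of every repeat-bearing read
   of a sample; `callFrda()` calls a carrier when **at least two of the
   top-3 RPRF values strictly exceed 35 GAA triplets**.  A read with
   exactly 35 countable triplets never qualifies.

Design choices worth stating explicitly:

* Both `split_read` and `pure_repeat` reads contribute RPRF values.  A
  junction-only rule would also work at realistic depths (an expansion
  always produces junction reads), but interior reads of long expansions
  are legitimate repeat evidence and discarding them buys nothing.  The
  carrier decision is insensitive to this choice in simulation.
* The anchor is 20 bases with one mismatch tolerated: long enough to be
  effectively unique in a short amplicon, tolerant of one sequencing
  error.
* The threshold semantics are strictly greater-than 35; the carrier rule
  is monotone in the threshold (property-tested).
* Read length must satisfy `readLength >= 3*36 + 2*20 = 148` so a single
  read *can* carry more than 35 triplets plus anchors; the default 250 bp
  read comfortably does.
* The packaged flank is a synthetic repeat-free sequence.  The algorithm
  depends only on the flank containing no GAA run of 4+ triplets (an
  enforced class invariant), not on its actual content, so no genome
  download is needed; a real flank can be supplied via
  `DecoyReference()`.

# The amplicon genotyper

The genotyping stage replaces a conventional aligner/caller pair with a
small, fully specified pipeline whose every threshold is declared:

* **Assignment** (`assignReadToAmplicon()`): a read goes to the amplicon
  containing the most of its k-mers (k = 15); fewer than 3 shared k-mers
  or a tie leaves it unassigned.
* **Alignment** (`alignRead()`): fit alignment (read global, reference
  window free) under match +1, mismatch −1, gap open −3, gap extend −1,
  with a deterministic leftmost tie-break; alignments scoring below
  −0.2 × read length are discarded.  Reads that fit ungapped at the
  k-mer-voted diagonal with at most 4 mismatches skip the dynamic
  programme — with a 0.3% substitution error model, a 250 bp read exceeds
  4 errors with probability ~1e−6, so the fast path is exact in practice
  and indel-bearing reads still take the full alignment.
* **Classification**: a read supports ref or alt only if its subsequence
  spanning the variant plus 10 anchor bases on each side equals the
  corresponding haplotype window exactly; for indels this realises the
  "full alt allele string" rule, and window equality is invariant to
  equivalent gap placements, which sidesteps indel left/right-shift
  ambiguity.  Anything else (including reads with an error inside the
  window) counts as `other` and dilutes neither allele.
* **Calling** (`callFromDepths()`): with `af = alt/(ref+alt)`, calls are
  `hom_ref` below 0.20, `het` in [0.20, 0.80], `hom_alt` above 0.80, and
  `no_call` under 20 informative reads.  These are conventional amplicon
  thresholds; they are declared so tests can be exact.

The copy-number deletion record in the panel (a 36.8 kb exon 2–7
deletion) is representable in the manifest but excluded from read-level
genotyping: single-amplicon reads carry no copy-number signal, so it
participates in fixture statistics only.

# The cohort simulator

The simulator exists so every downstream stage is testable without any
external data, and its defaults state the cohort model:

* **Genotypes**: carrier frequency `cf` converts to allele frequency by
  the exact Hardy–Weinberg inversion `q = 1 − sqrt(1 − cf)` (not `cf/2`,
  which is biased for the larger panel frequencies such as ~4%), and
  genotypes are drawn as `(1−q)²`, `2q(1−q)`, `q²`.  Default frequencies
  are the packaged mixed-cohort table values.
* **FRDA alleles**: normal lengths uniform on 8–30 triplets, expanded on
  70–1000; each allele is independently expanded with probability
  `1 − sqrt(1 − expansionCarrierProb)`.  The normal range is a declared
  default (the screened population's distribution is not published);
  boundary behaviour is exercised by dedicated tests rather than by the
  allele model.
* **Reads**: single-end 250 bp windows uniform along each amplicon,
  Poisson(100) depth per amplicon, substitution-only errors at 0.3%
  (amplicon short-read error profiles are substitution-dominated, and
  substitutions keep repeat-count arithmetic analysable).  Het sites
  yield alt reads at expected fraction 0.5.
* **Families**: each family draws one grandparental-ancestry pattern and
  1–4 siblings; sibling *genotypes* are drawn independently (no parental
  transmission model), which is immaterial downstream because
  `selectUnrelated()` removes all but one sibling before any statistic.
* **Determinism**: one seed in `SimConfig`; cohort and read generation
  use separate documented streams (`seed`, `seed + 1`), and the chunked
  cohort driver (`screenCohort()`) is deterministic for a fixed chunk
  size.

What the simulator does **not** model — PCR duplicates and stutter,
quality-score miscalibration, index hopping, allele dropout of very long
expansions under PCR, population structure beyond grandparent labels —
bounds what passing tests show: the pipeline's decision rules are correct
against the declared generative model, not that the thresholds are
optimal for any particular instrument's artefacts.

# Cohort statistics

* **Frequencies**: `carrierFrequency()` reports `carriers/n` with a
  Wilson 95% score interval (well-behaved at zero counts, where a Wald
  interval collapses; cross-checked in tests against
  `prop.test(correct = FALSE)`).  Percentages print at two decimals with
  half-up rounding, matching every value in the fixture tables (base R
  rounds half to even, which does not).
* **Per-gene aggregation** (`aggregateByGene()`): variant fractions sum
  within a gene — a rare-variant approximation that is exact for the
  at-risk-couple arithmetic below up to products of small fractions, and
  invariant to how carriers are split across variant rows.
* **At-risk couples** (`coupleAtRiskProbability()`): under random mating,
  `sum_g f_g^2`.  For the mixed cohort table this gives 5.53e-4, i.e.
  0.06% or 6 couples per 10,000.
* **Panel filter** (`filterScreeningPanel()`): variants above 0.6%
  retained, counting variants and distinct phenotype strings (20 and 17
  on the shipped table).  Phenotype identity is exact string equality of
  the table's phenotype column, which reproduces the published "25
  conditions" count without curation judgments.
* **Sharing filter** (`sharedWithPopulation()`): a variant is "present"
  in the comparison population when its percent *rounds* above 0.00 at
  two decimals.  Raw nonzero counts give 19 variants; the rounding rule
  gives the published 16 (13 conditions).  Both modes are available; the
  rounded rule is the default because it matches how the source tables
  display presence.

Two published quantities are deliberately reported but never asserted:

* The full-ancestry cohort couple risk: the printed 0.82% cannot be
  reconstructed from the table, whose per-variant denominators range from
  93 to 438 and whose aggregation is not described.  Under this package's
  stated rule the value is ~0.92%; `reproducePanelReport()` reports it
  with `expected = NA`.
* The 8.2% any-carrier rate: it requires individual-level genotypes
  across all 40 variants, which are not published (the 22-variant table's
  frequencies sum to ~6.1%, so the full panel clearly contributes).
  `anyCarrierRate()` implements the statistic for simulated or called
  genotype matrices.

# Problem sizes used in the test suite

The acceptance-style tests run the complete pipeline at the study's
cohort geometry: 3,401 unrelated mixed-ancestry individuals at the
packaged table's frequencies, depth 100, error 0.3%, verifying that every
estimated frequency covers the realised truth within its Wilson interval
and that genotype concordance exceeds 99.9%; and 100 simulated expansion
carriers plus 367 non-carriers at depth 50, verifying 100/100 sensitivity
and 0/367 false carriers.  Reads are streamed in per-sample chunks so the
full cohort (~7.5M reads) is never held in memory.

# Known limitations

* The genotyper handles biallelic SNVs and small indels only; no
  multi-allelic sites, no base-quality use, no local assembly.
* The expansion caller reports per-read repeat counts, not an estimated
  expansion length, and does not interpret premutation ranges.
* Synthetic amplicon references mean coordinates in outputs are the
  manifest's published positions while sequences are stand-ins; swapping
  in real amplicon sequences changes nothing in the algorithms.
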