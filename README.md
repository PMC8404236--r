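# ampliscreen

Amplicon-based premarital carrier screening for founder populations:
panel genotyping, Friedreich ataxia (FRDA) GAA repeat-expansion carrier
detection, and the cohort statistics behind a screening recommendation.

## What it is for

Communities with strong founder effects carry recessive disease alleles
at high frequency, and screening prospective couples against a panel of
known pathogenic variants prevents most affected births.  This package
implements the computational pipeline for such a programme built on
multiplex PCR amplicon sequencing of a 40-variant panel (SNVs, small
indels, one copy-number record, and the *FXN* intron-1 GAA expansion):

* **Panel data model** — a `GRanges`-backed `VariantPanel` (hg38
  coordinates as printed, categories 1–5) plus published cohort
  frequency tables shipped as plain-text fixtures.
* **Read simulator** — Hardy–Weinberg cohorts with family structure and
  grandparental ancestry, and amplicon reads with configurable depth,
  read length, substitution errors, and GAA allele-length distributions.
* **Genotyper** — k-mer read assignment, affine-gap fit alignment, exact
  windowed ref/alt classification (full alt-allele match for indels),
  and depth-threshold diploid calls (`het` for alt fraction in
  [0.20, 0.80], `no_call` under 20 informative reads).
* **FRDA caller** — per-read GAA repeat counts (repeat-per-read
  frequency, RPRF) from split and pure-repeat reads against a GAA decoy
  plus repeat-free flank; a sample is a carrier when **≥ 2 of its top-3
  RPRF values strictly exceed 35 triplets**.
* **Cohort statistics** — carrier frequencies with Wilson 95% intervals,
  per-gene aggregation, at-risk couple probability
  `sum_g f_g^2`, any-carrier rate, the > 0.6% screening-panel filter and
  cross-population sharing counts.

## Worked example

Recompute the mixed-cohort carrier frequencies and the at-risk couple
probability from the shipped table:

```r
library(ampliscreen)
t3  <- readCohortTable(screeningFixture("table3"), "syrian_mixed")
est <- carrierFrequency(t3$carriers, t3$n, t3$variant_id)
est$gene <- t3$gene
head(est[order(-est$fraction),
         c("variant_id", "carriers", "n", "percent", "ci_lo", "ci_hi")], 4)
#>         variant_id carriers    n percent   ci_lo   ci_hi
#>   COL6A2:c.1402C>T       56 3401    1.65 0.01270 0.02132
#>      GJB2:c.167del       41 3401    1.21 0.00890 0.01631
#>      GNE:c.2228T>C       24 3401    0.71 0.00475 0.01048
#>  FXN:GAA expansion       19 3401    0.56 0.00358 0.00871

coupleAtRiskProbability(aggregateByGene(est))
#> [1] 0.0005531245       # 0.06% of couples, ~6 per 10,000
```

So 1.65% of the mixed cohort carries the COL6A2 Ullrich muscular
dystrophy allele, and under random mating about 6 couples per 10,000
would both carry a variant in the same screened gene.

The expansion caller on a sample whose repeat-bearing reads count
44, 41, 38, 12 and 9 GAA triplets:

```r
ref   <- DecoyReference()
stats <- collectRepeatStats(strrep("GAA", c(44, 41, 38, 12, 9)), ref,
                            sampleId = "S1")
stats
#> RepeatReadStats for S1 : 5 repeat reads, 144 total GAA triplets,
#>   top3 RPRF [ 44, 41, 38 ]
callFrda(stats)
#> FrdaCall S1 : CARRIER (top3 RPRF [ 44, 41, 38 ], threshold 35 )
```

A full simulate-and-screen round trip (cohort truth → FASTQ → calls) is
available both programmatically (`simulateCohort()`, `screenCohort()`)
and from a shell via `inst/scripts/ampliscreen.R` with subcommands
`simulate`, `screen`, `frda`, `stats` and `reproduce-paper`.

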