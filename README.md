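# mhcdiv

Genotyping and allelic-diversity analysis for the major histocompatibility
complex (MHC) of Atlantic salmon (*Salmo salar*), built for comparing immune
gene diversity between wild river populations and escaped farmed fish.

Atlantic salmon carries a single classical MHC class I locus (*UBA*, on
chromosome 27) and tightly linked classical class II alpha/beta loci
(*DAA*/*DAB*, chromosome 12) that are inherited as one *DAA*–*DAB*
haplotype. These loci are genotyped by paired-end amplicon sequencing of
cDNA; conservation questions then come down to how many alleles a
population holds, how evenly they are distributed, and how much of that
diversity survives in farmed escapees. `mhcdiv` implements the whole chain:

* **Amplicon genotyping** — quality filter, zero-mismatch primer
  demultiplexing, FLASH-style overlap merging of read pairs (quality
  consensus in the overlap; both "innie" and read-through "outie"
  orientations), exact collapsing of merged reads, selection of the top
  five candidates above 1% of the pool's merged reads, 0–2 nt end trimming
  to restore the reading frame, and diploid calls (at most two alleles per
  locus, with `excess_alleles`, `low_support` and `missing` flags).
* **Allele nomenclature** — Smith–Waterman local alignment (Water scoring:
  nucleotide +5/−4, BLOSUM62 for peptides, gap 10/0.5) against a reference
  library with IPD-MHC-style names (`Sasa-UBA*13:01`). New sequences are
  named by amino-acid distance to the closest reference: more than T
  differences (T = 4 for *UBA*, 3 for *DAA*/*DAB*) founds a new two-digit
  family, 1–T a new four-digit protein variant, synonymous variants extend
  a six-digit series, and longer-but-identical sequences get the `_L`
  suffix. *UBA* alpha-1 domain lineages are assigned by Jukes–Cantor
  distance to lineage exemplars.
* **Haplotypes** — Clark-style parsimony phasing of unphased two-locus
  genotypes (homozygote anchoring, iterative resolution by known
  haplotypes, frequency parsimony for the rest), plus flagging of
  singleton and inconsistently segregating allele combinations with
  point-mutation vs recombination/conversion annotations.
* **Population statistics** — observed heterozygosity Ho; unbiased gene
  diversity He = N/(N−1)·(1 − Σp̂ᵢ²); hypergeometric rarefied allelic
  richness AR(g) = Σᵢ[1 − C(N−Nᵢ, g)/C(N, g)]; Nei's multi-population
  F<sub>ST</sub> = (H_T − H̄_S)/H_T with Nei–Chesser sample-size
  corrections; a seeded Monte-Carlo permutation test for Hardy–Weinberg
  heterozygote deficit; homozygosity rates by population and group.
* **Rarefaction / extrapolation** — Shannon–Weaver H′ = −Σp ln p;
  leave-one-third-out bootstrap accumulation curves; estimation of the
  total allele number K by matching the observed accumulation curve to
  simulated populations whose frequencies are drawn from a log-scale
  kernel fit of the observed spectrum; anchored extrapolation of expected
  allele counts beyond the observed sample size; Michaelis–Menten
  saturation fits D(n) = D_max·n/(K½ + n) by multi-start nonlinear least
  squares with leave-half-out bootstrap intervals for D_max.
* **Synthetic data** — a first-class generator producing allele libraries
  with shuffled alpha-1 lineages (the class I recombination signature),
  skewed allele-frequency spectra, genotypes with homozygote excess, and
  error-bearing paired reads with a truth manifest, so every stage is
  testable end to end without any sequence download.

Everything takes plain tibbles and returns tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a reference library and two river populations, push reads through
the genotyper, and compute the diversity statistics:

```r
library(mhcdiv)
library(dplyr)

lib <- bind_rows(
  sim_allele_library("UBA", K = 8, lineage_count = 3, seed = 1),
  sim_allele_library("DAB", K = 5, seed = 2)
)
freqs <- sim_allele_freqs(8, "geometric", r = 0.8)
gt <- bind_rows(
  sim_genotypes(freqs, 30, f = 0.2, alleles = lib$name[lib$locus == "UBA"],
                locus = "UBA", population = "river_a", seed = 3),
  sim_genotypes(freqs, 30, f = 0,   alleles = lib$name[lib$locus == "UBA"],
                locus = "UBA", population = "river_b", seed = 4)
)

reads  <- sim_reads(gt[gt$population == "river_a", ][1:3, ], lib,
                    depth = 300, error_rate = 0.01, seed = 5)
called <- genotype_amplicons(reads$reads, default_primers("UBA"), lib)
called$genotypes
#> # A tibble: 3 × 7
#>   individual   locus allele1   allele2   support1 support2 flags
#>   <chr>        <chr> <chr>     <chr>        <int>    <int> <chr>
#> 1 river_a_0001 UBA   UBA*01:01 UBA*05:01      107       95 excess_alleles
#> 2 river_a_0002 UBA   UBA*01:01 UBA*03:01       99      105 <NA>
#> 3 river_a_0003 UBA   UBA*02:01 UBA*04:01      101      105 <NA>
```

All three heterozygotes are recovered exactly (the first also had a third,
low-support candidate above the 1% floor — a sequencing-error variant —
which the caller discards and flags rather than silently resolving).

```r
diversity_summary(gt, rarefaction_n = 15)
#> # A tibble: 2 × 7
#>   locus population n_ind n_alleles    ho    he    ar
#> 1 UBA   river_a       30         8 0.733 0.842  7.62
#> 2 UBA   river_b       30         8 0.7   0.845  7.55
```

`river_a` was simulated with homozygote excess (f = 0.2): its Ho sits
below He, and the one-sided permutation test gives a deficit p-value of
0.081 at this sample size (`hwe_test`). Rarefied richness standardizes
both populations to 15 individuals (30 allele copies). Differentiation is
essentially zero, as simulated (`fst_nei` → F_ST = −0.002).

```r
cnt <- as.integer(table(c(gt$allele1, gt$allele2)[gt$population == "river_a"]))
m <- match_allele_count(cnt, reps = 200, seed = 7)
extrapolate_richness(cnt, c(60, 300), match = m)
#> # A tibble: 2 × 5
#>   n_prime expected    lo    hi best_k
#> 1      60     8.19  8.03  8.44      8
#> 2     300     8.22  8.03  8.57      8
```

All 8 alleles are common enough to be seen at n = 30, so the matched total
allele number equals the observed count and the extrapolated discovery
curve is nearly flat.

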