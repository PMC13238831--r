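---
title: "Models and methods for salmon MHC amplicon diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for salmon MHC amplicon diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcdiv)
```

`mhcdiv` analyses the three classical MHC loci of Atlantic salmon — the
class I locus *UBA* and the linked class II pair *DAA*/*DAB* — from
paired-end amplicon reads through to population-level diversity
comparisons. This vignette is the package's own account of the models,
parameters and design choices; the README shows the user-facing workflow.

## The genotyping model

Each individual's cDNA is amplified with locus-specific primer pools
(three *UBA* forward primers that partition the alpha-1 domain lineages —
F1: I, II, V, VI; F2: III, VII; F3: IV — plus single class II pairs) and
sequenced as 2 × 300 nt read pairs. Because each locus is single-copy, a
correct genotype is at most two allele sequences.

The pipeline is deliberately simple and deterministic:

1. **Quality filter.** Pairs are dropped if either read has mean Phred
   quality below 20 or length below 50 nt. Real pipelines delegate this to
   a trimmer with unstated thresholds; a mean-quality floor is the
   substitution-dominated equivalent.
2. **Primer demultiplexing with zero mismatches.** A pair must begin
   exactly with a pool's forward/reverse primers. At a 1 % per-base error
   rate this discards roughly `1 - 0.99^40` ≈ 33 % of pairs — intended
   behaviour: primer-region errors correlate with unusable reads, and
   depth is cheap.
3. **Overlap merging.** For each pair the reverse-complemented read 2 is
   scanned against read 1 over every overlap of at least 10 nt; the
   overlap maximizing matches subject to a mismatch density ≤ 0.25 wins
   (ties prefer the longer overlap). Both orientations are considered:
   the usual "innie" overlap (fragment longer than a read; the merged
   sequence is the union) and the read-through "outie" overlap (fragment
   shorter than a read, as for the ~300 nt class II amplicons; the merged
   sequence is the overlap consensus only, discarding read-through into
   primer/adapter). Disagreeing bases take the higher-quality call, ties
   take read 1. The scan is exhaustive, implemented in C++.
4. **Collapse and candidate selection.** Merged reads are collapsed by
   exact string identity and ranked by count (ties lexicographic, so the
   ranking is reproducible). The top five sequences with at least 1 % of
   the pool's merged reads go forward. The 1 % floor is the permissive end
   of the 1–2 % range used in practice, so weakly amplified second alleles
   survive; it is configurable.
5. **Reading-frame adjustment.** Among the nine combinations of trimming
   0–2 nt from each end, the one whose frame-0 translation is free of
   internal stop codons and longest wins; ties take the smallest
   `(offset5, offset3)`. Candidates with stops in all nine frames are
   rejected as non-coding artifacts. Translation never special-cases an
   initiator codon — these are mid-gene fragments.
6. **Classification and calling.** Candidates are named against the
   reference library (below), unified by name across pools, and reduced to
   at most two alleles by read support. Anomalies are flagged, never
   silently resolved: `excess_alleles` (more than two surviving
   candidates), `low_support` (homozygous call from fewer than 50 reads),
   `missing` (no surviving candidate). The 50-read floor is a package
   choice; no published threshold exists.

## Allele nomenclature

Alignments use Smith–Waterman local alignment with the EMBOSS Water
defaults (nucleotide match +5 / mismatch −4; BLOSUM62 for peptides; gap
open 10, extend 0.5), identity being matches over alignment columns
including gaps. A candidate's closest reference maximizes nucleotide
identity (ties: higher peptide identity, then name order). Names follow
the IPD-MHC convention with an amino-acid distance threshold T = 4 for
*UBA* and T = 3 for class II:

| situation | decision |
|---|---|
| identical nucleotide sequence | existing name |
| longer, identical over the matched span | reference name + `_L` |
| 0 aa difference, different nucleotides | six-digit extension (synonymous series) |
| 1–T aa differences | new four-digit variant in the matched family |
| > T aa differences | new two-digit family |

The aa difference counts substitutions plus gap columns over the locally
aligned peptide region — gap treatment is unstated in the convention, and
counting gaps is the conservative reading. Distances are measured on the
sequenced fragment only; allele pairs that differ solely outside the
fragment are inherently unresolvable and surface as one allele (the
`DAA*01:0x` situation). Number allocation is first-come in decreasing
order of read support (ties by sequence), which makes reruns reproducible
and family placement independent of input order; only the numbers
themselves depend on processing order. `_L` long variants are the same
allele for every statistic.

*UBA* alpha-1 lineages are assigned by Jukes–Cantor distance,
d = −(3/4)·ln(1 − 4p/3) over the ungapped columns (at least 50) of a local
alignment to one exemplar alpha-1 per lineage; saturation (p ≥ 0.75)
leaves the allele unassigned, and a winning margin below 0.01
substitutions/site is flagged ambiguous. This nearest-reference rule
replaces a full maximum-likelihood phylogeny, which is out of scope here.

## Haplotype inference

*DAA* and *DAB* sit ~3 kb apart and segregate as haplotypes, so phase is
usually forced by the data. The phasing is Clark-style parsimony:
individuals homozygous at either locus are obligate and seed the known
set; double heterozygotes whose two candidate phasings are separated by
the known set (one contains a known haplotype, the other none) are
resolved iteratively; the remainder go to the phasing with the larger
total known-haplotype count and are flagged `inferred` (ties by haplotype
name). An EM/likelihood phaser would be overkill at these sample sizes,
and co-segregation arguments are how such data are actually read.
Consistency flags: combinations seen once are `singleton` (possible typing
artifacts); an allele recurring in two or more well-supported haplotypes
is `conflicting`, annotated with the amino-acid distance between its
alternative partners — 1 aa suggests a point mutation, more suggests
recombination or gene conversion between the loci. Because of the
linkage, *DAA* allelic richness can be cross-checked from the *DAB*-linked
haplotype copies (`daa_richness_crosscheck()`).

## Population statistics

All statistics run on allele copy counts per population and locus;
individuals missing a call at a locus are excluded from that locus
entirely, so every counted individual contributes two copies.

* He is the unbiased gene diversity `N/(N-1) * (1 - sum(p^2))`.
* Rarefied allelic richness is exact hypergeometric rarefaction,
  `AR(g) = sum_i 1 - choose(N - N_i, g)/choose(N, g)`, computed in log
  space; the rarefaction unit is allele copies, `g = 2 * n` individuals
  (the conventional standard is 17 individuals, g = 34). `AR(N)` equals
  the observed allele count exactly.
* F<sub>ST</sub> is Nei's (H_T − H̄_S)/H_T with the Nei–Chesser
  corrections (harmonic-mean sample size and observed-heterozygosity
  terms in both H_S and H_T). The corrections leave a small finite-sample
  residual (|F_ST| up to ~0.005 even for identical samples), which is why
  the package reports the estimator rather than forcing zero.
* The Hardy–Weinberg test permutes the observed allele copies into random
  diploid pairs and uses the homozygote count as statistic; the p-value is
  the one-sided (heterozygote-deficit) tail fraction with the standard +1
  correction, fully seeded. Being a discrete one-sided exact test its
  p-values are conservative (super-uniform): the rejection rate never
  exceeds the nominal level, but strict uniformity of p under the null is
  not achievable — a property worth knowing before interpreting
  borderline p-values. Power is high where it matters (0.98 at f = 0.3,
  n = 50, measured by the test suite).

## Rarefaction, extrapolation and saturation

Accumulation analyses treat diversity as a function of sample size.
`accumulation_curve()` either leaves out a random third of individuals per
iteration (the bootstrap convention used with these data, 1000 iterations)
or subsamples along an explicit size grid for smooth curves; envelopes are
2.5/97.5 percentiles.

The total allele number K of a population is estimated by
`match_allele_count()`: the observed allele frequencies are smoothed with
a Gaussian kernel on the log scale (Silverman bandwidth); for each
candidate K, hypothetical populations draw K frequencies from that kernel,
renormalize, and diploid samples of the observed size are simulated; the K
whose mean accumulation curve is closest (L2 on a common grid) to the
observed curve wins, ties to the smaller K. Both observed and simulated
curves are the exact expected-value rarefaction curves of their copy
counts, which removes Monte-Carlo noise from the comparison.
`extrapolate_richness()` then anchors at the observed allele count and
adds, per replicate population q, the expected discoveries between the
observed n and the target n′, `sum((1-q)^(2n) - (1-q)^(2n'))`; this is
exactly the observed count at n′ = n, monotone in n′, and approaches K as
n′ grows. Intervals are replicate percentiles.

Two limitations are inherent and worth stating plainly. First, the kernel
can only posit unseen alleles at frequencies comparable to those already
observed: alleles far below the detectability floor (~1/2n) leave no trace
in the spectrum, so for strongly skewed truths (long geometric tails) the
matched K estimates the *effectively observable* allele number and can sit
far below the nominal K of the generating model. Self-consistency is good
(resampling a spectrum of common alleles recovers K within ±1), and
shallow spectra recover well, but deep tails are underestimated — the
acceptance suite measures this honestly rather than hiding it. Second,
the extrapolation interval reflects only the hypothetical-population draw
variation, not the sampling error of the observed spectrum, so it is
anti-conservative as a confidence interval for the true K; treat it as a
stability envelope of the procedure.

Saturation is summarized by Michaelis–Menten fits
`D(n) = Dmax * n / (Khalf + n)` via `minpack.lm::nlsLM` with multi-start
initials from the Lineweaver–Burk linearization plus perturbations; the
reported fit is the converged start with the lowest residual sum of
squares (the test suite checks optimality against a dense grid search).
`Dmax` intervals come from a leave-half-out bootstrap (refitting on random
halves of the curve points), which needs at least six points.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is verified.

* **Libraries.** *UBA* alleles are concatenations of a 236 nt alpha-1
  domain drawn from up to eight lineage prototypes (between-lineage
  substitution rate 0.25, within-lineage 0.02) and an allele-specific
  24 nt alpha-2 background (rate 0.15); when K ≥ 2 the first two alleles
  share an identical alpha-1 with different alpha-2, the documented
  shuffling signature of class I. Class II alleles are single 261 nt
  fragments. All sequences are stop-free in frame 0 and pairwise distinct.
  The short alpha-2 keeps the whole amplicon within one 300 nt read so
  pairs double-cover it — the same regime as real 2 × 300 chemistry on
  these fragment sizes — which is what lets overlap consensus correct
  sequencing errors.
* **Spectra.** `geometric(r)` gives p_i ∝ r^(i−1); r = 0.87 reproduces the
  ~0.93 expected heterozygosity typical of wild *UBA*, r = 0.8 the ~0.88
  of *DAB*. `dirichlet(alpha)` gives exchangeable random spectra.
* **Genotypes.** P(homozygote i) = p_i² + f·p_i(1−p_i), so f = 0 is
  Hardy–Weinberg and f ≈ 0.2 reproduces the wild *UBA* heterozygote
  deficit; marginal allele frequencies stay unbiased.
* **Reads.** Amplicon = forward primer + template + reverse-complemented
  reverse primer; reads are the two 300 nt ends with i.i.d. substitutions
  at `error_rate` (default depth 500 per locus, chosen for test power; the
  study's real depths are unpublished). Default qualities are two-tier
  ("informative"): miscalled bases carry low Phred scores, correct bases
  high ones, as real base callers produce; `quality = "constant"` writes a
  flat score matching the error rate instead. Indels, chimeras and
  index-hopping are out of scope. Per-individual random streams are
  derived by hashing individual IDs from one master seed, so any subset of
  individuals is bit-reproducible.

What passing tests do and do not show: the generator exercises
substitution errors, skewed spectra, homozygote excess, multi-pool *UBA*
amplification and read-through merging, so end-to-end recovery (≥ 99 % of
genotypes at 1 % error, depth 500) is evidence the pipeline logic is
correct — not that real libraries are this clean. Real data add indels,
chimeras, PCR amplification bias between alleles, and contamination, all
of which land in the flag system (`excess_alleles`, `low_support`) rather
than being modelled. Likewise the simulated populations share one global
spectrum with no genuine differentiation, so F_ST computed on them is a
null check (≈ 0), not a reproduction of real between-river structure.

## Numerical and degenerate-input conventions

Rarefaction uses `lchoose` differences (no overflow); g greater than the
copy total is an error, a monomorphic spectrum gives He = 0 and AR = 1.
F<sub>ST</sub> on loci monomorphic across all populations is `NA`
(undefined), never 0. The HWE test returns p = 1 for monomorphic samples
and refuses n < 5. Merging with no admissible overlap returns a missing
value that simply drops the pair from collapsing. Candidate selection on
an empty pool yields a `missing` genotype flag. All resampling functions
take explicit integer seeds and are reproducible byte-for-byte; problem
sizes used by the test suite (permutation counts, bootstrap iterations,
seed sweeps) are stated in the tests themselves and were chosen to keep
the full suite in the minutes range on a single CPU.
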