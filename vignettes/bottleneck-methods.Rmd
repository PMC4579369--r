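---
title: "Methods: diversity, DLA haplotypes and pedigrees in bottlenecked breeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, DLA haplotypes and pedigrees in bottlenecked breeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strdiv)
```

This vignette documents the statistical models behind `strdiv`, the
choices made where conventions diverge, and what the synthetic-data
tests do and do not establish about real data.

## Data model

Genotypes are unordered pairs of integer alleles (fragment sizes or
repeat counts) per dog per STR locus; a call is either fully present or
fully missing. Decimal repeat designations (e.g. 19.2) are stored as
integers scaled by ten, locus-wide, so exact matching against the DLA
haplotype registry is preserved. Missing data are handled by per-locus
pairwise deletion, the convention of the standard diversity software in
this field: each locus uses every dog typed at that locus, rather than
dropping dogs with any missing call. Allele frequencies are always
computed within an explicitly stated subset — pooled and per-population
frequency tables answer different questions, so pooling is never
implicit.

## Diversity statistics

Per locus: Na (allele count), Ne = 1/Σp² (effective alleles),
Ho (fraction of typed dogs with two distinct alleles),
He = 1 − Σp², and F~IS~ = (He − Ho)/He (0 when He = 0). Two conventions
needed fixing:

* **He is the biased form** (no n/(n−1) correction), matching the
  default of the program whose published tables the fixtures mirror.
* **F~IS~ is computed per locus and then averaged**, not from mean
  Ho/He. The alternative differs in the third decimal on realistic
  panels; the per-locus-then-average form matches tables that print
  F~IS~ beside per-locus means.

Across-locus means are unweighted and the SE is the across-locus sample
standard deviation over √(number of loci): loci are the replication
unit.

Interpretation note: positive mean F~IS~ in a pooled sample indicates
*substructure* (a Wahlund effect — inbred subgroups with diverged allele
frequencies), not merely related parents. This matters for the simulator
design below.

## Internal relatedness

IR = (2H − Σfᵢ)/(2N − Σfᵢ) over N typed loci with H homozygous, where
the frequency sum runs over **all** 2N alleles the dog carries.
Literature usage is ambiguous between this and a homozygous-loci-only
sum; we fixed the convention by its consequence: under the all-allele
sum the expected IR of full-sib offspring equals the kinship of full
siblings, 0.25 — verified exactly by enumeration at a single locus with
equifrequent alleles (`fullsib_ir_ratio_exact()` in the test oracles)
and by gene-drop simulation at the packaged 33-locus frequencies (mean
0.249 at 2000 offspring). The homozygous-only sum is biased upward
(≈0.30 for 10 equifrequent alleles). Frequencies include the focal
individual (no leave-one-out), and `adjusted_internal_relatedness()`
substitutes a reference table, giving alleles the reference lacks the
floor frequency 1/(reference haplotype count) — small enough to penalize
breed-private alleles only minimally, large enough to avoid division
artifacts.

## Distance and ordination

`genetic_distance()` is the codominant genotypic squared distance
(identical 0; one shared allele 1; het/het disjoint 2; hom vs disjoint
het 3; two different homozygotes 4), summed over co-typed loci.
`pcoa()` is classical metric scaling: Gower double-centering of −D²/2
and eigendecomposition, with coordinates only from positive eigenvalues
(tolerance: 10⁻⁹ of the largest absolute eigenvalue). Negative
eigenvalues — possible because the genotypic distance is not guaranteed
Euclidean — are reported, never silently dropped; percent variance is
taken relative to the positive part. The implementation is checked in
the tests against `stats::cmdscale` and against the identity that
full-rank coordinates reproduce the input distances.

## DLA haplotype phasing

The class I (4 STRs) and class II (3 STRs) blocks are phased by the
classic multilocus EM under random haplotype pairing: the E-step
distributes each dog's weight over the haplotype pairs consistent with
its genotype in proportion to 2pᵢpⱼ (pᵢ² for homozygous pairs); the
M-step re-estimates frequencies from expected counts. Numerical
choices:

* convergence when the log-likelihood gains < 10⁻⁸, cap 2000
  iterations; the log-likelihood is asserted non-decreasing at every
  step (a violated assertion is a bug, not a warning);
* the likelihood can be multimodal, so the EM restarts from 10 seeded
  random frequency vectors plus one uniform start and keeps the best
  final likelihood — deterministic given data and seed, unlike the
  Bayesian sampler it replaces;
* dogs with any missing call in a region are excluded and reported, not
  imputed;
* haplotypes below 10⁻⁶ estimated frequency are pruned;
* maximum-posterior diplotypes break exact ties by the
  lexicographically smallest tuple; dogs with ≤ 1 heterozygous locus
  are phase-unambiguous and get posterior exactly 1.

Registry naming is exact-tuple matching; novel tuples get provisional
ids from 9001 upward in sorted-tuple order, a range disjoint from the
published 1001–1999/2001–2999 ids. Extended class I–II haplotypes come
from a second EM over the cis/trans pairings of the per-region
diplotypes, seeded from the product of the per-region frequencies —
this joint refinement is this package's stand-in for the unpublished
correction rule the original study applied across regions, and
`homozygosity_consistency()` (class I homozygote must be class II
homozygote under tight linkage) is the corresponding error screen.

## Association statistics

Relative risk with the Katz log-method: RR = (a/n₁)/(c/n₂),
se = √(1/a − 1/n₁ + 1/c − 1/n₂), z = |ln RR|/se, two-sided normal p,
CI = exp(ln RR ± 1.96 se). The unit of analysis is the haplotype (two
per dog) for per-haplotype and grouped scans, and the dog for
homozygosity risk — this pairing reproduces every published association
value the fixtures carry. Zero cells are flagged `undefined` with no
continuity correction, and no multiple-testing correction is applied in
scans (a `low_count` flag below five total carriers is advisory); both
follow the source analyses the package mirrors. The null behaviour of
the scan is tested: across 500 simulated null replicates the type-I
error at α = 0.05 is within 0.05 ± 0.02.

## Pedigree algorithms

Kinship uses the recursive tabular method, recursing on the individual
deeper in the pedigree; F(x) = kinship(sire, dam). A generation cap g
treats any ancestor more than g generations above the focal individual
— counted along each path — as unknown, matching "COI over 10/15
generations" outputs of studbook software; uneven path depths are
handled per path because no published convention covers them. Capped
COI is non-decreasing in g. Correctness is established against an
independent Wright path-counting oracle (Σ(½)^(n₁+n₂+1)(1+F_A) over
common-ancestor paths disjoint except at A) and against Monte-Carlo
gene-drop IBD rates (±0.01 at 10⁵ drops).

Founder-set contributions use the parental-average recursion stopped at
set members (a set member contributes 1 even if its own parents are
recorded), preventing double counting when the set is internally
related — which the historical founder lists are. The
influential-ancestor ranking is the greedy probability-of-gene-origin
procedure: select the ancestor with the largest mean expected
contribution to the reference cohort, sever the parent links of
selected ancestors, and iterate on marginal contributions, which are
therefore non-negative and sum to at most 1. Marginals are computed
exactly by recursion (deterministic), with gene-drop agreement checked
in the tests; ties break by earliest birth date, then id. Both raw and
marginal values are reported because published rankings do not state
which was printed.

Decades are floor(year/10)·10; dogs without birth dates are excluded
from decade rows and counted separately. Ancestry–disease curves bin
founder-set coefficients into half-open intervals (default width 0.01,
a parameter because published figures do not state their binning) and
report affected/healthy ratios, leaving bins with no healthy dogs
undefined rather than zero.

## The simulator: what it emulates, and what it does not

`simulate_pedigree()` models discrete generations at constant census:
each mating draws a dam uniformly (with replacement) and a sire with
probability ∝ exp(w·quality), quality ~ N(0,1) per sire per generation.
w = 0 is random mating — the final-generation mean COI then matches
1 − (1 − 1/(2N))^t within ±20% (tested) — and larger w concentrates
paternity, the popular-sire effect. The population is split into
`n_lines` breeding lines with a 5% default sire-migration rate because
substructure, not mating between relatives per se, is what produces the
positive pooled F~IS~ observed in bottlenecked breeds; a single
panmictic pool actually yields slightly *negative* F~IS~ from family
structure. `gene_drop()` transmits one random allele per parent per
locus, with the DLA region inherited as two linked blocks recombining
at a configured per-meiosis rate (default 0.01 for a ~2 Mb MHC
interval with known hotspots).

The "paper-like" preset (`paper_like_config()`) adds the features of
the study system, all as configuration:

* 120 founders in 4 lines, 6 generations, litter size 3, sire weight 3
  — 840 dogs, mean final COI ≈ 0.15–0.25 in the core lines;
* founder DLA haplotypes drawn from the published skewed registry
  frequencies, fully coupled across class I/II at founding
  (rank-paired), with the **outlier line's** spectrum flattened toward
  uniform (`dla_outlier_flatten = 0.8`) and that line mating without
  popular sires — rare haplotypes persist in a genuinely less inbred
  stratum, which is the mechanism behind minor-haplotype "protection";
* two liability-threshold diseases: liability = β_F·F + β_h·(risk
  haplotypes) + ε, ε ~ N(0,1), affected above a threshold. The SA-like
  disease is strongly inbreeding-linked (β_F = 8, threshold 2.6,
  ≈3–30% risk over the realized F range); the AD-like disease is weakly
  linked (β_F = 0.5, threshold 1.6, ≈6–10%) with a class II risk
  haplotype (β_h = 0.8 on haplotype 2006). These values were calibrated
  once, as configuration, to give ~10% prevalence each and the
  qualitative cohort pattern (SA cohort significantly more inbred;
  AD indistinguishable from healthy); they are not estimates of any
  real-world effect size.

Determinism: every stochastic operation derives its RNG stream from
(seed, operation name), so outputs are bit-identical across runs and
insensitive to call order.

What the simulator does **not** emulate: STR mutation (relevant to real
registries only as rare haplotype anomalies), realistic recombination
maps, overlapping generations, selection on phenotype beyond sire
usage, genotyping error, and the sampling biases of a voluntary disease
registry. Passing tests on synthetic data therefore demonstrate the
*estimators* (that diversity statistics, EM phasing, RR machinery and
pedigree recursions recover known truth), not that any particular
real-breed dataset will show the same effect sizes.

## Problem sizes and runtime

Test and acceptance runs use desk-scale sizes chosen as the smallest
that leave comfortable statistical margins: 840-dog simulated
populations for cohort contrasts, 200 dogs for EM frequency recovery
(±0.03), 2000 gene-dropped offspring for the full-sib IR calibration
(SE ≈ 0.004), 10⁵ single-locus drops for IBD convergence (±0.01), and
500 replicates for type-I error (±0.02). The full suite runs in well
under a minute on one CPU.

## Known limitations

* The EM phaser assumes random pairing of haplotypes within the phased
  sample; strong within-sample substructure can bias posteriors for
  double-heterozygous dogs (frequency estimates are more robust).
* Generation-capped kinship counts depth per path; software that counts
  whole-pedigree generations can differ on pathologically uneven
  pedigrees.
* The codominant genotypic distance is not guaranteed Euclidean;
  negative PCoA eigenvalues are reported and excluded from coordinates,
  so percent-variance figures are relative to the positive part only.
* `homozygosity_rr_from_freq()` reconstructs counts by rounding
  frequency × cohort size; with small cohorts the rounding step can
  move RR by a few percent, which is why published homozygosity RRs are
  matched at their printed precision rather than exactly.
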