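# strdiv

Population-genetic and pedigree analysis of breeding bottlenecks in
closed dog-breed populations — written for breed-health researchers and
canine geneticists who work with microsatellite (STR) panels, dog
leukocyte antigen (DLA) haplotypes and deep studbook pedigrees.

Registered breeds cannot outcross, so a handful of heavily used sires
can concentrate ancestry breed-wide within a few decades. `strdiv`
quantifies the three fingerprints such a bottleneck leaves:

1. **Genome-wide diversity and its imbalance.** Per-locus and mean
   Na, Ne = 1/Σp², Ho, He = 1 − Σp² and F<sub>IS</sub> = (He − Ho)/He
   (`diversity_stats()`); internal relatedness per dog,
   IR = (2H − Σfᵢ)/(2N − Σfᵢ) with the frequency sum over all 2N carried
   alleles (`internal_relatedness()`), optionally re-weighted by an
   outbred reference population's allele frequencies
   (`adjusted_internal_relatedness()`); codominant genotypic distance
   and principal coordinate analysis (`genetic_distance()`, `pcoa()`);
   one-way ANOVA with Tukey HSD across cohorts (`compare_groups()`).
2. **DLA haplotype structure and disease association.** Multilocus
   expectation–maximization phasing of the 4-STR class I and 3-STR
   class II blocks (`em_phase()`), naming against the published
   haplotype registry (`name_haplotypes()`, ids 1001…/2001…), extended
   class I–II haplotypes (`extended_haplotypes()`), and case/control
   relative risk with the Katz log-method CI,
   RR = (a/n₁)/(c/n₂), se = √(1/a − 1/n₁ + 1/c − 1/n₂)
   (`relative_risk()`, `haplotype_scan()`, `group_relative_risk()`,
   `homozygosity_rr()`).
3. **Pedigree algorithmics.** Recursive kinship and Wright's inbreeding
   coefficient with generation caps (`kinship()`, `coi()`), founder-set
   ancestry percentages such as %MCB/%Wycliffe/%OEA
   (`founder_contribution()`, `founder_sets()`), greedy
   probability-of-gene-origin ancestor ranking
   (`influential_ancestors()`), ancestry-vs-disease curves
   (`ancestry_disease_curve()`) and per-decade summaries
   (`decade_summary()`).

A seeded simulator (`sim_config()`, `simulate_pedigree()`,
`gene_drop()`, `simulate_disease()`, `paper_like_config()`) generates
bottlenecked pedigrees, gene-dropped genotypes, linked DLA blocks and
liability-threshold disease phenotypes, so every statistic can be
validated against known truth. `run_pipeline()` chains all stages and
writes TSV artifacts plus a JSON manifest.

Packaged fixtures carry the published Standard Poodle data: the 33-locus
genomic STR allele-frequency spectrum, the DLA class I/II haplotype
registry, and case/control haplotype counts for sebaceous adenitis (SA)
and Addison's disease (AD).

## Worked example

```r
library(strdiv)

sim <- simulate_dataset(paper_like_config(seed = 1))   # 840 dogs, 6 generations
gg  <- subset_genotypes(sim$genotypes,
                        loci = setdiff(sim$genotypes$loci, dla_panel()$locus))

diversity_stats(gg)
#>   statistic   mean      se
#> 1        Na 7.8485 0.44407
#> 2        Ne 3.2496 0.22333
#> 3        Ho 0.6142 0.02078
#> 4        He 0.6501 0.02117
#> 5       FIS 0.0536 0.01129
```

The positive mean F<sub>IS</sub> (0.054 ± 0.011) is the signature of a
substructured population: an inbred core plus outbred outliers. Cohort
comparisons of internal relatedness show the inbreeding-linked disease
(SA) concentrated in that core while AD dogs are indistinguishable from
healthy ones:

```r
ir <- internal_relatedness(gg)
compare_groups(ir$IR, sim$phenotypes$cohort)
#> one-way ANOVA: F(2, 837) = 78.354, p = 6.43e-32
#>   comparison     diff      lwr      upr     p_adj
#> 1      SA-AD  0.19241  0.13202  0.25280 7.252e-13
#> 2 healthy-AD -0.01208 -0.06191  0.03775 8.366e-01
#> 3 healthy-SA -0.20449 -0.24286 -0.16611 1.423e-13
```

DLA class I phasing and registry naming:

```r
ph <- em_phase(sim$genotypes, "dla_class_I", seed = 1)
named <- name_haplotypes(ph$frequencies$haplotype, dla_registry("dla_class_I"))
head(cbind(id = named$id, ph$frequencies), 3)
#>     id       haplotype frequency
#> 1 1002 380/365/281/181     0.173
#> 2 1003 387/375/277/186     0.171
#> 3 1001 380/373/281/182     0.146
```

Association statistics on the published class I counts (haplotype 1003,
SA cases vs healthy controls; counts are haplotypes, two per dog):

```r
relative_risk(30, 122, 95, 628)
#>    a  n1  c  n2       RR    log_se        z           p   ci_low  ci_high
#> 1 30 122 95 628 1.625539 0.1845822 2.632105 0.008485763 1.132082 2.334087
```

i.e. SA dogs carry haplotype 1003 at 1.63 times the control rate
(95% CI 1.13–2.33, z = 2.63, p = 0.0085).

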