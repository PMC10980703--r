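# mitoburden

Analysis of mitochondrial DNA (mtDNA) heteroplasmy in matched case–control
cohorts sampled at two visits, aimed at studies that sequence the mtDNA
whole genome from sorted immune cells (or any tissue) and ask whether the
mitochondrial genotype differs between patients and matched healthy
controls, or drifts within patients over time.

The package takes per-sample variant tables from two callers, applies a
dual-caller consensus filter, annotates variants with rCRS loci and
pathogenicity scores, and computes the full battery of paired
cross-sectional and longitudinal statistics — everything downstream of
variant calling, nothing upstream of it.

## The quantities at its core

For a sample with accepted variants *i* at variant level (heteroplasmic
fraction) `VL_i`:

* **Cumulative deleterious burden** = Σᵢ `VL_i · s_i`, where
  `s_i = (MutPred_i + APOGEE_i)/2` is the deleterious score of a protein
  variant (flagged deleterious when `s_i > 0.5`);
* **Cumulative MitoTIP score** = Σᵢ `VL_i · MitoTIP_i` over tRNA variants;
* **Adjusted mutational rate** of region *R* = Σ_{i∈R} `VL_i / size(R)`
  (per bp), with VL·score numerators for the deleterious and MitoTIP
  rates. Macro regions are OxPhos Complex I/III/IV/V, tRNA, rRNA, D-loop
  and the complement region "Other" (gene overlaps and unannotated
  positions).

Paired comparisons between patients and their sex- and age-matched
controls use discordant-pair machinery: with `b` pairs where only the
patient qualifies and `c` where only the control does, the exact McNemar
test is the two-sided binomial test `b ~ Bin(b+c, ½)` (chi-square with
continuity correction for `b+c ≥ 25`), and discordant prevalences are
`b/N` vs `c/N`. Rate differences use paired t-tests, haplogroup effects
Kruskal–Wallis, contingency analyses Monte Carlo Fisher tests, all with
Benjamini–Hochberg FDR within each analysis family. Longitudinally,
variants are partitioned into *persistent* (both visits; ΔVL tested
against zero) and *transient* (one visit) trajectories. A matched-pair
power routine computes the power of the McNemar design by exact trinomial
enumeration. A seeded synthetic triplet-cohort generator with a
ground-truth ledger makes the whole pipeline testable without restricted
data.

## Worked example

```r
library(mitoburden)

cfg    <- sim_config(n_triplets = 10, seed = 7)   # 10 matched triplets
cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort, pipeline_config(fisher_nsim = 1000, seed = 7))
report
#> mtDNA cohort analysis report
#>   accepted variants: 467 in 30 samples ( 0 dropped by the consensus filter)
#>   transient proportions: 4.89% (V1) / 3.47% (V2)
#>   mean VL change (persistent): +0.0007 (p = 0.285)
#>   cross-sectional families: macro_prevalence, deleterious_prevalence,
#>   macro_rates, deleterious_rates, haplogroup, haplogroup_independence,
#>   covariates

head(summary(report)[, c("family", "unit", "test_name", "effect",
                         "p_raw", "p_fdr")], 4)
#>             family       unit     test_name effect  p_raw p_fdr
#> 1 macro_prevalence   ComplexI exact McNemar    0.0 1.0000     1
#> 2 macro_prevalence ComplexIII exact McNemar    0.0 1.0000     1
#> 3 macro_prevalence  ComplexIV exact McNemar   -0.1 1.0000     1
#> 4 macro_prevalence   ComplexV exact McNemar   -0.2 0.6875     1
```

30 samples were simulated and all their variants passed the consensus
filter (the generator's callers agree except for a 5% dropout of low-VL
variants, which the curated-database rescue path recovers). About 4% of
each patient's variants per visit are transient, persistent variant levels
do not drift (+0.07% mean change, p = 0.29), and no paired macro-region
comparison is FDR-significant — as expected for a cohort simulated with no
group effect. Single calls work the same way:

```r
mcnemar_exact(9, 2)              # 0.06542969, exact two-sided
dupont_paired_power(20, 0.45, 0.10)   # 0.471: power of a 20-pair design
```

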