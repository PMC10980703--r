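---
title: "mitoburden: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoburden: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoburden)
```

## Scope

`mitoburden` analyses mitochondrial DNA (mtDNA) whole-genome variant tables
from matched cohorts sampled at two visits: a healthy control (HC), a
patient at visit 1 (V1) and the same patient at visit 2 (V2) form one
triplet. The package covers the analysis layer only — it consumes the
tabular outputs of upstream variant callers and of pathogenicity predictors
(MutPred, APOGEE, MitoTIP) and never re-implements read-level processing,
variant calling, haplogroup assignment, or the predictors themselves.

## Coordinate system and region model

All coordinates are 1-based inclusive on the 16,569-bp circular rCRS
(NC_012920.1), matching m.-notation. The bundled annotation
(`inst/extdata/rcrs_regions.tsv`) lists the 13 protein genes, 22 tRNAs,
2 rRNAs and the D-loop; the D-loop wraps the origin (16024–576, 1,122 bp).
Macro regions are the OxPhos complexes I/III/IV/V, tRNA, rRNA, D-loop and
the complement macro **Other**: every position claimed by two loci (the
MT-ATP8/MT-ATP6, MT-ATP6/MT-CO3, MT-ND4L/MT-ND4, MT-TI/MT-TQ and
MT-TC/MT-TY overlaps, 58 bp) or by no locus (88 bp of inter-locus gaps)
resolves to Other. This makes the macro partition total and disjoint, so
macro-region rates never double-count a variant. Validation tolerates
uncovered or doubly-claimed runs only up to 50 bp — above the largest
genuine gap (31 bp) and overlap (46 bp) — so a table missing a whole gene
fails loudly while the true annotation loads.

A consequence worth noting: a variant inside a gene overlap contributes to
Other's adjusted rates, not to either parent gene's, while locus sizes are
the full annotated spans. Numerator restriction and denominator convention
are therefore deliberately asymmetric for the few overlap positions; the
alternative (counting the variant twice) would break additivity of the
macro-region sums.

## Consensus variant filtering

Each sample arrives with records from two callers: the read-level pipeline
(PCP, mutserve-style table) and the Ion Torrent suite (TSS, VCF). The
acceptance rules, keyed per sample on (pos, alt):

* variant level (VL) ≥ 10% — the TSS limit of detection — requires support
  from **both** callers;
* VL < 10% with a TSS match is accepted;
* VL < 10% without a TSS match is rescued only if it passes all four
  reliability indicators (normalized coverage ≥ 0.5, coverage ratio in
  [0.5, 2.0], mean reported NUMT count ≤ 1.0, amplicon-edge distance
  ≥ 5 bp) **and** is present in a curated allow-list;
* TSS-only variants are never accepted.

The four rescue thresholds are package defaults, configurable via
`rescue_rules()`; they are deliberately documented as artifact choices
because the upstream pipeline that defines these indicators does not fix
universal cutoffs. The bundled allow-list is a compact example of
well-established variants; production use should substitute a full curated
database export. Sample-level QC flags samples with coverage uniformity
below 85% or mean coverage below 1,500 reads/bp for resequencing.

Variant identity uses (pos, alt) with the reference taken from rCRS; this
is the only key that works both across callers and across visits.

## Burden scores and adjusted rates

With MutPred and APOGEE scores in [0, 1], the deleterious score of a
protein variant is their mean when both are present, never imputed
otherwise; a variant is *deleterious* when that mean exceeds 0.5 strictly.
Per sample:

* **cumulative deleterious burden** = Σ VL × deleterious score over scored
  protein variants;
* **cumulative MitoTIP score** = Σ VL × raw MitoTIP score over tRNA
  variants;
* **adjusted mutational rate** of a region = Σ VL of the region's variants
  divided by the region size in bp, with deleterious and MitoTIP variants
  (Σ VL × score) for the corresponding adjusted rates.

Whether the burden sums over all scored variants or only flagged
deleterious ones is genuinely open; both are implemented
(`burden_scope = "all_scored"` — the default, since the score itself
already weights benign variants down — or `"deleterious_only"`).
tRNA variants with a raw MitoTIP score above 12.66 (the public
"likely pathogenic" quartile boundary) are flagged pathogenic.

## Paired cross-sectional statistics

Comparisons between V1 and matched HC are paired throughout:

* **Discordant prevalence.** For a binary qualifier (e.g. "carries ≥ 1
  deleterious variant in Complex I"), `b` counts pairs where only the
  patient qualifies and `c` pairs where only the control does; the
  discordant prevalences are `b/N` and `c/N`. Exact McNemar: a two-sided
  binomial test of `b ~ Bin(b + c, 1/2)` while `b + c < 25`, a
  continuity-corrected chi-square at or above — the cutover is a package
  choice at the conventional small-sample boundary.
* **Discordant adjusted rates.** Paired t-tests of per-pair rate
  differences. By default the rate entering the test is computed from
  *pair-discordant variants only* (variants present in exactly one member,
  by (pos, alt)); `discordant_only = FALSE` gives the all-variants
  reading. Both are reported because the phrase "discordant mutational
  rate" admits either.
* **Degenerate pairs.** Zero-variance differences are never propagated
  into a t statistic: all-zero differences report p = 1 with zero effect
  ("no evidence" rather than NaN), a nonzero constant shift reports the
  shift with p = 0, both flagged `degenerate`.
* **Haplogroup tests.** Kruskal–Wallis (midrank tie correction) on variant
  counts, deleterious counts, burden and cumulative MitoTIP across
  haplogroups with at least three samples.
* **Monte Carlo Fisher tests** for contingency analyses (haplogroup ×
  subject type, medication change × evolution, haplogroup × evolution),
  100,000 simulated tables by default, with a mandatory seed; the caller's
  RNG state is restored so pipeline reruns are bit-reproducible.
* **FDR.** Benjamini–Hochberg within each analysis family (one family per
  reported batch: per-macro prevalence, per-macro rates, deleterious
  variants thereof, per-variant tests, covariate battery, longitudinal
  batteries), mirroring how such batches are reported.
* **Covariate battery.** Linear regression of metrics on age, Kendall rank
  correlation for count metrics, two-sample t of paired differences by
  sex, and carrier-by-sex chi-square / two-proportion z tests.

### Matched-pair power

`dupont_paired_power()` computes the power of the paired design by exact
enumeration: a pair is case-only discordant with probability `p1`,
control-only with `p2`; the discordant total is Binomial(n, p1 + p2) and,
given the total, the case-only count is Binomial(m, p1/(p1+p2)). The
rejection rule is exactly the one `mcnemar_exact()` applies, so the
enumeration and the simulated test agree by construction; it is validated
against an independent 100,000-replicate Monte Carlo simulation in the
test suite.

## Longitudinal dynamics

Within a patient, visit tables are matched on (pos, alt) into a total
partition: **persistent** variants (both visits, with ΔVL = VL₂ − VL₁) and
**transient** variants (exactly one visit). The transient proportion of a
visit uses that visit's variant count as denominator (matching per-visit
reporting; a union denominator is available), and subjects with no
variants at a visit are censored, never counted as zero. ΔVL is tested
against zero by one-sample t-tests, pooled and per subject; transient and
persistent variants are contrasted by two-sample t-tests on VL, the four
reliability indicators, deleterious and MitoTIP scores, FDR within the
family. For interpersonal analyses each patient collapses to one data
point (means over both visits). Clinical variables are grouped by
diagnostic evolution (CIS–CIS, CIS–RRMS, RRMS–RRMS) via batch
Kruskal–Wallis in two modes — per-variable visit means and visit-2 minus
visit-1 deltas.

NEDA-3 requires zero relapses, zero gadolinium-enhancing lesions, no new
or enlarging T2 lesions and no EDSS worsening; any missing component
censors the classification. EDSS worsening uses the field-standard
confirmed-progression thresholds (≥ 1.5 from baseline 0, ≥ 1.0 from
0.5–5.5, ≥ 0.5 from ≥ 6.0), configurable because source definitions vary.
Annualization uses 365.25-day years.

## The synthetic cohort generator

Real genotype-level data of this kind is access-restricted, so the
generator produces the full pipeline input with known ground truth. What
it emulates, and the defaults:

* **Haplogroup structure.** European haplogroup mix (H 40%, HV 5%, U 13%,
  K 8%, J 9%, T 9%, V 5%, W 4%, X 3%, I 4%). Each haplogroup has a
  backbone pool of homoplasmic variants drawn once from the master seed;
  samples take a pool prefix, so haplogroup mates share variants
  (phylogenetic nesting). Backbone counts are low for H/HV (≈ 4/9, the
  reference sequence itself being haplogroup H) and high (≈ 26–31) for
  the others, which makes cohort variant counts bimodal.
* **Score structure.** Protein backbone variants of J/T draw
  MutPred/APOGEE from Beta(6, 2) (deleterious-enriched), others from
  Beta(2, 6); tRNA backbone MitoTIP is Normal(11, 3) for K/U, Normal(4, 2)
  for H/HV, Normal(7, 3) otherwise, truncated to [0, 21].
* **Heteroplasmies.** Poisson(3) private heteroplasmies per individual
  with VL ~ Beta(1, 12) floored at 2% — mostly below 10%, so the rescue
  path is exercised on every run. Each patient heteroplasmy is transient
  with probability 0.3 (assigned to a random visit, VL halved via
  `transient_vl_scale = 0.5`); persistent VLs drift by Normal(0, 0.02)
  between visits. The transient probability is calibrated so the mean
  per-visit transient proportion lands near 4% and the transient/persistent
  VL asymmetry near the reported 8.4%/4.7% scale — calibration to the
  study conditions, not a claim of distributional fidelity.
* **Caller echo.** TSS echoes every PCP variant, dropping 5% of sub-10%
  VLs, so all consensus-filter branches run; quality indicators are drawn
  inside the passing ranges, with transient variants given a lower
  coverage ratio. The generated allow-list covers the simulated variants;
  consequently trajectory recovery under default noise is exact, and the
  filter's rejection branches are exercised by dedicated unit fixtures
  rather than by cohort noise.
* **Clinical covariates.** Evolution mix 23/13/64%, ages 19–56, 66%
  female, HC matched on sex with age difference at most 5 years; EDSS,
  lesion counts, OCT metrics drawn in realistic ranges purely for
  plumbing — no distributional fidelity is claimed or used.
* **Reproducibility.** One master seed; each triplet consumes its own
  arithmetically derived substream, so extending a cohort never perturbs
  existing triplets, and identical configurations produce byte-identical
  output files.

**Effect injection** (`inject_effect()`) sets the carrier prevalence of
"≥ 1 deleterious variant in a macro region" to `baseline + delta` in the
case group and `baseline` in controls: existing protein scores in the
region are capped at 0.5 and carriers — drawn independently per pair
member — receive one shared deleterious variant (score 0.9, VL 0.15–0.6;
patient carriers at both visits). Independent assignment implies
discordance probabilities `p1 = (baseline+delta)(1-baseline)` and
`p2 = baseline(1-baseline-delta)`, which is what the power enumeration is
fed when checking detection rates.

What the generator does **not** emulate: read-level error processes, NUMT
contamination, strand artifacts, indels, caller-specific biases beyond the
dropout model, linkage between clinical covariates and genotype, and
haplogroup-correlated clinical structure. Passing tests on synthetic
cohorts therefore validate the *analysis machinery* — filtering logic,
arithmetic, test calibration, bookkeeping — not biological claims about
real cohorts.

## Validation strategy and problem sizes

The test suite validates every scoring operation against independent
brute-force summation (1,000 random samples, tolerance 1e-12), the
consensus filter against a rule-by-rule oracle (1,000 random toy samples,
exact set equality), and every test statistic against closed-form or
reference implementations (100 random fixtures each, tolerance 1e-10).
Calibration checks run 200 null 61-triplet cohorts (no injected effect)
and require each paired family's rate of any FDR-significant result to
stay within Monte Carlo error of the nominal 5%; power checks run 500
replicates of the injected pilot configuration (prevalences 0.55 vs 0.20)
at 61 pairs and compare the empirical rejection rate with the trinomial
enumeration within ±0.02. These sizes keep the full suite to a few
minutes on a single CPU while leaving Monte Carlo error well below the
asserted margins.

## Worked example

```{r example}
cfg <- sim_config(n_triplets = 10, seed = 7)
cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort, pipeline_config(fisher_nsim = 1000,
                                               seed = 7))
report
truth_check(report, cohort)[c("trajectory_accuracy", "max_burden_error")]
```

## Known limitations

* Indels are matched as literal (pos, alt) strings; left-alignment and
  trimming are assumed done upstream.
* The per-variant McNemar family can grow large on big cohorts; it is off
  by default (`per_variant = TRUE` enables it).
* The Dupont-style power routine is validated against its own simulation
  oracle; the original matched case-control parameterization admits
  variants that were not disambiguated here.
* Haplogroup assignment is consumed, not computed; samples with missing
  haplogroups are dropped from haplogroup families only.
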