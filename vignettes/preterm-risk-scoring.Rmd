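---
title: "Scoring early preterm-delivery risk from vaginal microbiome diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring early preterm-delivery risk from vaginal microbiome diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptdiv)
```

## The problem

The vaginal microbiome of pregnant women is typically dominated by
*Lactobacillus*, with a long tail of minority taxa; ranked abundances trace
a highly skewed Lorenz curve, much like an inequitable wealth distribution.
Women who go on to deliver preterm tend to carry *less* diverse vaginal
communities than women who deliver at term — but only during roughly the
first 15–20 gestational weeks, after which the two groups converge. `ptdiv`
operationalizes that observation as a screening statistic: it computes
within-sample diversity and inequality measures from OTU-level taxonomic
profiles, finds the metric threshold that best separates preterm (PTD,
the positive class throughout) from term samples, and quantifies how well
and how robustly the separation holds as pregnancy progresses.

## Measures

Nine per-sample measures are computed on each profile (counts `x`,
relative abundances `p = x / sum(x)` over the cohort's shared taxon
universe):

* **Shannon** `-Σ p_i log p_i` and **Simpson** `1 - Σ p_i²` (evenness;
  the inverse form `1/Σ p_i²` is available as an option), natural log
  throughout, matching the common ecology-package defaults.
* **Chao1**, bias-corrected: `S_obs + F1(F1-1) / (2(F2+1))`. The
  bias-corrected form avoids division by zero when no doubletons exist.
  Chao1 is the one measure that requires integer counts; everything else
  is scale invariant.
* **Gini**, **Atkinson** (aversion `ε = 0.5` by default, the customary
  inequality-package default), **Theil T**, **Ricci-Schutz** (Pietra), and
  the **90:10 decile ratio** — econometric inequality indices applied to
  the abundance vector. All are computed over the *full* vector including
  zero-abundance taxa, mirroring inequality measures on a fixed
  population; the decile ratio alone is restricted to nonzero abundances
  (and is reported missing for single-taxon profiles) because its lower
  quantile is otherwise zero.
* **TCS** (taxonomic composition skew): a skewness statistic of the
  abundance distribution. TCS is deliberately a *pluggable strategy*
  (`tcs_register_variant()`): the shipped default is the Fisher–Pearson
  moment skewness `g1 = m3 / m2^(3/2)` of the relative-abundance vector,
  zeros included, with the convention that a constant vector has zero
  skew. All threshold and validation machinery is agnostic to the variant
  in use, so alternative skew definitions drop in without touching the
  pipeline.

Numerical conventions worth knowing: Atkinson at `ε = 1` uses the
geometric-mean limit, and any zero abundance drives the index to 1 for
`ε ≥ 1`; Theil uses `0·log 0 = 0`; quantiles are linear-interpolation
(type 7).

## Threshold classification and its scores

For one metric on one sample group, `fit_best_threshold()` scans every
candidate threshold — midpoints between consecutive sorted unique values,
plus `±Inf` sentinels — in both directions (PTD below or PTD at/above the
cut) and keeps the rule maximizing the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

Midpoint candidates give the same confusion matrices as scanning observed
values but place the fitted threshold in the interior of the separating
gap, which matters when a frozen threshold is later transferred to
external data. Conventions: a zero factor in the MCC denominator yields 0;
0/0 rates (accuracy, sensitivity, specificity, PPV, NPV) are reported
missing; values exactly at the threshold fall on the above-or-equal side
(irrelevant at fit time with midpoint candidates, relevant for transferred
thresholds). Ties in MCC are broken toward larger extent of segregation,
then the smaller threshold, then the PTD-below direction; since the extent
of segregation depends only on the two value sets (not on the threshold),
the operative tie-breaks are the latter two, kept deterministic so
repeated fits are bit-identical. The direction is learned per metric per
fit, since which side of a given index is "preterm-like" is not fixed a
priori.

When a metric separates the classes completely (MCC = 1), the **extent of
segregation**

$$ES = \frac{\min[\,\delta(\max D_{TD}, \min D_{PTD}),\;
\delta(\max D_{PTD}, \min D_{TD})\,]}
{\max[\,\delta(\max D_{TD}, \min D_{PTD}),\;
\delta(\max D_{PTD}, \min D_{TD})\,]} \times 100$$

grades *how cleanly* the value sets separate (`δ(a,b) = |a-b|`; ES is
symmetric in the two sets and lies in [0, 100]). The sweep report follows
the convention of printing ES in brackets only next to MCC = 1 cells,
though the quantity is computed for every fit.

## Gestational-age grouping

`cumulative_week_groups()` builds the nested groups `Week_8 … Week_40`:
group `Week_N` pools every sample collected *on or before* week N
(inclusive boundary; fractional weeks are allowed, as sampling day / 7).
Grouping is per sample, not per subject, so one subject can contribute
several samples to a group; a `per_subject` mode (latest sample per
subject) is provided for leakage-averse analyses. `sliding_week_windows()`
provides the overlapping-window view used for diversity-trend summaries;
the default of 15 windows of width 6 weeks at step 2.5 covers weeks ~1–40
with ~58% overlap. The window geometry is fully configurable because no
single construction is canonical.

## Validation protocols

**Internal cross-validation** (`internal_cv()`): within the samples at or
before the week cutoff (15 or 20 are the conventional choices),
two-thirds are drawn as a training corpus, the MCC-optimal threshold is
fitted there, frozen, and scored on the held-out third; repeated
`n_iterations` times. Splits are stratified by outcome by default —
stratification guarantees both classes in every corpus and hence estimable
parameters in every iteration; a plain unstratified mode (with resampling
of degenerate splits) is available. One master seed drives everything;
iteration `i` re-seeds with the derived child seed `seed + i`, so any
single iteration is reproducible in isolation and reruns are
bit-identical.

**External validation** (`external_validate()`): the arithmetic mean of
the per-iteration thresholds and the majority direction across iterations
(disagreement rate recorded) are frozen into one rule per metric and
applied, untouched, to an independent cohort.

**Metric comparison**: week-wise MCC (or ES) columns of a sweep, or
per-iteration CV parameters, are compared against a reference metric with
the paired Wilcoxon signed-rank test, Benjamini-Hochberg-adjusted across
competitors. Zero differences are dropped (the standard signed-rank
convention — documented here because exact ties are common on small
sweeps where several metrics reach MCC = 1). The signed-rank null
distribution is computed exactly for up to 25 nonzero differences via a
generating-function dynamic program, which handles tied midpoint ranks
exactly (equivalent to enumerating all 2^n sign patterns); larger n uses
the normal approximation with continuity and tie corrections. The
week-wise comparison defaults to weeks 8–20 (13 pairs), the window where
early-gestation differences are expected to live.

## The synthetic cohort generator

Real cohorts of this kind cannot be bundled, so `generate_cohort()`
produces seeded cohorts with the statistical structure the analysis
assumes, and the whole pipeline is exercised end to end on them:

* **Composition**: Dirichlet-multinomial — one dominant component
  (concentration `dominance_alpha = 100`, the *Lactobacillus* surrogate)
  plus `n_taxa - 1 = 199` tail components. With the default term-arm tail
  concentration (0.3 per taxon) the dominant taxon's median relative
  abundance sits near 0.63, and ranked abundances form the skewed
  Lorenz-curve shape typical of vaginal communities. The concentrations
  are deliberately high enough that compositional noise is small relative
  to the between-arm effect, emulating the pronounced early-week
  separation the method is designed to detect.
* **Effect**: the preterm arm's tail concentration is depressed
  (0.003 per taxon) through week 12, then interpolates log-linearly to
  the term value at `convergence_week = 20`, and equals it afterwards —
  lower early diversity, convergence by mid-pregnancy, placed on tail
  evenness (not on dominant-taxon presence) so that *all*
  evenness-sensitive measures respond.
* **Cohort shape**: 300 subjects, 13.8% preterm (matching a 224/1621
  preterm sample share), 2–8 samples per subject at fractional weeks
  uniform on [4, 40], depths uniform on [500, 50000] so every profile
  passes the 500-read inclusion filter.
* **External cohorts** (`generate_external_cohort()`): same family and
  effect structure with perturbed nuisance parameters (default: depths
  halved, dominance concentration ×1.25; taxon count optionally changed),
  emulating an external study with different protocol and sequencing
  depth. The neutral shift reproduces the base generator exactly.

What the generator does *not* emulate: within-subject longitudinal
autocorrelation (samples are conditionally independent given arm and
week), community state transitions, taxon-specific signatures
(pathogen presence), or batch/primer effects beyond the simple nuisance
shifts. Passing tests on synthetic cohorts therefore demonstrates that the
machinery recovers the structure it assumes — not that any particular
metric will attain these MCC values on real data.

## Problem sizes and runtime choices

The bundled checks run the default 300-subject cohort (~1 550 samples ×
200 taxa) for the 33-group week sweep, 100-iteration cross-validation at
cutoff 15 (both on the effect cohort and on a null cohort with the effect
switched off), and one frozen-threshold external transfer — sizes chosen
so the full suite completes in about a minute on a laptop while keeping
per-group class counts comparable to the week-wise counts of real
cohorts. Property-style tests use 200 random instances per oracle
comparison.

## Known limitations

* TCS (as moment skewness) has a narrow dynamic range on wide taxon
  universes dominated by one taxon, so its frozen-threshold transfer is
  sensitive to shifts in dominance concentration; with stronger external
  dominance shifts its external MCC can drop well below the internal
  mean — the same qualitative degradation expected when thresholds cross
  study boundaries in practice. Shannon-type measures transfer more
  stably under the default shifts.
* Per-sample week grouping reuses subjects across weeks; for subject-level
  claims use `per_subject = TRUE` grouping and subject-aware splits.
* The best-threshold MCC on a full group is an apparent (resubstitution)
  value; the cross-validated means are the honest estimates.
* The decile ratio is undefined for single-taxon profiles and unstable at
  low richness; it is propagated as missing and excluded pairwise.
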