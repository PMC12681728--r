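---
title: "Methods: laboratory-based screening for G6PD p.Val68Met deficiency risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laboratory-based screening for G6PD p.Val68Met deficiency risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g6pdscreen)
```

## The problem

Glucose-6-phosphate dehydrogenase (G6PD) deficiency is an X-linked
enzymopathy that shortens erythrocyte lifespan. Because HbA1c accumulates
over a red cell's life, carriers have systematically lower HbA1c relative to
their true glycemia, which puts them at risk of diabetes underdiagnosis and
undertreatment. The common African-ancestry variant p.Val68Met
(rs1050828-T) is responsible for most of this burden, yet carriers are
rarely diagnosed clinically. `g6pdscreen` implements a screening algorithm
that flags probable carriers from two routine laboratory values, plus the
machinery to evaluate that algorithm and to quantify its downstream
association with diabetic retinopathy.

## The glucose gap and the decision rule

The estimated average glucose (eAG, mg/dL) implied by HbA1c is the linear
glycation relationship

$$\mathrm{eAG} = 28.7 \times \mathrm{HbA1c} - 46.7,$$

and the **glucose gap** is measured blood glucose minus eAG. In carriers,
HbA1c under-reports glycemia, so the gap shifts upward. Carriers also show
a lower red cell distribution width (RDW). The screening rule combines one
inclusive cut on each axis (defaults RDW $\le 12$, gap $\ge -15$ mg/dL):

* **possible** deficiency: RDW $\le 12$ **or** gap $\ge -15$ — the
  sensitivity-first screening criterion;
* **likely** deficiency: RDW $\le 12$ **and** gap $\ge -15$ — the
  enrichment criterion; by construction likely $\Rightarrow$ possible.

Units are fixed at mg/dL and NGSP %; no IFCC/mmol conversion is attempted
because the glycation constants are mg/dL-specific. No rounding happens
inside any operation — the decomposition `gap + eAG = glucose` is exact to
machine precision, and one-decimal rounding is applied only when reports
are formatted. RDW is treated as a unitless clinical quantity (the values
~12–14 correspond to the RDW-CV scale); thresholds are applied on that
scale without conversion.

## Cohort construction

Clinical draws of unknown fasting state are filtered to blood glucose in
[70, 200] mg/dL; the bounds are retained (exclusion is strict, "below 70 or
above 200"). Cohorts where fasting was requested at the draw bypass the
filter via `fasting_assured = TRUE`, a per-run switch, since the range
heuristic exists only to approximate fasting. Draws missing any of the
three analytes are dropped first and counted. Among a participant's
eligible draws, the one with the lowest glucose — most likely fasting — is
the index draw; ties break by earliest date and then input order so that
selection is deterministic. `build_cohort()` emits one row per genotyped
participant with at least one eligible draw and an exclusion ledger whose
counts (`retained`, `no_genotype`, `no_eligible_draw`) always sum to the
input size. A draw is one row with all three analytes; analytes are never
merged across dates.

## X-linked zygosity and Hardy-Weinberg consistency

Zygosity is a pure function of sex and variant allele count: males are
`ref`/`var` hemizygotes, females `ref_homozygote` / `heterozygote` /
`var_homozygote`. At allele frequency $q$, X-linked Hardy-Weinberg
equilibrium implies hemizygote frequency $q$, heterozygote frequency
$2q(1-q)$, and homozygote frequency $q^2$; the $q \mapsto q^2$ identity
links the male and female frequencies in a cohort and is the package's main
external consistency check. The VCF reader accepts both X dialects for
males (haploid `1` and homozygous-coded diploid `1/1`) and rejects male
heterozygous calls loudly, naming the sample — silent coercion hides data
errors. Female haploid calls are likewise rejected rather than guessed at.
Heterozygote enrichment above Hardy-Weinberg, visible in some biobank
frequencies, is deliberately not modelled: no generative account of it is
available, so only the hemizygote/homozygote identities are used as checks.

## Threshold learning

`learn_rule()` re-derives the two cuts from labelled data by axis-aligned
recursive partitioning: a depth-2 partition where the root split is the
better of the two features and the second cut is the best split on the
*other* feature within whichever child yields the larger weight-scaled Gini
decrease. Candidate thresholds are midpoints between consecutive sorted
unique values; ties break toward the smaller threshold; `min_leaf`
(default 20) guards against sliver leaves. Determinism is exact: identical
data and configuration give identical thresholds.

Class weighting matters because genotype-positives are a ~10–15% minority.
The default `"balanced"` weighting is applied **per node**: each split
re-balances the two classes to equal total weight within the node being
split. A single global re-balancing was considered and rejected: after a
strong root split on RDW the low-RDW child is dominated by re-weighted
positives, and the glucose-gap cut drifts toward the negative-class centre
(around $-26$ mg/dL) instead of the between-class boundary; per-node
balancing keeps each cut near the equal-prior Bayes boundary of the data
reaching that node, which is what a threshold extractor should report. The
learner reports thresholds and directions; it never silently replaces the
published defaults in `decision_criteria()` — adopting learned cuts is an
explicit user step.

## Evaluation

Precision is TP / test-positives and recall is TP / genotype-positives,
with true positives the participants meeting the criterion *and* carrying
the relevant genotype. Three target populations are evaluated: male
hemizygotes, female homozygotes, and females with at least one variant
allele. `evaluate_stratified()` produces the full
(task × cohort × criterion) grid with an `"Overall"` row per task that
pools **counts**, not rates, so pooled TP equals the sum of per-cohort TPs.
Empty denominators yield `NA` with an explicit defined-flag, never a
silent 0 or 1. AUROC is the Mann–Whitney rank statistic with midrank tie
handling; its uncertainty is the standard deviation over a seeded
nonparametric bootstrap (default 1000 resamples) — reported "±" values are
taken to be bootstrap SDs, a documented assumption. The continuous score
for a two-feature model is the leaf-wise positive fraction of the fitted
partition (`predict()` on a `g6pd_rule_fit`), the natural score of a
recursive-partitioning model.

## Survival contrasts

The population-application stage contrasts diabetics who meet a screening
criterion against the complement ("general population" reference — the
complement-stratum reading; possible and likely are fitted as two separate
models, not one three-level factor). Twenty-year rates are Kaplan–Meier
cumulative incidence $1 - S(20)$, not crude proportions, because censoring
(death, end of follow-up) is explicit; if follow-up ends before the
horizon the last estimate carries forward with a warning. Hazard ratios
come from Cox partial-likelihood fits adjusting for age, sex, smoking,
diabetes duration, LDL, and hypertension, with Efron tie handling by
default (ties are common at year resolution; Breslow is available as a
comparison switch — note Efron's fractional correction means estimates are
not exactly invariant to dataset replication, while Breslow's are). The
absolute risk difference between strata and its reciprocal, the number
needed to harm, are reported with the undefined case flagged rather than
coerced.

## The synthetic cohort generator

Real cohorts of this kind are access-controlled, so `generate_cohort()`
emulates the statistical structure the pipeline assumes: sex, X-linked
genotypes at configurable $q$ (default 0.12) under Hardy-Weinberg; a
per-participant mean glucose by diabetes status (defaults 90 ± 8 mg/dL
non-diabetic, 150 ± 30 diabetic, 30% prevalence); true HbA1c from the
inverse glycation relationship $(\bar g + 46.7)/28.7$ with a downward
shift of 0.75% in hemizygotes/homozygotes; a downward RDW shift of 1.8
units in the same groups (baseline 13.9 ± 1.1); one to four draws per
participant, 60% fasting, non-fasting draws elevated by a Gamma-distributed
post-prandial bump (mean 40 mg/dL); and, for diabetics, exponential
retinopathy times at 0.006/year scaled by a hazard ratio of 1.4 in
affected carriers, censored Uniform(5, 25) years. X-inactivation mosaicism
is modelled as a single Beta(2, 2) multiplier per heterozygote, shared
between the HbA1c and RDW shifts, producing the attenuated, heterogeneous
female signal expected from random X silencing. One `cohort_label` column
partitions the population into pseudo-cohorts to exercise the stratified
grid without modelling distinct biobanks.

Effect magnitudes are the generator's own choices — no quantitative HbA1c
or RDW effect sizes for p.Val68Met are available to copy — selected once as
physiologically plausible values (a 0.75% HbA1c deficit maps to ~21.5
mg/dL of glucose gap through the 28.7 slope, comfortably separating carriers
without making classification trivial) and recorded in the fixture
manifest. What the generator does *not* emulate: realistic longitudinal
glycemic trajectories, treatment feedback (therapy intensification driven
by the artificially low HbA1c is implicit in the hazard ratio, not
mechanistic), heterozygote excess over Hardy-Weinberg, and the real
fasting/postprandial structure that makes observed population gap medians
sit well below zero. Consequently passing tests demonstrate that the
machinery is correct and that planted effects of realistic direction and
size are recovered — not that the specific published operating
characteristics would be reproduced on real biobank data.

## Problem sizes and numerical choices

The test suite validates parameter recovery at the scales where the checks
are statistically meaningful while staying quick: threshold recovery on
4,000-row samples across ten seeds (requiring eight of ten within ±1 RDW
unit and ±5 mg/dL of the planted cuts), planted hazard-ratio recovery at
n = 5,000 with a 20-replicate coverage check, and survival-stratum
enrichment on 20,000-participant cohorts across five seeds — the "possible"
stratum contrast is intrinsically small (most carriers are diluted among
the many rule-positives), so its sign is checked as a seed-majority and the
incidence ordering as a seed-average. Cox convergence follows
`survival::coxph` defaults; undefined ratios are always `NA` plus a flag;
all generation is reproducible from a single integer seed and restores the
caller's RNG state.

## Reproducing the headline arithmetic

```{r}
# HWE: male hemizygote frequency q predicts female homozygote frequency q^2
round(100 * hwe_expected_frequencies(0.154)$female_homozygote, 1)

# glucose gap at male median labs
round(glucose_gap(88.0, 5.6), 1)

# 20-year risk difference and number needed to harm
risk_difference_and_nnh(0.143, 0.112)[c("risk_difference", "nnh_rounded")]
```

## A full synthetic run

```{r}
bundle <- generate_cohort(synthetic_config(n_participants = 2000, seed = 1))
cohort <- build_cohort(bundle$participants, bundle$draws, bundle$genotypes)
exclusion_ledger(cohort)

screen <- screen_cohort(cohort)
grid <- evaluate_stratified(cohort, screen)
subset(grid, cohort == "Overall" & task == "male_hemizygote",
       select = c(criterion, prevalence, recall, precision))
```

## Known limitations

The algorithm targets a single variant and is most informative for male
hemizygotes; female heterozygotes are attenuated by X-inactivation, and
low homozygote prevalence makes that stratum noisy in any cohort of
moderate size. The glucose-range fasting heuristic is crude, and phenotype
flags (diabetes, retinopathy, G6PD diagnosis) are taken as precomputed
inputs — diagnosis-code mapping is a configuration concern outside the
package. The synthetic generator is a validation harness, not a digital
twin of any health system.
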