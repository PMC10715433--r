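---
title: "Measuring recall quantity and recall order in retrieval-practice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring recall quantity and recall order in retrieval-practice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallorder)
```

## The design

The package targets a standard two-group, three-condition, two-phase
free-recall experiment on text materials. Each participant studies three
texts, each coded into 30 idea units grouped in five contiguous sections of
six. One text is restudied (`restudy`), one is practiced by a single
whole-text free recall (`WTR`), and one by a free recall after each section
(`SR`). Days later all three texts receive a criterion free-recall test.
Group (e.g. ADHD vs. typically developed, screened with the 18-item ASRS,
sum-score cutoff 51) is between participants; condition is within.

Condition order and the text-to-condition assignment are fully
counterbalanced: `generate_design()` crosses the 6 condition orders with
the 6 assignments, giving 36 versions, and `assign_versions()` uses each
version equally often within each group. Versions are numbered
lexicographically by (condition order, text assignment) with conditions
ordered restudy < WTR < SR — the numbering is arbitrary, so we fix a
deterministic one. The planning constant for the sample size (at least 34
per group for d = 0.50 at power 0.80) is recorded by `planned_power()` as
metadata; it comes from standard power software and is not recomputed.

## The two dependent measures

**Proportion recalled.** `proportion_recalled()` divides the number of
distinct correctly recalled idea units by the text's `n_units`. Raw coded
outputs are first passed through `clean_output()`, which drops repeated
units (keeping the first occurrence) and out-of-range codes (intrusions),
reporting both.

**Recall-order score.** `order_score()` quantifies how consistently an
output follows the text. Each recalled unit has an *actual* serial position
(its 1-based position in the output) and a *relative* serial position (its
rank among the recalled units when sorted by original text position). The
score is the mean absolute difference between the two, divided by the
number of recalled units *n*. Dividing by *n* makes the score comparable
across outputs of different lengths; 0 means perfect text order.

The normalization is kept exactly as the defining worked examples dictate
(recalling units 30, 10, 20 in that order scores [(2+1+1)/3]/3 = 4/9 ≈
0.44; recalling 10, 30, 20 scores 2/9 ≈ 0.22). One consequence deserves
emphasis: the score's attainable maximum is **not** 1. Summing |actual −
relative| over a permutation of length *n* is maximized at `floor(n²/2)`
(the reversal is one maximizer), so the score tops out at
`floor(n²/2)/n² ≤ 0.5`, approaching 0.5 from below. `max_order_score()`
exposes this closed form and the test suite confirms it by exhaustive
search over all permutations up to length 7. We deliberately do not
"rescale to 1": the worked examples are authoritative for the statistic,
and the published two-decimal values (0.44, 0.22) are exact under this
arithmetic (tests compare to 4/9 and 2/9 with tolerance 0.005, matching
two-decimal rounding).

**Edge cases.** An empty output has no order to measure: `order_score()`
returns `NA` with `n_recalled = 0`, the proportion is 0, and order-based
analyses drop the observation listwise. Section-recall *practice* outputs
are produced section by section, so a whole-output order score would mix
task structure with memory organization; by default their order score is
missing, with an optional per-section variant
(`score_dataset(..., sr_practice_order = "per_section")`) that scores each
section and averages.

## The inferential layer

`mixed_anova()` fits the classical split-plot decomposition via `aov()`
error strata: the group effect is tested against participants within
groups, the condition and condition-by-group effects against the
condition-by-participant stratum. Partial η² is computed per effect as
`SS_effect / (SS_effect + SS_error_for_that_stratum)`. Participants missing
any analysed within level are dropped from that analysis only (listwise
deletion per analysis), so the error degrees of freedom follow the retained
sample — with 72 complete participants the 2-level practice analysis has
(1, 70) dfs; if one participant lacks one criterion observation, the
3-level criterion analyses have (2, 138) and (1, 69). The dfs are never
hard-coded; a test constructs exactly this missingness pattern and checks
they emerge.

Sphericity for the 3-level within factor is uncorrected by default — the
convention in the reporting style this package mirrors — with a
Greenhouse–Geisser correction (`sphericity = "GG"`; ε estimated from the
pooled within-group covariance of the repeated measures) available by
flag. The correction rescales degrees of freedom only; F is unchanged.

`bonferroni_pairwise()` runs paired t-tests per pair of within levels,
pooled across groups, with `p_adj = min(1, m × p)` for `m` pairs (m = 3
for three conditions). Cohen's d for a repeated-measures contrast has no
single convention, so both common ones are offered: the default `"av"`
divides the mean difference by the pooled SD of the two condition
distributions, `sqrt((sd₁² + sd₂²)/2)`; `"z"` divides by the SD of the
paired differences. For independent groups, `independent_t()` uses the
pooled-variance Student t and derives the effect size exactly as
`d = t·sqrt(1/n₁ + 1/n₂)` — this conversion reproduces published values
such as t(70) = 9.29 → d = 2.19 and t(70) = 1.48 → d = 0.35, so it is
fixed rather than configurable. `pearson_r()` uses pairwise-complete
observations. Group contrasts are computed as first level minus second
(TD − ADHD under the default ordering), so a group difference in which
ADHD scores are higher appears as a negative t; published reports often
print the magnitude.

`analyze_study()` chains the full battery: the 2×2 practice-proportion
ANOVA, the 3×2 criterion-proportion ANOVA with pairwise contrasts, four
proportion-vs-order correlations (WTR practice and criterion, restudy and
SR criterion), the group t-test on the WTR practice order score, and the
3×2 criterion order-score ANOVA with pairwise contrasts. All p-values are
carried as numbers; only the print method floors the display at "< 0.001".

## The synthetic-data generator

`simulate_study()` exists so the whole pipeline — scoring, IO, the ANOVA
strata — can be exercised and validated without raw participant data. Its
generative model is deliberately the simplest structure with the right
statistical shape:

- **Retention.** Each idea unit is retained independently with a per-cell
  probability. The defaults are the condition-level means such designs are
  expected to produce: practice 0.54 (WTR) and 0.81 (SR); criterion 0.42
  (restudy), 0.45 (WTR), 0.37 (SR); identical across groups, since the
  group effect on quantity is null in expectation.
- **Between-participant heterogeneity.** Each participant carries one
  normal offset (SD `sd_logit`, default 0.7) on the log-odds scale, shared
  across cells, which induces the positive within-participant correlation
  a split-plot design assumes. The location of each cell's distribution is
  calibrated by quadrature so that the *mean* of the back-transformed
  draws equals the configured probability — a plain logit shift would
  shrink cell means toward 0.5 (by about 0.02 at p = 0.81) and the
  simulator would fail to recover its own parameters. The default 0.7 puts
  the simulated practice-proportion SDs near 0.19 at p = 0.54, in the
  range typical for this paradigm; only means are calibrated exactly,
  matching cell SDs jointly is left as a calibration exercise.
- **Order noise.** Retained units start in text order and receive
  `K ~ Poisson(rate × n_retained)` uniformly random adjacent
  transpositions. Adjacent-transposition (Kendall-type) noise was chosen
  over arbitrary-displacement noise because it has a clean zero-noise
  limit and a tunable, monotone relationship with the displacement-based
  order score. The default per-cell rates were calibrated once by Monte
  Carlo bisection (30,000 replicates per evaluation) so that expected
  order scores land on the canonical condition-by-group pattern —
  criterion grand means of about 0.10 (restudy), 0.11 (WTR), 0.21 (SR),
  split into group means of about 0.12 (TD) vs. 0.16 (ADHD), and practice
  WTR means of 0.05 (TD) vs. 0.08 (ADHD). The calibrated rates (TD
  0.56/0.56/0.86/1.17/3.66, ADHD 1.27/1.27/1.53/2.18/9.62, ordered as
  practice WTR/SR then criterion restudy/WTR/SR) are frozen as defaults.
  The SR practice rate is set equal to the WTR practice rate per group,
  since SR practice order is not scored by default.
- **Phases.** SR practice is generated per six-unit section and
  concatenated, mirroring the task. Criterion retention is drawn
  independently of practice by default; an item-level dependence hook
  (`carryover` in `[0, 1]`) is available but off, because the analyses the
  package targets do not model item-level carryover.
- **Reproducibility.** One root seed; each participant's data come from a
  substream seeded deterministically by (seed, participant index), so a
  dataset is stable under partial regeneration and identical across runs.

**What passing tests do and do not show.** The simulator reproduces the
*direction* of the canonical effects (SR > WTR at practice, WTR > SR at
criterion proportion, SR least ordered at criterion, ADHD less ordered
than TD) in the large majority of seeded replicates, and recovers its
configured retention probabilities within Monte-Carlo error. It does not
model serial-position (primacy/recency) effects, semantic clustering,
encoding-variability or temporal-context dynamics, item-level
practice-to-criterion dependence (by default), or coder noise; agreement
of the pipeline with simulated data is therefore evidence about the
pipeline's correctness, not about any particular human dataset.

## Numerical and testing choices

Exact arithmetic is used throughout scoring (integer displacements, one
division); no tolerances enter except two-decimal comparisons against
printed values. The ANOVA path is validated two ways: against textbook
split-plot sums-of-squares formulas recomputed independently on a toy
table, and by a 2,000-replicate null simulation checking that each
effect's type-I error rate at α = 0.05 lies in [0.035, 0.065]. Simulation
property tests use 50 replicate studies of 72 participants for parameter
recovery and 10 for the direction-of-effects check — sizes chosen to keep
Monte-Carlo error well below the effects being checked while the full
suite runs in a few minutes. All stochastic tests fix their seeds.

## Known limitations

- The order score is undefined for empty outputs and insensitive below
  n = 2; analyses on it use listwise deletion, which assumes missingness
  is ignorable.
- Uncorrected within dfs are the default; with three levels and real data
  one should check sphericity (the GG flag is provided).
- Which d convention a given published pairwise d used cannot generally be
  determined post hoc; both are labelled in the output
  (`attr(x, "d_method")`).
- The ASRS per-item range is instrument-version dependent; the default
  0–4 (sum range 0–72) is configurable via `item_range`, and the cutoff
  51 is applied to the sum regardless of scale.
- The simulator's ASRS and age fields are cosmetic roster covariates, not
  calibrated psychometrics.
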