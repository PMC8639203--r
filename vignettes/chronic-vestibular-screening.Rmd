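---
title: "Screening test batteries and sequential diagnostic algorithms for chronic vestibular syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening test batteries and sequential diagnostic algorithms for chronic vestibular syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestscreen)
```

## The problem

Chronic vestibular syndromes — dizziness persisting beyond three months —
are dominated by four diagnoses: persistent postural-perceptual dizziness
(PPPD), chronic dizziness due to anxiety (CDA), unilateral vestibular
hypofunction (UVH), and undifferentiated dizziness (UD). Patients typically
receive a large battery of vestibular tests (bithermal caloric test, cVEMP
and oVEMP, video head impulse test, posturography, rotatory chair) and
questionnaires (DHI, HADS, NPQ), most of which show no abnormality in any
given patient. `vestscreen` implements a pipeline that asks which of those
items actually separate the four diagnoses, turns the discriminating items
into thresholds, and chains them into simple sequential classifiers whose
accuracy can be quantified.

The pipeline has four stages, each usable on its own:

1. **Instruments** — derived asymmetry indices: Jongkees canal paresis
   CP% = |(Rw+Rc) − (Lw+Lc)| / (Rw+Rc+Lw+Lc) × 100, directional
   preponderance on beating-direction totals, the VEMP interaural
   asymmetry ratio (Ar−Al)/(Ar+Al) × 100, and the vHIT gain asymmetry
   |(RL−LL)/(RL+LL)| × 100, plus questionnaire structure validation.
2. **Screening** — per-item Kruskal–Wallis across the four groups on each
   item's available cases, Dunn post-hoc z tests with Bonferroni
   correction over the six group pairs for the significant items. Items
   with at least one significant pair form the battery shortlist.
3. **Thresholds** — one-vs-rest ROC per battery item (CP% for UVH, NPQ
   visual/total for PPPD, HADS-A and age for CDA), AUC with a DeLong 95%
   CI, and the Youden-optimal cutoff J = max(sens + spec − 1).
4. **Algorithms** — three disease rule blocks (PPPD: NPQ total or visual
   at/above threshold; UVH: CP% at/above threshold or catch-up saccades;
   CDA: HADS-A at/above threshold or age below threshold) tested in each
   of the six possible orders, with UD as the fallback; evaluation
   reports per-class recall and overall accuracy excluding UD.

Because no patient-level data are available for this class of study, the
package ships a seeded synthetic-cohort generator whose group-level
behaviour emulates the published summary statistics, so the whole pipeline
is exercised end to end by reproducible simulation.

## The synthetic cohort: what it emulates

`generate_cohort()` reproduces, at `scale = 1`:

* group sizes 92 (PPPD), 44 (CDA), 31 (UVH), 37 (UD), and an excluded
  "OTHER" stratum of 27 that carries demographics only;
* for every item, the published per-group mean and SD, realised as a
  normal draw clipped (censored) to the item's legal range and rounded to
  the item's granularity — integers for age/HADS/NPQ, even integers for
  DHI subscales (items score 0/2/4), continuous otherwise;
* questionnaire totals computed by summation of the drawn subscales,
  never drawn independently, so additivity holds for every record
  (matching the subscale means and deriving the totals is the only choice
  that cannot break additivity);
* caloric CP% and DP% realised through a single raw four-velocity
  quadruple (`generate_caloric_raw()`), so the stored asymmetries are
  exactly the Jongkees and directional-preponderance transforms of the
  stored raw values. The summed slow-phase velocity of the four
  irrigations is not published; we draw it from a normal with mean 60
  and SD 20 °/s (clipped to 5–200), a realistic total for four responses
  of roughly 10–25 °/s each. CP% is invariant to this choice;
* the published per-cell missingness: for each group × instrument block,
  exactly `group size − n_available` records lose that block;
* a vHIT sub-cohort of 56 PPPD and 6 UVH records with gains drawn from
  the published sub-cohort means/SDs (better ≥ worse enforced by ordering
  the pair) and catch-up-saccade status drawn Bernoulli(1/56) and
  Bernoulli(3/6).

A single seed spawns one sub-seed per stage (item draws, vHIT assignment,
missingness), so each stage is independently reproducible and the whole
cohort is byte-identical across runs.

### Missingness and the complete-case cohort

The published per-item n's are identical within an instrument block, so
masks are drawn per block, which also preserves subscale/total additivity.
In retrospective chart data incomplete workups cluster within patients, so
the block masks are not independent: each patient carries a latent
propensity `exp(kappa * z)`, `z ~ N(0,1)`, and the per-block missing
records are sampled without replacement proportionally to it. With the
default `kappa = 2`, the number of records with all five algorithm inputs
observed comes out in the 110–125 range (independent masks would give
about 96; fully nested masks about 127). The complete-case count is
deliberately left emergent rather than forced, because the published
per-item n's do not uniquely determine which patients overlapped; at the
default seed it happens to equal 118, the study's complete-case size.

The five gating inputs are age, HADS-A, NPQ visual, NPQ total and CP%.
Catch-up-saccade status is *not* gated on: the vHIT was performed only in
a 62-patient sub-cohort, so requiring it would shrink the evaluable cohort
to at most 62 and remove every CDA and UD patient, which is inconsistent
with a 118-patient algorithm cohort. A missing CUS simply never fires the
UVH block's second criterion (the block is an OR, so CP% still can).

### What the generator does not emulate

Items are independent within patient apart from structural sums. Real
subscales correlate strongly — visible in the published DHI total SD
(21.6) exceeding the independence-implied SD (14.5) — so derived-total
SDs are mildly understated and one or two total-score cells sit a little
off their printed means. Clipping at range boundaries also skews moments
for items whose SD is large relative to the distance to a bound (DP% near
0, the posturography ratios): we accept this and verify cell means at a
3-standard-error tolerance rather than re-standardising after clipping.
There is no longitudinal structure and no comorbidity; the OTHER stratum
is a placeholder, not a model of the rarer diagnoses. Passing simulation
checks therefore demonstrates the pipeline's correctness and the
plausibility of the published group separations under independence — not
patient-level realism.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided significance level for KW and Dunn (the study's threshold) |
| abnormality cutoffs | CP% > 20, \|IAAR\| > 33.3, \|VOR-DP\| > 12, gain < 0.6 | conventional instrument criteria; strict inequalities, so a value exactly at the cutoff is normal |
| `combinator` | `"any"` | within-block logic; OR is consistent with "CP%/CUS"-style pairing and with the observed leakage of anxious CDA patients into a sensitive PPPD block; `"all"` is available |
| `missing_policy` | `"complete_required"` | mirrors the study's restriction to patients with all batteries; `"missing_negative"` classifies everyone for screening-style use |
| `scale` | 1 | multiplies all group sizes; used at 10 for parameter-recovery checks |
| `kappa` | 2 | missingness-propensity concentration (0 = independent masks) |
| CI method | `"delong"` | DeLong is standard, deterministic and fast; stratified bootstrap (2000 resamples) available and agrees within 0.03 on fixtures |

## Numerical choices

* **Candidate thresholds are midpoints** between adjacent distinct
  observed scores plus ±∞. On integer questionnaire and age scales every
  cutoff is then a half-integer, so boundary equality cannot occur; this
  matches the half-integer published cutoffs (10.5, 33.5, 8.5, 48.5) and
  a continuous-scale CP% cutoff of 19.8.
* **Youden ties** are broken toward higher sensitivity, then lower
  threshold — a screening instrument prefers sensitivity at equal J.
* **Tie handling**: midranks with tie correction in KW, Dunn and the
  large-sample Mann–Whitney; the small-sample Mann–Whitney p is an exact
  enumeration over relabelings of the observed pooled values, which is
  valid under ties (the classical tabled null is not).
* **Degenerate inputs** error informatively: all-zero caloric responses,
  both VEMP amplitudes zero, both gains zero, a single class in an ROC.
  An all-tied Kruskal–Wallis input returns H = 0, p = 1 rather than the
  0/0 the tie correction would produce.
* **CP%/DP% are reported as absolute values** with a side/direction
  label, consistent with non-negative published group means; whether the
  study averaged signed or absolute values is not stated, and this is the
  interpretation under which group means are reproducible.
* **Rounding**: overall accuracies are reported to one decimal, matching
  the published precision.

## Open design points and how they were resolved

* The two-sample test behind the published vHIT continuous comparisons is
  not named; we use Mann–Whitney for consistency with the rank-based
  screen and do not treat those p-values as reproduction targets.
* The ROC stage defaults to per-item available cases (matching the
  varying published per-item n's); a complete-case switch exists.
* The within-block logic (OR vs a two-question cascade) is not
  recoverable from the source; both are implemented, OR is the default.
  Under OR the distinction is moot for classification but not for
  reporting which criterion fired.
* The six algorithm orderings are fixed as: 1 PPPD→UVH→CDA,
  2 PPPD→CDA→UVH, 3 UVH→PPPD→CDA, 4 UVH→CDA→PPPD, 5 CDA→PPPD→UVH,
  6 CDA→UVH→PPPD. With complete-case class sizes (70, 14, 19) this
  mapping reproduces all six published overall accuracies exactly from
  the published per-class recalls — an identity the test suite checks.

## Problem sizes used by the checks

Parameter recovery uses three cohorts at `scale = 10` (2310 records
each); the screening and AUC plausibility checks use fifty cohorts at
study size; oracle equivalences use exhaustive enumeration at n ≤ 8 (KW
permutations) and small random fixtures elsewhere. These sizes give the
simulation checks comfortable power while keeping a full run in the tens
of seconds.

## Limitations

The classifiers are screening aids, not diagnoses; the final diagnosis
for these syndromes rests on clinical criteria. No item separates PPPD
from CDA, so CDA recall is structurally poor whenever PPPD is tested
first — visible in both the published accuracies and the simulations.
All simulation-level conclusions are conditional on the generator's
independence assumptions described above.

## A worked example

```{r example, eval = FALSE}
library(vestscreen)

cohort <- generate_cohort(seed = 1)        # 231 synthetic patients
cmp <- compare_all_items(cohort)           # KW + Dunn-Bonferroni screen
cmp$shortlist

battery <- derive_battery(cohort)          # ROC/Youden per battery item
battery$cp_percent                         # AUC, CI, threshold for UVH

algs <- enumerate_algorithms(build_blocks(battery))
evaluate(cohort, algs[["1"]])              # PPPD -> UVH -> CDA
```

The same stages, with narrative output and files under `results/`, are
run by the numbered scripts in `analysis/`.
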