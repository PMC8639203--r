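# vestscreen

Test batteries and sequential diagnostic algorithms for chronic vestibular
syndromes.

Chronic dizziness (symptoms lasting more than three months) is dominated by
four diagnoses — persistent postural-perceptual dizziness (PPPD), chronic
dizziness due to anxiety (CDA), unilateral vestibular hypofunction (UVH) and
undifferentiated dizziness (UD) — yet patients receive a wide battery of
vestibular tests and questionnaires, most of which are unremarkable in any
one patient. `vestscreen` is for clinical researchers in neurotology and
biostatistics who want to (a) identify which battery items actually separate
these diagnoses, (b) convert the discriminating items into operating
thresholds, and (c) evaluate simple ordered rule-based screening algorithms
built from them. Because patient-level data for this class of study are not
public, the package includes a seeded synthetic-cohort generator that
emulates the published group-level statistics, making every stage
reproducible end to end.

## Methods at the core

* **Instrument asymmetry indices** — canal paresis by the Jongkees formula
  CP% = |(Rw+Rc) − (Lw+Lc)| / (Rw+Rc+Lw+Lc) × 100 from the four caloric
  slow-phase velocities; directional preponderance on beating-direction
  totals; the VEMP interaural asymmetry ratio IAAR = (Ar−Al)/(Ar+Al) × 100;
  the vHIT gain asymmetry AR = |(RL−LL)/(RL+LL)| × 100; questionnaire
  (DHI/HADS/NPQ) range and additivity validation.
* **Item screening** — per-item Kruskal–Wallis across the four groups with
  tie correction, Dunn post-hoc z tests with Bonferroni correction over the
  six group pairs; Fisher's exact test and Mann–Whitney for the vHIT
  sub-cohort comparisons.
* **Threshold derivation** — one-vs-rest empirical ROC per battery item,
  AUC as the Mann–Whitney pair-counting probability, DeLong 95% CI, and the
  Youden-optimal cutoff J = max(sensitivity + specificity − 1) over
  midpoint thresholds.
* **Sequential classifiers** — three disease rule blocks (PPPD: NPQ total
  or visual score ≥ threshold; UVH: CP% ≥ threshold or catch-up saccades;
  CDA: HADS-A ≥ threshold or age < threshold) evaluated in all six orders
  with UD as fallback; reported as per-class recall and overall accuracy
  excluding UD.

## Worked example

```r
library(vestscreen)

cohort <- generate_cohort(seed = 1)   # 231 synthetic patients
attr(cohort, "complete_case_n")
#> [1] 118

battery <- derive_battery(cohort)
battery$cp_percent
#> ROC: cp_percent -> UVH (higher indicates target)
#>   AUC 0.829 (95% CI 0.717-0.941), n = 23 vs 147
#>   Youden threshold 45.25: sensitivity 60.9%, specificity 93.9% (J = 0.547)

algs <- enumerate_algorithms(build_blocks(battery))
evaluate(cohort, algs[["1"]])         # PPPD -> UVH -> CDA
#> Algorithm 1: overall accuracy (excl. UD) 73.1% on 118 patients (86 excluded as incomplete)
#> Per-class recall (%):
#> PPPD  CDA  UVH   UD
#> 93.1 27.8 28.6 57.1
#> Confusion matrix (true x predicted):
#>       predicted
#> true   PPPD CDA UVH UD
#>   PPPD   67   4   0  1
#>   CDA    10   5   1  2
#>   UVH     5   1   4  4
#>   UD      4   2   0  8
```

Reading the output: of the 231 simulated patients, 118 have all five
algorithm inputs observed (age, HADS-A, NPQ visual/total, CP%). On this
cohort CP% discriminates UVH from the other three diagnoses with AUC 0.83.
Testing the PPPD block first recovers PPPD well (93% recall) but absorbs
over half of the CDA patients — anxiety-related dizziness and PPPD overlap
on every screened item — so CDA recall is low, and the overall accuracy for
the three target diseases is 73.1%.

The same stages run as numbered narrative scripts:

```sh
Rscript analysis/01_simulate_cohort.R 1     # cohort -> results/cohort.csv
Rscript analysis/02_screen_items.R          # KW + Dunn screen
Rscript analysis/03_derive_thresholds.R     # ROC/Youden battery
Rscript analysis/04_evaluate_algorithms.R   # six ordered classifiers
Rscript analysis/05_published_checks.R      # exact published-number checks
```

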