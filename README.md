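# stpifd

Development and validation toolkit for Delphi-weighted
pattern-identification questionnaires, built around the standard tool of
pattern identification for functional dyspepsia (STPI-FD).

## The problem

Functional dyspepsia (FD) is a chronic gastrointestinal disorder without
an identifiable organic cause. In traditional Korean medicine, treatment
choice is guided by *pattern identification* (syndrome differentiation):
classifying a patient's overall presentation into one of several named
patterns — here six: spleen and stomach deficiency and cold (SSDC), spleen
deficiency with qi stagnation (SDQS), liver–stomach disharmony (LSDH),
tangled cold and heat (TACH), dampness and heat in the spleen and stomach
(DHSS), and food retention disorder (FRDO). Without a standardized
instrument this classification depends on the individual practitioner.
`stpifd` implements the full statistical machinery of a weighted
pattern-identification questionnaire, for researchers developing or
validating such instruments:

* **Weight derivation.** Each symptom item carries an expert Delphi
  importance rating (mean m, standard deviation s on a 1–5 scale). Item
  weights within a pattern are

  w_i = 100 · (m_i/s_i) / Σ_j (m_j/s_j),

  so every pattern's weights sum to 100 and items the panel rated
  important *and* consensual dominate (`derive_weights`). Candidate
  selection uses the mean ≥ 3.00 retention rule with expert overrides
  (`select_by_importance`).
* **Scoring and classification.** A respondent answers each item on a
  0–4 Likert scale; the pattern score is S_p = Σ x_i · w_{i,p}
  (bounded by 400) and the diagnosis is the argmax, with explicit tie
  reporting (`score_respondent`, `classify_cohort`).
* **Reliability.** Cronbach's α (overall, per pattern), corrected
  item-total correlations, α-if-item-deleted, and the pruning rule used
  in instrument revision — flag items with r_it ≤ 0.3 or whose removal
  raises α, confirm with the expert panel, remove and re-derive weights
  (`reliability_report`, `prune_items`).
* **Validity battery.** Fisher–Freeman–Halton exact test (or Pearson
  chi-square, by the expected-frequency rule) for the pattern × Rome IV
  subtype table; tie-corrected Kruskal–Wallis tests per item with
  Dunn–Bonferroni post-hoc pairs; Pearson correlation screens against
  the companion scales (VAS, TDS, SDS, FD-QoL) with Bonferroni tiers
  (`contingency_test`, `kruskal_wallis`, `posthoc_pairwise`,
  `correlation_screen`, `score_scale`).
* **Synthetic cohorts.** A seeded latent-class ordinal generator
  (`generate_cohort`) emulating a validation cohort — six latent patterns
  with uneven prevalence, responses elevated on own-pattern items,
  subtypes drawn conditionally on pattern, and auxiliary scales
  moderately-to-strongly correlated with pattern scores — plus
  parameter-recovery metrics (`recovery_report`).

The draft (38 patient + 11 evaluator items) and final (36 items)
instruments ship as JSON fixtures: `stpi_draft38()`, `stpi_final36()`.

## Worked example

```r
library(stpifd)
instr <- stpi_final36()
instr
#> Pattern-identification instrument <STPI-FD> version final36
#>   items: 36 (patient: 36)
#>   patterns: SSDC[8] SDQS[8] LSDH[11] TACH[9] DHSS[9] FRDO[7]
#>   overrides: Q8

cohort <- generate_cohort(cohort_config(n = 95, seed = 7))
classify_cohort(instr, cohort$data, tie = "order")
#> Cohort classification (n = 95)
#>  pattern  n  pct
#>     SSDC 46 48.4
#>     SDQS  8  8.4
#>     LSDH  8  8.4
#>     TACH 11 11.6
#>     DHSS 11 11.6
#>     FRDO 11 11.6
```

The frequencies track the generator's prevalences (51.6 % SSDC, …) up to
sampling noise and classification error. Reliability of the simulated
responses:

```r
rel <- reliability_report(instr, cohort$data)
round(rel$alpha_pattern, 3)
#>  SSDC  SDQS  LSDH  TACH  DHSS  FRDO
#> 0.888 0.881 0.920 0.888 0.894 0.902
```

Every pattern's α exceeds the 0.7 acceptability benchmark, as expected
from the generator's within-respondent correlation. Recovery of the
latent labels and the concurrent-validity correlations:

```r
rr <- recovery_report(cohort)
round(rr$accuracy, 3)
#> [1] 0.842
round(rr$scale_correlations$r[, "sds"], 2)
#> SSDC SDQS LSDH TACH DHSS FRDO
#> 0.45 0.49 0.51 0.56 0.49 0.54
```

At the default pattern effect (δ = 1) scoring recovers 84 % of latent
labels, and pattern scores correlate moderately (0.4–0.6) with the total
SDS score. `run_study()` wires all stages together and writes the CSV
report bundle plus a provenance JSON.

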