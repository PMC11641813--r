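---
title: "Methods: weighted pattern identification and its validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted pattern identification and its validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpifd)
```

## The instrument model

A pattern-identification questionnaire consists of six named patterns and
a pool of symptom items; an item may belong to several patterns, and each
*membership* carries its own expert importance rating (mean m, SD s on
the 1–5 Delphi scale). Two modelling commitments follow from that
structure and are hard-wired into the `stpi_instrument` container:

* ratings are membership-specific, not item-specific — the same symptom
  can matter differently to different patterns (e.g. Q26 under SSDC vs.
  SDQS carries distinct means), so importance lives on the
  (item, pattern) edge;
* weights are a per-pattern budget: within each pattern

  $$w_i = 100\,\frac{m_i/s_i}{\sum_j m_j/s_j},$$

  so weights are positive, sum to 100, and the ratio of two weights
  equals the ratio of the mean-over-SD "signal-to-disagreement" scores.
  The normalization is the instrument's only cross-pattern comparability
  device: patterns differ in item count, but all share the same 100-point
  budget, which makes the weighted sums directly comparable.

The mean-over-SD form is adopted as the package's weight rule because it
reproduces the printed weight column of the instrument's development
study within the resolution of the two-decimal printed inputs (worst
absolute deviation 0.12, on FRDO's Q4); `derive_weights` keeps the
formula isolated behind one function should a different functional form
ever be needed. Re-derivation retains full floating precision; rounding
to two decimals happens only at serialization (`weight_2dp`) and
printing.

Degenerate ratings (s = 0, a unanimous panel) make the ratio blow up.
The default is to refuse them loudly; an opt-in `sd_floor` (default 0.1
when enabled) substitutes a consensus floor. The packaged fixtures
contain no zero SDs, so the fallback never triggers silently.

Item selection uses the Delphi retention rule: mean ≥ 3.00, the midpoint
of the importance scale, with an explicit override list for items the
expert panel retains despite the statistics (the packaged draft carries
Q8, retained at mean 2.82 as a discriminator between two deficiency
patterns). Overrides are data, not code: they ride in the instrument
JSON.

## Scoring and tie policy

A respondent's pattern score is the weighted sum
$S_p = \sum_{i\in p} x_i\,w_{i,p}$ over 0–4 responses, bounded by
$[0, 400]$; the diagnosis is the arg-max. The development study never
defines a tie-break, and silently inventing a diagnosis seemed wrong, so
the default reports `"tie"` with the tied set attached; an optional
deterministic policy (`tie = "order"`) resolves by the canonical pattern
listing order (SSDC, SDQS, LSDH, TACH, DHSS, FRDO). The deterministic
mode is what the classification-accuracy metrics use, since they need a
single label per respondent.

Missing responses are an error by default, listing the offending item
ids; `score_cohort(impute = TRUE)` substitutes the rounded cohort mean
per item and flags every imputed cell in the output, so imputation is
never invisible.

## Reliability analysis and pruning

All reliability statistics use sample variances (n − 1), matching the
conventions of the commercial software most validation studies report.
Cronbach's α is computed from the variance form
$\alpha = \tfrac{k}{k-1}\bigl(1 - \sum_i \sigma_i^2 / \sigma_T^2\bigr)$;
the test suite checks it against the independent covariance form
$k\bar c/(\bar v + (k-1)\bar c)$ to 1e−10. Item-total correlations
default to the *corrected* form (item excluded from the total), again the
convention of the reporting software; the uncorrected form is available.
The overall α is scoped to patient-rated items only — evaluator (tongue/
pulse) items are excluded from reliability, mirroring how the instrument
was revised.

Pruning (`prune_items`) implements the published decision rule — flag
items with corrected item-total correlation ≤ 0.3, or whose deletion
increases α, screened both overall and within each pattern — but
deliberately does *not* pretend the decision is algorithmic: the
procedure emits candidates, and a `confirm` list carries the
expert-panel decision (default: accept all candidates). This is what
makes the published revision reproducible: confirming {Q32, Q33} on a
draft cohort yields exactly the packaged 36-item final instrument with
per-pattern counts 8/8/11/9/9/7, with all weights re-derived. A single
pass is the default, matching the published one-shot revision; an
iterative mode repeats until stable.

## The validity battery

**Contingency analysis.** The pattern × subtype table is tested by the
expected-frequency rule: Pearson chi-square when all expected counts
reach 5 (Cochran's criterion), otherwise the exact Fisher–Freeman–Halton
test. The exact p follows the probability-ordering two-sided definition —
the total probability, under fixed margins, of tables no more probable
than the observed one — evaluated by the network enumeration algorithm in
R's `fisher.test`, with a seeded Monte-Carlo estimate (≥ 10^6 tables) as
the fallback when enumeration exceeds the workspace budget. On 2×2
tables this definition coincides with the classical two-sided
hypergeometric test; the suite verifies that exhaustively for all
margins up to 6 against a brute-force enumeration written independently
of `fisher.test`. All-zero rows are dropped with a message (an unused
pattern level is a reduction, not an error); an all-zero column margin
is an error, because the test is then undefined.

**Rank comparisons.** Per-item group differences use the tie-corrected
Kruskal–Wallis H with mid-ranks,
$$H = \frac{\frac{12}{N(N+1)}\sum_i n_i\bigl(\bar R_i -
\tfrac{N+1}{2}\bigr)^2}{1 - \sum_t (t^3-t)/(N^3-N)},$$
referred to χ² on g − 1 degrees of freedom. The statistic is computed
in-package rather than delegated because the reporting layer needs the
mean ranks, the uncorrected numerator and the correction factor, and
because the fully tied sample must return the defined degenerate value
H = 0, p = 1 (the textbook ratio is 0/0 there); `stats::kruskal.test`
serves as the independent oracle in the tests, agreeing to 1e−10.
`kw_from_mean_ranks` reconstructs the uncorrected numerator from
*printed* mean ranks and group sizes — since the correction divisor is
≤ 1, the reconstruction is a lower bound on any honestly reported
tie-corrected χ², a consistency check that works even when the raw data
are unavailable. Printed tables are rounded, so a violated rank-sum
identity $\sum n_i \bar R_i = N(N+1)/2$ raises a warning rather than an
error; one row of the published symptom table (Q26) fails that identity
by 11 % — no real ranking can produce it, so the bound check treats it
as a printing defect and the warning is the designed signal.

**Post-hoc pairs.** The published analysis names only "Bonferroni" for
its post-hoc comparisons. Dunn's rank-based z test with tie-corrected
variance is the standard Kruskal–Wallis follow-up and is the default
here; pairwise Mann–Whitney with Bonferroni is available as the
alternative. Adjustment is p·m truncated at 1 over all g(g−1)/2 pairs
(15 for six patterns), with significance tiers at 0.05/0.01/0.001.

**Correlation screen.** Pearson r per (pattern score, scale) pair with
two-sided t-based p. The default star thresholds, 0.00125 and 0.000125,
are configured constants — they correspond to a Bonferroni family of
m = 40 at α = 0.05 and 0.005, matching how the published correlation
table annotates significance, but the family size behind them is not
derivable, so they are parameters, not derived quantities. Strength
bands label |r|: 0.4–0.6 moderate, 0.6–0.8 strong. A zero-variance
column yields an undefined (NA) cell rather than an error, since one
degenerate anchor should not abort the screen.

## Companion scales

`scale_definition` encodes the four concurrent-validity anchors exactly
as administered: VAS (0–100 continuous line), TDS (eight 0–3 severity
items, total 0–24), SDS (four cardinal symptoms × frequency/intensity/
discomfort on 0–3), FD-QoL (21 items on 0–4 across eating 5 / vitality
4 / emotions 6 / social 6 domains, total 0–84). The SDS is described in
its source as per-symptom dimensions without a total; the package
implements per-symptom and per-dimension subtotals *and* a 0–36 grand
total, and takes "total SDS score" to mean that grand total — an
interpretation, recorded here. The VAS inclusion criterion (≥ 40) is a
hard boundary: 40 is in, 39.9 is out.

## What the synthetic generator emulates — and what it does not

`generate_cohort` stands in for the undeposited 95-patient validation
cohort. It emulates the statistical structure the analysis pipeline
assumes:

* six latent pattern classes with the published uneven prevalences
  (0.516, 0.095, 0.074, 0.137, 0.147, 0.032, normalized);
* ordinal 0–4 item responses from a thresholded latent-Gaussian model,
  $y_i = g + \delta\,1[i\in z] + \sqrt{\rho}\,u + \sqrt{1-\rho}\,e_i$,
  with severity factor g ~ N(0,1), cutpoints (−1.5, −0.5, 0.5, 1.5);
  this graded-response-like mechanism was chosen over direct multinomial
  sampling so that a single δ knob controls separability and a single ρ
  knob controls internal consistency;
* FD subtypes drawn from P(subtype | pattern) proportional to the
  published cross-table rows;
* a severity VAS as a clipped affine map of g, floored at the 40-point
  inclusion criterion;
* companion-scale items driven by the same severity factor plus scale
  noise, with 45 % of the noise variance at the respondent level —
  purely item-level noise would average out of a 12-item total and push
  the scale correlations toward 1.

Defaults were calibrated once, before the regression seeds were frozen:
δ = 1, ρ = 0.15 and scale noise 1.3 place per-pattern α in a 0.6–0.95
band and the pattern-score vs. total-SDS correlations in the
moderate-to-strong 0.4–0.8 band across seeds, the regimes the
reliability and validity stages are designed for. The recovery tests
then probe the δ axis: chance-level accuracy at δ = 0 (accuracy equals
the independence expectation Σ P(assign p)·P(latent p)), monotone
improvement over δ ∈ {0, 1, 2, 3}, and ≥ 0.80 accuracy at δ = 3 with
n = 400.

The generator does **not** emulate: evaluator tongue/pulse behaviour
(the final instrument dropped those items); the expert Delphi panel;
demographic covariates beyond subtype; item-specific difficulty or
category usage differences (all items share one threshold vector);
missingness (responses are complete by construction, missingness
handling is tested separately); or any real-data guarantee that the
published α and correlation magnitudes would be reproduced — those
per-patient statistics are functions of an undeposited dataset, so
passing tests on synthetic cohorts show the *pipeline* is correct under
its assumed structure, not that the clinical numbers are recoverable.

## Numerical conventions and problem sizes

* Per-pattern weight sums are validated to 1e−6; printed-weight
  reproduction is checked within ±0.15 absolute, the propagation
  envelope of two-decimal rounded inputs (spot items to ±0.01).
* Score maxima/ties use a 1e−9 comparison tolerance on the weighted
  sums.
* All variances are n − 1 sample variances; α's degenerate case (zero
  total variance) and the correlation screen's zero-variance columns are
  handled explicitly as described above.
* Test problem sizes are deliberately modest — cohorts of 95 (the study
  scale) for pipeline and reliability checks, 400 for the strong-signal
  and marginal-coverage checks, 1000 for the δ-monotonicity sweep, 20–25
  replicates for the property loops — enough for the asserted tolerances
  while keeping the whole suite in well under a minute of compute.

## Known limitations

* The weight formula is validated empirically against the printed weight
  table; its original algebraic source is not restated in the
  development study, so other candidate forms cannot be ruled out — only
  this one reproduces the table.
* The final instrument's weights are re-derived from the draft
  importance ratings rather than read from the (unavailable) published
  appendix.
* No test–retest or inter-rater reliability, no ROC/cut-off derivation
  (explicitly future work for the instrument), no clinical decision
  support beyond the arg-max label.
* Evaluator items, when present in a cohort, are treated as ordinary 0–4
  ratings; a presence-coding mode ({0, 4}) can be emulated upstream by
  recoding the cohort columns.
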