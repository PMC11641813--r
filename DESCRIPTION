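Package: stpifd
Title: Delphi-Weighted Pattern-Identification Instrument for Functional
    Dyspepsia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Development and validation toolkit for weighted
    pattern-identification questionnaires in traditional East-Asian
    medicine, built around the standard tool of pattern identification
    for functional dyspepsia (STPI-FD). Derives per-item weights from
    expert Delphi importance ratings, scores respondents by weighted sums
    and classifies them to the highest-scoring pattern, runs the
    internal-consistency battery (Cronbach's alpha, corrected item-total
    correlations, alpha-if-deleted) with reliability-driven item pruning
    and re-weighting, and performs the validity battery: exact r x c
    contingency analysis (Fisher-Freeman-Halton), tie-corrected
    Kruskal-Wallis tests with Dunn-Bonferroni post-hoc comparisons, and
    Pearson correlation screens against companion dyspepsia scales (VAS,
    TDS, SDS, FD-QoL). A seeded synthetic-cohort generator with latent
    pattern classes supports end-to-end testing and parameter-recovery
    studies without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
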