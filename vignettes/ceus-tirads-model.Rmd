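---
title: "The CEUS-TIRADS model: scoring, re-grading and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CEUS-TIRADS model: scoring, re-grading and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceustirads)
```

## The clinical problem

Thyroid nodules graded C-TIRADS 4 (sub-categories 4a, 4b, 4c) are the
diagnostically uncertain middle of the Chinese TIRADS scale: their
malignancy risk spans roughly 2–90%, conventional ultrasound alone calls
too many benign nodules malignant, and the usual consequence is an
invasive fine-needle aspiration. Contrast-enhanced ultrasound (CEUS)
images the micro-vascularity of a nodule and its qualitative features
separate benign from malignant lesions reasonably well, but has no
widely agreed diagnostic criterion. This package implements a combined
model: an integer-weighted CEUS score is used to shift the C-TIRADS
category of a nodule by at most one level, and the shifted category is
dichotomised into a benign/malignant call.

## The model

**C-TIRADS counting.** Five suspicious conventional-ultrasound signs —
solid composition, markedly hypoechoic echotexture, vertical
orientation, microcalcifications, ill-defined or irregular margin
(including extrathyroidal extension) — each add one point; the benign
comet-tail artifact subtracts one. A score of 1 maps to category 4a, 2
to 4b, 3–4 to 4c. For totality `category_from_score()` also maps −1/0
to category 3 and 5 to category 5, following the published counting
table the study grading is based on; the study cohort itself only
contains 4a–4c.

**CEUS score.** Four risk features enter a weighted sum:
hypo-enhancement (weight 2), later arrival time, heterogeneous
enhancement, and centripetal enhancement (weight 1 each), giving a
score in 0–5. The weights discretise multivariable logistic odds
ratios: the dominant feature gets 2, the rest 1 (`derive_weights()`).
Earlier washout is a recognised malignancy sign and is carried in the
data model, but it was dropped from the multivariable model and never
contributes to the score. Two findings are standalone benign
indicators that override the score entirely: absent enhancement, and a
regular peripheral hyper-enhancement ring. The dichotomous CEUS call is
malignant when no override applies and the score reaches the cutoff
(default 2, the ROC-derived operating point).

**Combination rule** (`regrade()`). Per nodule, starting from the
C-TIRADS category:

* absent enhancement → the combined category is set to 3 outright;
* ring, or score < 2 → one category down;
* score = 2 → unchanged (deliberate: the borderline score should not
  create false positives);
* score > 2 → one category up.

Combined categories 4b, 4c and 5 are called malignant; 2, 3 and 4a
benign.

One published worked example deserves a note: a nodule described with
all four risk features (later arrival, hypo-enhancement, heterogeneous,
centripetal) is quoted with a score of 4, yet the stated weights sum to
5. The package follows the weights — that panel scores 5 — which leaves
every downstream result of the example unchanged, since both 4 and 5
exceed the upgrade threshold.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `weights` | 2/1/1/1 | integer weight per CEUS risk feature (dimensionless points) |
| `cutoff` | 2 | CEUS score at or above which the CEUS call is malignant |
| `alpha` | 0.05 | significance level of the univariate feature screen |

The re-grading thresholds themselves (score < 2 / = 2 / > 2) are part
of the published rule and are fixed; `cutoff` only parameterises the
standalone CEUS call, so that re-derivation experiments (different
weights, different operating points) remain possible without touching
the combination rule.

## Decisions the published rule leaves open

* **Override precedence.** Absent enhancement beats the ring, and both
  beat the score threshold. The source treats no enhancement and the
  ring as standalone benign indicators and its false-negative
  accounting counts ring-positive nodules as benign-called regardless
  of score; a ring with score ≥ 2 is therefore resolved benign. Only 1
  of 116 malignant nodules in the study carried a ring, so the choice
  is empirically near-neutral either way.
* **Clamping at the scale ends.** The combined scale in practice is
  {3, 4a, 4b, 4c, 5}: a downgrade bottoms out at category 3 (an input
  of category 2, which the study never feeds, stays 2), an upgrade caps
  at 5, and absent enhancement sets category 3 from anywhere. This
  makes `regrade()` total over all 6 × 6 × 3 combinations of category,
  score and override, which the test suite enumerates exhaustively.
* **Score-2 nodules.** Kept at their input category even though the
  standalone CEUS call at the default cutoff is malignant; a 4a nodule
  with score 2 ends benign. This mirror of the published rule is
  deliberate and tested.

## Statistics

The feature screen is the plain Pearson chi-square without continuity
correction — the convention that reproduces the published screening
statistics (arrival time 24.333, washout 3.216, enhancement degree
39.21) from their own count tables; enhancement degree is tested as a
3-level factor and enters the multivariable model as a single
hypo-vs-other indicator, matching the single reported odds ratio.
Covariates use the two-sample t-test; because published tables report
only summaries, a summary-statistic form (`t_test_summary()`) sits
alongside the sample form, and the pooled-variance Student form is the
default (it reproduces the published age p-value of 0.001).

`fit_logistic()` is a maximum-likelihood logistic fit by iteratively
reweighted least squares (deviance tolerance 1e-8, at most 50
iterations, intercept always included), with standard errors from the
inverse observed information. Perfect separation is detected from
boundary fitted probabilities and flagged as non-converged rather than
returning divergent estimates; linearly dependent predictors are an
error. Odds ratios of 2×2 tables use the cross-product ratio with a
Woolf log-scale interval; zero cells are an error unless the
Haldane–Anscombe +0.5 correction is requested explicitly.

Diagnostic performance: sensitivity, specificity and accuracy follow
the usual definitions (accuracy is exactly the prevalence-weighted mix
of the other two, a property the tests assert). The AUC of a
dichotomous call is the single-threshold trapezoid
(sensitivity + specificity)/2 — this exactly reproduces the published
validation-cohort AUCs of 0.798 and 0.873 from their count tables. The
AUC of an ordinal score is the Mann–Whitney pair probability with ties
counted half, checked against an exhaustive pairwise-enumeration oracle
to 1e-12. Confidence intervals and the paired comparison of correlated
AUCs use the DeLong structural-components variance; a degenerate
variance collapses the interval with a warning, and identical
predictors compare with delta 0 and p 1 by definition. The Youden
cutoff scans every observed score value (call positive at or above the
threshold) and breaks ties toward the lowest threshold.

## The synthetic generator and the fixture builder

`simulate_cohort()` emulates the structure of the 228-nodule study
cohort: prevalence 116/228; per-class category frequencies; absent
enhancement in 20/112 benign and no malignant nodules; class-conditional
CEUS feature marginals (e.g. hypo-enhancement in 73/116 malignant vs
18/92 benign enhancing nodules); age and size as truncated normals from
the published per-class means and SDs. US features are back-filled at
random so that every record's counting score matches its category (4c
records draw a score of 3 or 4 with equal probability — the source does
not split them). All of this is deterministic given the seed, and the
generator restores the global RNG state.

Features are **conditionally independent given class**, because only
marginals are published. Two consequences matter for interpreting
tests. First, passing large-sample tests shows marginal fidelity, not
joint realism: real CEUS features are correlated (hypo-enhancing
nodules are disproportionately heterogeneous and centripetal). Second,
under conditional independence the population logistic coefficients
equal the class-conditional marginal log odds ratios, and with these
marginals the centripetal odds ratio (≈45) dominates hypo-enhancement
(≈7) — so logistic fits on simulated cohorts systematically rank
centripetal first, whereas the published multivariable analysis (fit on
the real, correlated records, which are not available) ranked
hypo-enhancement first with an odds ratio of 39. The published ordering
cannot be reproduced from published information by any
conditionally-independent generator; the tests document both facts: a
recovery test asserts the generator reproduces its own generating
marginal odds ratios, and the acceptance-level check of the published
ordering fails honestly.

`build_fixture()` exists precisely because simulated joints cannot
reproduce printed joint counts. It solves for an integer assignment
over (pathology × input category × re-grading trigger) cells under the
printed constraints, honouring them in priority order: class totals
(116/112), then the combined-model confusion (111, 16, 5, 96), then the
destination counts, then the per-category class splits. The printed
splits sum to 115 malignant / 113 benign — one off each way — so the
lowest-priority group is relaxed by one nodule (category 4b holds 68
malignant / 46 benign), and the C-TIRADS and CEUS confusion rows then
come out one off per cell from their printed versions; every such
relaxation is reported on the returned cohort. Where the narrative
gives two different counts of malignant 4b downgrades (2 in one
paragraph, 3 in another), the builder uses 3, the only value consistent
with the five final false negatives. Cells the narrative does not pin
down (the benign/malignant split of 4b keep-vs-upgrade nodules, one
benign 4c nodule among keep/upgrade) place benign nodules at the
borderline score 2, reflecting the remark that score-2 cases are the
marginal ones; no printed count depends on this choice. Each cell is
materialised with a canonical CEUS panel attaining its trigger and a
canonical US feature set attaining its category, so `apply_model()` on
the fixture reproduces every non-relaxed count exactly — the end-to-end
test the suite runs.

`table2_cohort()` is a third, deterministic reconstruction used only
for contingency-level checks: 208 enhancing records whose per-feature
class-conditional marginals equal the published screening table, with
feature columns filled independently (staggered, not nested). Its joint
combinations are arbitrary; it is the right input for
`univariate_screen()` and the wrong one for pipeline counts.

## Problem sizes and numerical checks in the test suite

The parameter-recovery property runs 200 seeds at n = 5000 (about half
a minute); the large-sample marginal check uses one cohort of 50,000;
the screen-stability property 120 seeds at the study size n = 228. The
DeLong interval's coverage is measured over 2000 Monte-Carlo replicates
of 20 + 20 records with normal scores separated to a true AUC of 0.70 —
a separation typical of a moderate diagnostic marker, where the
asymptotic variance is expected to be well calibrated — and must land
in 95 ± 2%. The paired DeLong test's power is checked at n = 200
against predictors with true AUCs 0.9 vs 0.6 (rejection in at least 95%
of 500 replicates).

## Known limitations

* The generator models no inter-feature correlation beyond class
  conditioning and no reader variability; its covariates are carried
  but unused by the model, as in the source analysis.
* Discovery-cohort ordinal AUCs printed in the source (0.753, 0.803,
  0.916) match neither the Mann–Whitney estimator nor the
  single-threshold trapezoid recomputed from the printed counts; the
  computation that produced them is not recoverable and the package
  does not attempt to reproduce them. The re-computable ordinal AUC of
  the C-TIRADS categories from the printed per-category splits is
  0.808.
* The published multivariable odds ratios (39/24/12/6) are treated as
  given inputs to the weight derivation; they cannot be re-estimated
  without the per-nodule records.
* The model consumes already-coded features; image acquisition and
  sonographic interpretation are out of scope.
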