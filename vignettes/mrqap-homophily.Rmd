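---
title: "Methods: dyadic homophily analysis with MR-QAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic homophily analysis with MR-QAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collabnet)
```

## The data and the model

The package analyses directed, valued collaboration networks collected by
an egocentric sociometric instrument: each respondent names colleagues and
rates tie strength on a five-point scale. The dependent variable is the
n × n adjacency matrix of strengths 0–5 (0 = no nomination), with a
dichotomized 0/1 version analysed in parallel. Ties to alters who are not
themselves respondents are excluded before any computation — with n
respondents the analysis set is exactly the n(n−1) ordered
respondent–respondent dyads — and the exclusion counts are always logged.

Homophily enters through dyadic covariates, all symmetric even though the
response is directed:

* **difference** — |x_i − x_j| for continuous attributes (age, years
  since graduation, NHS/LHA tenure, publication count). Zero means the
  two actors are identical, so a *negative* coefficient means similarity
  predicts collaboration (homophily), a positive one heterophily.
* **match** — 1 iff both actors share a category (EBM attitude, gender,
  specialization, managerial role, hospital, directorate). A *positive*
  coefficient is homophily.
* **tie** — a binary relational control (co-authorship: sharing at least
  one publication).
* **distance** — km between the actors' sites, looked up in a
  user-supplied symmetric site-distance table (never computed from
  coordinates, which the source data lack).

The model is a linear probability / linear strength model over ordered
dyads, y = β₀ + Xβ + ε, fitted by OLS. Reported "Estimate" values are
standardized coefficients — y and each column of X z-scored with the
population SD over included dyads — so the intercept is identically zero
and magnitudes are comparable across predictors; raw coefficients are
always retained alongside.

## Permutation inference

Dyads within one network are not exchangeable, but *node labels* are:
permuting rows and columns jointly preserves every label-invariant
feature of the dependence structure. Two schemes are implemented:

* **y_permute** — permute the response matrix only, refit, collect all
  coefficients.
* **DSP** (default) — Dekker double semi-partialing: for predictor k,
  residualize X_k's matrix on the other predictors plus intercept, permute
  the residual matrix, refit with the permuted residual in X_k's place,
  and collect that coefficient. DSP is the default because dyadic
  covariates are typically collinear (e.g. hospital and directorate
  matches), and semi-partialing makes the permuted statistic pivotal in
  that setting.

P-values use the add-one convention p = (#exceedances + 1)/(n_perm + 1),
so the smallest attainable value is 1/(n_perm + 1) and p is never zero.
Both one-sided proportions and the two-sided value are reported; the
output table stars the two-sided p at 0.05 (\*\*) and 0.01 (\*\*\*).

A deliberate choice: exceedances are counted on the **raw** coefficient
scale. By Frisch–Waugh the observed raw coefficient of X_k equals the
coefficient of its residual on the other predictors, so observed and
permuted statistics live on the same scale; standardized coefficients
would bring in the permuted residual's SD, which differs (slightly, and
only under masking) from the observed predictor's SD. Since the raw and
standardized coefficient differ by a positive factor, the choice does not
change which associations are ranked extreme under either one-sided tail.

## Missing data

A missing attribute on either member of a dyad masks that dyad in the
derived covariate; the regression excludes, listwise, the union of all
covariate masks (plus any missing response cells), and every permuted fit
keeps the same exclusion set. Masks are symmetric by construction because
attribute missingness affects both directions of a pair. If a permutation
maps a masked cell onto an included dyad (possible only in masked
designs), that replicate's coefficient is computed by an exact
complete-case refit rather than the fast projection path.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dichotomize_threshold` | 1 | strength | any nomination counts as a tie; the cut-off is a config parameter since reasonable analyses may require stronger ties |
| `n_perm` | 2000 | permutations | two-sided p resolved to 5 × 10⁻⁴; 500 suffices for screening |
| `method` | `"dsp"` | — | robust to collinear covariates; `y_permute` kept for cross-checks |
| `alpha` | 0.05 | — | conventional two-sided criterion |
| `seed` | required | — | no hidden global randomness; identical seeds give bit-identical results |

Duplicate nominations of the same alter resolve to the **maximum**
strength — idempotent, order-independent, and monotone (a respondent who
ever reports a strong tie has one). Self-nominations are dropped and
counted. The network is never symmetrized by default (observed arc
reciprocity is far below 100%); `symmetrize_max()` exists as an explicit
utility only.

## The synthetic generator

`synth_config()` defaults emulate the surveyed 297-physician system:

* attributes drawn independently per node — truncated normals for age
  (47.01 ± 8.01, 30–67), years since graduation (27.05 ± 8.69, 7–55),
  NHS tenure (16.01 ± 9.74, 1–41) and LHA tenure (10.95 ± 7.94, 1–37),
  all rounded to whole years; gender Bernoulli(158/297); a 4-level EBM
  attitude with probabilities (0.01, 0.13, 0.73, 0.13) chosen to give
  mean 2.98 and SD ≈ 0.56; categorical hospital/directorate/specialty
  shares at the published percentages; negative-binomial publication
  counts (mean 4.27, dispersion 0.22 so the SD ≈ 9.3);
* co-authorship as a Poisson number of co-author pairs (expected
  `n · coauthor_rate / 2`, default rate 3 giving mean co-authorship cell
  ≈ 0.01 at n = 297), sampled with 4× weight on same-directorate pairs;
* a logistic tie model P(arc i→j) = logit⁻¹(θ₀ + Σ θ_k x_k(i,j)) applied
  independently per ordered dyad, strengths 1–5 drawn from a distribution
  with mean ≈ 3.3 so the valued mean × 100 sits near the observed 5.7;
  θ₀ = −4.46 places the arc density near the observed ~1.7–2% once the
  default planted effects (positive same-specialty/hospital/directorate/
  EBM-attitude/co-authorship, negative seniority-difference,
  publication-difference, managerial-match and distance effects, signs
  matching the published table) are active.

What it deliberately does **not** emulate: joint attribute dependence
(specialty and directorate are confounded in the real system; a
`directorate_specialization_coupling` knob exists but defaults to 0),
reciprocity (arcs are independent by default, so generated reciprocity ≈
density; `reciprocity_boost` ≈ 4.5 reaches the observed ~61% regime when
realistic fixtures are wanted), degree heterogeneity beyond what the
covariates induce, and any fitting of the planted θ to the published
regression table (impossible without the data). Consequently, passing
recovery tests show the estimator works *under the generator's
assumptions* — independent dyads given covariates — not that the original
survey's coefficients are reproduced.

The site-distance table is synthetic: a plausible symmetric km matrix
over the six named hospitals spanning 0–77 km, matching the published
range; it is an input, replaceable by any real table.

## Numerical choices

* Population (divide-by-N) variance and SD throughout the descriptives —
  the convention under which a binary network's off-diagonal variance is
  exactly p(1 − p).
* OLS via QR; rank deficiency or a constant column aborts with the
  offending column named rather than silently dropping terms.
* Adjusted R² = 1 − (1 − R²)(N − 1)/(N − k − 1) with N included dyads —
  the naive convention, stated rather than tuned to any published value
  (network-analysis packages differ here).
* The permutation engine gathers each permuted matrix through a
  precomputed linear-index map and evaluates DSP coefficients by projection
  onto a cached orthonormal basis of the other predictors, in blocks of
  250 permutations — BLAS-3 throughout, so a 13-predictor, 87,912-dyad,
  2,000-permutation run takes ~2 minutes on one CPU.
* Degenerate permuted residuals (numerically zero projection norm) score
  a coefficient of 0 rather than NaN.
* Arc reciprocity is defined as 0 for an empty network; symmetric-pairs
  counts include null–null pairs. The published reciprocity/symmetry
  percentages for the valued matrix cannot be re-derived without the
  data, so these definitions are declared, not reverse-engineered.

## Problem sizes in the test suite

The suite exercises brute-force oracle comparisons at 12–15 nodes, QAP
calibration at n = 30 (300 replicates × 500 permutations), planted-effect
recovery at n = 100 (100 replicates × 500 permutations, full
13-predictor panel), and one full survey-scale run (n = 297, 2,000
permutations). These sizes give stable Monte-Carlo verdicts (binomial
99% bands) at a few minutes per experiment.

## Known limitations

* Linear probability model for the binary response — no logistic or
  ordinal QAP variants.
* No ERGM-style structural terms (transitivity, reciprocity) in the
  regression; the QAP null conditions only on node labels.
* Listwise deletion is the only missing-data strategy.
* The generator's independence assumptions understate the dependence of
  real sociometric data; calibration results transfer to real data only
  to the extent QAP's exchangeability argument holds there.
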