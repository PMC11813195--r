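---
title: "Methods: nonresponse-adjusted burnout prevalence estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonresponse-adjusted burnout prevalence estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

Voluntary well-being surveys observe burnout only among responders. If the
probability of responding depends on characteristics that also relate to
burnout — or on burnout itself — the responder prevalence is a biased
estimate of the population prevalence. The pipeline in this package
addresses the part of that bias that is *explainable by observed features*:
per-physician EHR-use measures (workload, efficiency, proficiency) that
exist for responders and nonresponders alike.

The estimator has four stages:

1. **Scoring.** The 10-item burnout battery (0–4 Likert) is averaged over
   answered items and rescaled to 0–10 (× 2.5); ≥ 3.325 flags burnout
   symptoms; ≥ 4 answered items of 10 defines a survey response. When 4–9
   items are answered we score the mean of the available items rather than
   imputing — the response definition guarantees at least 4 items, and the
   mean of a subset is an unbiased estimate of the full mean under
   item-exchangeability.
2. **Response propensity.** Elastic-net logistic regression (mixing
   α = 0.5) of response on features, 10-fold cross-validation grouped by
   physician (both waves of one physician share a fold, preventing
   within-physician leakage). Every invitation receives an out-of-fold
   propensity p.
3. **Weighted ensemble.** Three elastic-net linear regressions of the
   burnout score on features, with observation weights 1 (unweighted),
   1/max(p, 0.1) (full-population target; the 0.1 floor caps weights at 10),
   and 1 − p (nonresponder target). On a physician-level 20% calibration
   split of always responders, actual scores are regressed (OLS) on the
   three predictions; the coefficients β₀..β₃ define the bias-corrected
   ensemble. Scores convert to probabilities via the logistic link
   σ((ŷ − 3.325)/s).
4. **Combination.** Population prevalence = (Σ observed flags + Σ predicted
   probabilities) / (total invitations), a group-size-weighted convex
   combination; percentile bootstrap over physicians, with Bernoulli
   resampling of predicted probabilities to propagate prediction
   uncertainty.

# Tunable parameters

| parameter | default | units / scale | why |
|---|---|---|---|
| burnout threshold | 3.325 | 0–10 score | instrument validation cutoff; fixed |
| response rule | ≥ 4 of 10 items | count | single definition used everywhere downstream |
| propensity floor | 0.1 | probability | only inside the 1/p weights; stored propensities are never truncated |
| elastic-net mixing | 0.5 | — | correlated feature families make pure lasso unstable; pure ridge drops no features |
| CV folds | 10 | count | grouped by physician |
| train fraction | 0.8 | proportion of physicians | 80/20 split; 340 physicians split 272/68 |
| sigmoid scale s | sd(residuals)·√3/π | score points | see below |
| operating threshold | Youden's J on calibration | probability | single sensitivity/specificity pair |
| jitter | triangular(−0.5, 0, 0.5) | propensity units | reduction experiment |
| selection | lowest 20%, ≥ 50 of 100 cycles | — | reduction experiment |

**Sigmoid scale.** The score-to-probability link treats the unexplained part
of the burnout score as logistic noise around the prediction:
P(score ≥ τ | ŷ) = σ((ŷ − τ)/s). We set s so that the implied logistic
error has the *same standard deviation* as the calibration residuals:
a logistic distribution with scale s has SD sπ/√3, hence
s = sd(residuals)·√3/π. Using the raw residual SD as the scale would imply
an error distribution √3/π⁻¹ ≈ 1.8× too wide, compressing all probabilities
toward 0.5 and dragging the predicted nonresponder prevalence toward 50%
regardless of the data.

**Operating point.** The single sensitivity/specificity pair is computed at
the probability threshold maximizing Youden's J on the calibration split,
then applied unchanged to the test split. Any threshold rule would do; this
one is conventional and uses no test-set information.

**Test population.** Individual-level accuracy is evaluated on partial
responders' response-year observations — the physicians most similar to
nonresponders for whom actual scores exist. The final model used for
nonresponder prediction is refit on *all* responses (always responders plus
partial responders' response years).

# The synthetic cohort generator

The generator emulates the structure of a two-wave physician well-being
survey joined to EHR-use metadata, with full ground truth:

- **Features.** k = 12 correlated latent Gaussians (compound-symmetric
  ρ = 0.3 across features; correlation 0.7 across waves via a physician
  component), exponentiated (log-SD 0.5) for workload-like right skew, with
  a 10% per-(physician, feature) structural zero. A structural zero also
  sets the latent value to −2: "no clinical activity" is genuinely
  informative, pairing zero workload with low response propensity — the
  never-responder phenotype.
- **Latent burnout.** burnout_mean + zᵀβ_b + physician intercept + wave
  noise, clamped to [0, 10] (clamping rather than truncation keeps the
  3.325 threshold interpretable). The intercept/noise split (SD 2.0 total,
  0.8 wave-level) makes both waves of a physician correlated, which the
  partial-responder contrasts require.
- **Response.** logit P(response) = 3.285 + zᵀβ_r − m·(burnout −
  burnout_mean). m = `mnar_strength` is the *suppression* of response per
  point of latent burnout: m = 0 gives missingness at random given
  features; m > 0 makes burned-out physicians less likely to respond in a
  way no feature-based model can fully see.
- **Items.** Responders answer all 10 items, each Binomial(4, score/10) —
  binomial thinning is mean-faithful (expected rescaled item mean equals
  the latent score) without asserting a full polytomous IRT model.

**Calibration of defaults (done once, a priori).** The defaults describe a
specific world: 477 physicians, 88 invited in one wave; response intercept
3.285, chosen by Monte Carlo so the *marginal* response rate is ~80.5%
(the marginal rate is below plogis(intercept) because feature effects add
logit-scale variance); burnout_mean 2.0, which with the structural-zero
shift (+0.2) and total SD ≈ 2.5 puts true prevalence near 31–33%; and
effect vectors β_r (strong response signal, logit SD ≈ 2.4) and β_b chosen
*anti-aligned* (corr ≈ −0.72 between the two linear predictors), so that
nonresponders' feature profiles predict markedly higher burnout. The
anti-alignment is deliberate and strong: in the emulated world the entire
observed-vs-predicted prevalence gap is carried by features, since any
model of nonresponders sees features only.

**What the generator does not emulate.** Real EHR vendor semantics, note
text or sentiment, seasonal/pandemic shocks, moment-matching to any real
feature table (only qualitative skew/zero-inflation structure), and
item-level missingness patterns within a response. A green test therefore
establishes that the *estimation machinery* recovers truth in a world with
the stated structure — not that any real cohort satisfies that structure.

# Numerical and design notes

- **Out-of-fold null AUROC is pessimistic, not 0.5.** With features
  independent of response, each fold's near-constant predictions carry an
  intercept fitted on the complementary folds, which anti-correlates with
  the held-out fold's response rate; mean out-of-fold AUROC sits around
  0.45 (n = 1000), a known artifact of cross-validated AUC under the null.
  The null test asserts no *spurious* discrimination (one-sided) rather
  than centering at 0.5.
- **Weighting schemas are near-equivalent here.** Under direct
  missingness-not-at-random (m > 0), all three schemas underestimate the
  true nonresponder prevalence by a similar margin (pilot: signed error
  ≈ −0.40 each at m = 0.6), because the outcome-driven part of nonresponse
  is invisible to feature-based models; the 1 − p schema is not measurably
  better (10/20 pilot replicates). The suite asserts agreement within the
  piloted band rather than a superiority that the data do not show.
- **Bias-correction degeneracy.** If the three schema predictions are
  collinear (e.g. all models shrink to the intercept), the OLS falls back
  to ridge with a 10⁻⁸ penalty, with a warning. OLS optimality guarantees
  the ensemble never has higher calibration MSE than any single schema.
- **Exact small-sample tests.** The signed-rank test drops zero
  differences, uses midranks for ties, and is exact (full sign-flip
  enumeration, two-sided by symmetric distance) up to 16 nonzero pairs;
  beyond that, a tie-corrected normal approximation. Fisher's test is exact
  through 2×3 tables and Monte Carlo (fixed internal seed) beyond.
  Degenerate inputs (zero-variance measures, all-zero differences) are
  flagged rather than given arbitrary p-values. No multiple-testing
  correction is applied anywhere.
- **Combination conventions.** Survey-level combination (each invitation
  one unit) is the default; physician-level combination (average within
  physician first) is available because the two conventions genuinely
  differ whenever physicians contribute unequal invitation counts, and
  published headline figures do not always state which was used.
- **Reduction no-op.** `frac_selected = 0` selects no candidates and
  reproduces the fully informed run exactly (same derived seeds,
  deterministic pipeline); for any positive fraction the per-cycle
  candidate count is max(1, floor(frac·n)).
- **Determinism.** Every stochastic step (cohort, folds, splits,
  bootstraps, jitter) derives its seed from the configuration; identical
  configuration gives byte-identical cohorts and identical reports.

# Known limitations

- Direct outcome-driven nonresponse is fundamentally unidentifiable from
  features; the estimator corrects feature-explainable bias only, and under
  strong direct MNAR the combined estimate remains conservative (between
  the observed rate and the unknowable truth).
- Individual-level burnout prediction from EHR features is weak (here as in
  the literature); the pipeline's value is at the group level.
- The partial-responder test set is small in realistic cohorts, so
  individual-level evaluation metrics carry wide intervals.
- Linear models only; no interactions or nonlinear learners, by design.
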