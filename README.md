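# burnoutprev

Nonresponse-adjusted estimation of physician burnout prevalence from
EHR-use metadata.

## The problem

Physician well-being surveys are voluntary, and physicians experiencing
burnout may respond at systematically different rates, so the prevalence
observed among responders can misrepresent the population. Electronic
health record (EHR) use metadata — workload, efficiency, and proficiency
measures collected for every physician regardless of survey behaviour —
offer a window into nonresponders. This package implements a pipeline that
uses those features to (1) model each survey invitation's response
propensity, (2) predict burnout scores for nonresponders with a
propensity-weighted model ensemble, and (3) combine observed and predicted
prevalence into a population-level estimate. It is aimed at biostatisticians
and survey methodologists who need a tested, reproducible implementation of
this estimation strategy, with a synthetic-cohort generator providing ground
truth for validation.

## The method

**Burnout score.** Ten items scored 0–4 (Likert) are averaged and rescaled
to 0–10 (× 2.5); a score ≥ 3.325 flags burnout symptoms. An invitation is a
*response* when ≥ 4 of 10 items are answered. Physicians are *never*,
*partial*, or *always* responders by their pattern over two survey waves.

**Response propensity.** p = P(response | features) is estimated by
elastic-net penalized logistic regression with 10-fold cross-validation
grouped by physician; every invitation is scored out-of-fold.

**Weighted ensemble.** Three penalized linear regressions predict the
continuous burnout score from features, weighted per schema:

| schema | weight | approximates |
|---|---|---|
| unweighted | 1 | responder population |
| 1/p | 1 / max(p, 0.1) | full population |
| 1−p | 1 − p | nonresponder population |

On a held-out calibration split (a physician-level 80/20 split of always
responders), actual scores are regressed on the three predictions
(OLS); the resulting β coefficients define the bias-corrected ensemble
ŷ = β₀ + β₁ŷ_unw + β₂ŷ_1/p + β₃ŷ_1−p. Predicted scores convert to burnout
probabilities with a logistic link centered at the threshold,
P(burnout) = σ((ŷ − 3.325)/s), with s matched to the calibration residual
SD.

**Population estimate.** With n_r observed responses (burnout flags b_i)
and n_n nonresponses (predicted probabilities π_j),

    prevalence = (Σ b_i + Σ π_j) / (n_r + n_n),

with percentile bootstrap CIs resampling physicians (and Bernoulli-
resampling the π_j). A jitter-and-select procedure (triangular jitter on
propensities, repeated candidate selection of the lowest 20%) synthetically
reduces the response rate to validate behaviour at lower response rates.

## Worked example

```r
library(burnoutprev)

cohort <- generate_cohort(generator_config(n_physicians = 200, seed = 1))
result <- run_pipeline(cohort, pipeline_config(seed = 1, n_boot = 50))
print(result)
```

```
nonresponse-adjusted burnout prevalence pipeline
  physicians: 200 (never 19 / partial 37 / always 144)
  invitations: 363, responses: 295 (81.3%)
  response-propensity AUROC: 0.883 (95% CI 0.842-0.930)
  burnout AUROC on partial responders: 0.509
population burnout prevalence (survey-level combination)
  observed  (n=295 responses):    27.8%
  predicted (n=68 nonresponses): 52.3% (95% CI 43.2-60.7%)
  population:                    32.4% (95% CI 26.0-36.9%)
```

Reading the output: EHR features discriminate responders from nonresponders
well (AUROC 0.88), individual-level burnout prediction is weak (AUROC ~0.5
on the small partial-responder test set), yet the *group-level* signal is
informative: nonresponders' feature profiles predict a 52% burnout
prevalence against the 28% observed among responders, lifting the population
estimate to 32%. The synthetic truth for this cohort (31.4% at invitation
level) lies inside the CI. In this generator world, burned-out physicians
are genuinely less likely to respond through their feature profiles, so the
observed prevalence underestimates the population — exactly the bias this
estimator corrects.

The reduction experiment:

```r
red <- run_reduction_experiment(cohort, pipeline_config(seed = 1, n_boot = 50),
                                reduction_config(frac_selected = 0.2, seed = 9))
print(red)
```

## Command line

```sh
Rscript inst/cli/burnoutprev.R simulate --out cohort/ --seed 1
Rscript inst/cli/burnoutprev.R pipeline --cohort cohort/ --out run1/ --seed 1
Rscript inst/cli/burnoutprev.R reduce --cohort cohort/ --out red1/ --seed 1
```

Artifacts are plain CSV/JSON with a run manifest (config echo, versions,
seeds); identical configuration reproduces identical artifacts.

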