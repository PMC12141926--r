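---
title: "Parenclitic network mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parenclitic network mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parenclitic)
```

## The problem and the method

Severity scores such as SOFA treat organ systems as independent and sum
their dysfunction. Network physiology instead asks how organ systems are
*coupled*, and whether the coupling differs between patients who survive
and patients who do not. This package implements that programme for
routine laboratory panels in two stages.

**Population stage.** For one outcome group (say, 30-day survivors), every
pair among the 15 panel variables (`lab_registry()`) is tested for Pearson
correlation. Missing laboratory values are handled by pairwise deletion:
each pair uses only the patients with both values observed. With
$m = 15$ variables there are $\binom{15}{2} = 105$ tests, so an edge is
drawn only when its two-sided p-value (from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df) is at or below the Bonferroni
threshold $\alpha/105 = 0.00047619$ at $\alpha = 0.05$. The result is a
binary adjacency matrix plus signed correlation weights
(`build_network()`, `export_network()`).

**Individual stage.** Correlation is a population property; a single
patient has no correlation. The parenclitic idea is to measure how far a
patient's data point lies from the *reference population's* trend. For
each significant pair we fit an orthogonal (total least squares)
regression line on the reference population — survivors for the 30-day
outcome, non-deteriorated patients for the 48-h outcome — and the
patient's parenclitic deviation (PD) for that pair is the perpendicular
distance of their $(x, y)$ point from that line (`fit_orthogonal_line()`,
`compute_pd_matrix()`). TLS is used rather than ordinary least squares
because both variables are measured with error and neither is a natural
regressor: the TLS line is the first principal axis of the $2 \times 2$
covariance matrix, passes through the centroid, is symmetric in the two
variables, and remains well defined for vertical trends (slope/intercept
are derived outputs only).

The evaluation battery (`run_survival_pipeline()`) then mirrors a standard
clinical workup: Mann–Whitney comparison of PD between outcome groups
with the effect size $r = |Z|/\sqrt{n_0+n_1}$; for separating edges, a
multivariate Cox model of 30-day survival on the z-normalized PD plus the
edge's two variables, SOFA and ventilation status; for Cox-significant
PDs, ROC analysis with DeLong confidence intervals, the Youden cut-off,
and a Kaplan–Meier / log-rank comparison of the two predicted classes.

## Statistical conventions that matter

* **Mann–Whitney orientation and approximation.** $U$ counts
  comparison-group wins (plus half-ties), so $U/(n_0 n_1)$ is the
  probability that a non-survivor's PD exceeds a survivor's — which is
  exactly the empirical ROC AUC. The package computes both from the same
  ranks, so the identity is exact on every dataset. The deviate $Z$ uses
  the tie-corrected normal approximation *without* continuity correction;
  this convention reproduces published effect sizes recomputed from
  $(U, n_0, n_1)$ triples to three decimals (`effect_size_from_u()`).
* **Significance gates are inclusive** ($p \le$ threshold), matching the
  threshold's published form.
* **Cox ties** default to Efron; PDs are continuous so ties are rare, and
  Efron is the less-biased choice. Breslow is available for emulating
  software that defaults to it. Wald CIs use $\exp(\beta \pm 1.96\,SE)$.
* **DeLong machinery** is computed from placement values in-package (the
  pipeline controls score orientation, and the calibration studies run
  thousands of replicates); `pROC` serves as an independent cross-check in
  the test suite. For unpaired comparisons the p-value uses the asymptotic
  normal reference; `pROC` pushes the identical z statistic through a t
  reference, a difference visible only in the third decimal of p.
* **Youden classification** predicts the poor outcome when score
  $\ge$ cut-off; ties at the cut-off go to the predicted-poor class, and
  the lowest maximizing cut-off is reported when several tie on $J$.
* **Quartiles** in descriptive tables use linear interpolation between
  order statistics (R's type 7), stated because summary tables rarely
  document a rule.
* **Missing covariates are never imputed.** Every model drops incomplete
  rows and logs the count; pairwise deletion at the correlation stage and
  per-edge complete-case Ns downstream reproduce the differing Ns that
  pairwise-deleted analyses produce.

## Numerical choices and degenerate inputs

The TLS fit refuses clouds with fewer than 3 points, identical points, or
an isotropic covariance (equal eigenvalues within $10^{-12}$ relative — no
direction is defined). Pairs that cannot be evaluated at the network stage
(fewer than 3 complete pairs, zero variance) are recorded with a reason
and counted as non-significant rather than dropped; edges evaluated on
fewer than 10 pairs carry a low-n flag in exports. Perfect collinearity
reports $p = 0$, the boundary convention. PD is the unsigned distance
(reference tables report strictly positive means); the signed residual is
available as a diagnostic. Distances are computed in raw variable units
with no pre-standardization: published PD magnitudes track raw scales
(acid–base PDs of order 0.05 versus cell-count PDs of order 3–5), which
is inconsistent with standardized inputs. A consequence worth knowing:
PD is invariant under translation and rotation but *not* under per-axis
rescaling, so unit conventions must be fixed before fitting — the test
suite asserts both the invariance and the non-invariance. Reference
patients are scored against a line whose fit includes themselves, since
the method defines a single reference regression; a leave-one-out
sensitivity mode was considered and left out of scope as the reference
groups here (~130 patients) make the self-influence negligible.

Z-normalization of PD uses mean and sample SD over *all* patients with
that PD available, not only the reference group, because the downstream
Cox models are fit on whole-cohort complete cases.

## The synthetic cohort generator

Real critically-ill cohorts sit behind credentialed access, so the
generator (`default_config()`, `generate_cohort()`) emulates the study
conditions with known ground truth; every pipeline property is tested
against what was planted.

Each patient draws a latent severity class — "reference" with probability
$1 - 33/162$, "poor" otherwise. Labs come from a class-specific
15-variate normal on raw scales (e.g. arterial pH $\sim N(7.39, 0.052^2)$
in the reference class), truncated at plausibility bounds rather than
log-transformed so the linear correlation structure the analysis assumes
is preserved. The reference-class correlation matrix plants the survivor
map edges (WBC–platelets 0.6, INR–ALT 0.6, pH–HCO$_3^-$ 0.7,
urea–creatinine 0.8); the poor class plants WBC–phosphate 0.65,
lactate–pH $-0.7$, lactate–HCO$_3^-$ $-0.7$, urea–creatinine 0.8, with
pH–HCO$_3^-$ at $0.49 = (-0.7)(-0.7)$ — conditional independence given
lactate, the metabolic-acidosis structure; signs are a physiological
choice, as the emulated maps constrain only $|r|$.

Survival over 30 days is exponential with rate
$\lambda_0 \exp(\beta_{PD} z + \beta_S z_{SOFA} + \beta_V V)$, where $z$
is the standardized orthogonal distance of the patient's true
(pH, HCO$_3^-$) point from the planted axis (the TLS axis of the
reference class's true distribution). Defaults are anchored to the
published multivariate model: $\beta_{PD} = 0.733$ (hazard ratio 2.08 per
SD), $\beta_S = 0.47$ per SOFA SD ($\approx 0.21$ per point) and
$\beta_V = 1.0$. $\lambda_0$ is solved deterministically (internal
fixed-seed large-sample draw of the generator's own structures) so
marginal 30-day mortality matches $33/162$; administrative censoring at
day 30 encodes survivors as `time_days = 30`, `event30 = 0`. The 48-h
deterioration flag is Bernoulli with a logistic link on the same
deviation, intercept-solved per draw to the $30/162$ fraction — it is a
label generator, not a SOFA simulator.

Two calibration details deserve emphasis. First, observed outcome groups
are *mixtures* of latent classes (only part of the deaths come from the
poor class), which attenuates any class contrast by roughly the
difference in class composition between the groups; latent-class means
are therefore the published group medians inflated by a factor 2.2 about
the survivor anchor, so that the *observed* groups land near the
published contrasts. Second, missingness is MCAR per variable with
observation probabilities solved from published pairwise complete-case
counts (pH 0.73, HCO$_3^-$ 0.79, lactate 0.62 observed, INR/ALT 0.67,
near-complete elsewhere); the real mechanism is unknown and MCAR is the
weakest assumption consistent with pairwise deletion. What passing tests
therefore show is that the pipeline recovers planted structure under
Gaussian, MCAR, exponential-hazard conditions — they cannot certify
behavior under informative missingness, non-linear coupling, or real
laboratory error structure.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as:
default cohorts of 162; planted-recovery studies of 50 replicates at
$n = 1000$ with $\beta_{PD} = 0.7$ (true HR 2.01) and 50 null replicates;
family-wise error calibration over 2000 replicate null networks at
$n = 200$; DeLong size calibration over 2000 replicates at $n = 1000$;
Cox coverage over 200 replicates at $n = 500$; TLS brute-force oracle
scans over 100 clouds on a $10^4$-step angle grid. These sizes put
Monte-Carlo error well below the property margins being asserted.

## The deterioration outcome

The 48-h deterioration analysis groups patients by the deterioration
flag, with the non-deteriorated as reference population. The cohort
carries no time-to-deterioration, so the Cox stage treats deterioration
as an event with all follow-up ending at the 48-h assessment; with every
event tied at the same time the partial likelihood reduces to a
conditional-logit comparison, which is the appropriate reading of a
proportional-hazards model for a fixed-horizon binary endpoint. The
ROC/Kaplan–Meier stage always evaluates 30-day survival, the only
outcome with a follow-up time.

## Known limitations

* Single-edge deviations only: no per-patient graph summaries over the PD
  edge set, no kernel or non-linear parenclitic variants.
* Parametric Pearson gating; a rank-based alternative exists as a config
  option but is off by default to match the emulated analysis.
* No multiplicity control across edges beyond the network-stage
  Bonferroni gate (a Holm option exists for sensitivity analyses),
  mirroring the emulated workflow.
* The generator does not reproduce marginal distribution shapes beyond
  medians/IQRs, nor time-series dynamics; transfer-entropy-style dynamic
  coupling is out of scope.

## Worked example

```{r example, eval = FALSE}
res <- generate_cohort(default_config(), seed = 1)
net_s <- build_network(res$cohort, "survived30")
net_d <- build_network(res$cohort, "died30")
pd <- compute_pd_matrix(res$cohort, "survived30",
                        pd_edge_union(net_s, net_d))
report <- run_survival_pipeline(res$cohort, pd)
print(report)
```
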