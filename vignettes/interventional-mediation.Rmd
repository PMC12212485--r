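---
title: "Interventional (in)direct effects for three mixed-type mediators"
author: "intervmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional (in)direct effects for three mixed-type mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

A six-week smartphone intervention based on behavioural activation was
evaluated in two randomised trials in adults with depression (baseline
PHQ-9 at least 10) and comorbid hypertension and/or diabetes: one trial
individually randomised with stratification, the other cluster
randomised across 20 health facilities.  The intervention improved
depressive symptoms at three months but the evidence was weaker at six
months.  To learn which intervention features carry the effect, this
package decomposes the intervention's total effect on a binary six-month
outcome — an improvement of at least 50% in the PHQ-9 score from
baseline — into pathways through three mediators measured at three
months:

* **M1** (binary): the participant understood the session content
  without difficulty;
* **M2** (three levels): number of assigned activities completed,
  categorised none / 1–10 / 11–27;
* **M3** (score, 0–54): behavioural activation measured with the
  BADS-SF.

M1 and M2 exist only under intervention; control-arm participants are
assigned the *unexposed* level 0, which is what makes a
counterfactual contrast for these mediators well defined.

## Estimands

Let $A$ denote the randomised arm, $C$ baseline confounders, and
$G(a)$ the joint distribution of $(M_1, M_2, M_3)$ given $C$ under
exposure $a$; let $g_k(a)$ be the corresponding marginal distribution
of mediator $k$ alone.  Writing $P[a_Y; \cdot]$ for the standardised
mean of $Y$ when the outcome model is evaluated at exposure $a_Y$ with
mediators drawn from the indicated distributions, the package computes

$$
\begin{aligned}
\psi_{TE} &= P[1; G(1)] - P[0; G(0)] \\
\psi_{DE} &= P[1; G(0)] - P[0; G(0)] \\
\psi_{IE_1} &= P[1; g_1(1), g_2(0), g_3(0)] - P[1; g_1(0), g_2(0), g_3(0)] \\
\psi_{IE_2} &= P[1; g_1(1), g_2(1), g_3(0)] - P[1; g_1(1), g_2(0), g_3(0)] \\
\psi_{IE_3} &= P[1; g_1(1), g_2(1), g_3(1)] - P[1; g_1(1), g_2(1), g_3(0)] \\
\psi_{dep} &= \bigl(P[1; G(1)] - P[1; G(0)]\bigr) - (\psi_{IE_1} + \psi_{IE_2} + \psi_{IE_3}).
\end{aligned}
$$

These are *interventional* effects: mediator values are drawn from
counterfactual distributions rather than set to cross-world individual
values, so the decomposition is identified without cross-world
independence assumptions.  The residual term $\psi_{dep}$ captures the
pathway through the mediators' mutual dependence: it is near zero when
the mediators are conditionally independent given $C$ and the outcome
model has no mediator–mediator interactions, and non-zero when they
covary or interact.  By construction
$\psi_{TE} = \psi_{DE} + \psi_{IE_1} + \psi_{IE_2} + \psi_{IE_3} + \psi_{dep}$
exactly; the implementation telescopes the same Monte Carlo draws
through all regimes (common random numbers via inverse-CDF sampling),
so the identity holds to floating-point round-off on every run, not
just in expectation.

The indirect effects are defined sequentially in the order M1, M2, M3,
matching the theorised chain (understanding enables activity
completion, which raises activation).  Interventional decompositions
depend on this ordering; `fit_mediator_models(order = ...)` makes it
explicit and configurable.

## Models and estimation

Five nuisance models feed the estimator, all fitted on complete cases:

* M1: logistic regression on confounders, intervention arm only;
* M2: multinomial logit on confounders (marginal) and additionally on
  M1 (sequential-joint), intervention arm only;
* M3: linear regression on arm plus confounders (marginal) and
  additionally on M1 and the M2 indicators (sequential-joint), both
  arms, with the fitted residual SD retained for counterfactual draws;
* outcome: logistic regression of $Y$ on arm, M1, M2 (two indicator
  contrasts against "none"), M3, confounders, and configurable
  interactions.  The default interaction set is all three pairwise
  mediator–mediator interactions, M3 × baseline medication, and
  M3 × site in pooled runs; `moderated_mediation_test()` reports a Wald
  test for any of them.

Estimation expands the dataset $K$-fold (default $K = 1000$), draws
mediators for every expanded row under each regime, evaluates the
outcome-model probability, and averages — Monte Carlo integration over
the empirical covariate distribution, which is never resampled.  The
four-step construction is: expand; draw joint chains at each exposure
level; draw independent marginals; predict and average.

Counterfactual M3 draws add normal noise with the fitted residual SD
and are *not* truncated to the 0–54 score range: truncation would bias
the conditional mean implied by the fitted linear model.  A binary-M3
variant (`m3_family = "binomial"`) exists chiefly because it makes
every counterfactual mean exactly enumerable, which the test suite uses
as an oracle.

## Confounder screening

Baseline candidates are screened per site: a candidate is kept when a
univariable association model against any mediator or the outcome gives
p < 0.10 (Wald for single-coefficient models, likelihood-ratio joint
test for the three-level M2).  M1 and M2 are screened in the
intervention arm only — in the control arm they are structurally zero,
and including it would manufacture association.  Pooled analyses adjust
for the union of the two site selections plus a site indicator.
Screening runs once on the original sample and stays fixed across
bootstrap resamples; re-screening inside the bootstrap would change the
estimand from "effects adjusted for this confounder set" to "effects
under a random selection procedure".

## Inference

Confidence intervals are bias-corrected (BC, not accelerated)
nonparametric bootstrap intervals with $B = 1000$ resamples by default:
$z_0 = \Phi^{-1}\{(\#\{\theta^* < \hat\theta\} + \tfrac12\#\{\theta^* =
\hat\theta\})/B\}$, bounds at the bootstrap quantiles
$\Phi(2z_0 \pm 1.96)$, with $z_0$ clamped (and a warning raised) if the
proportion reaches 0 or 1.  Resampling honours each site's design: the
cluster-randomised site resamples whole clusters with replacement
(resampled clusters are relabelled so a cluster drawn twice contributes
two independent blocks); the individually randomised site resamples
within strata, with arm as the default stratum since the trial's true
randomisation strata are not recorded in the data model.  Pooled runs
resample each site by its own rule and concatenate.  Both the mediator
and the outcome models are refitted on every resample; replicates on
which any model is unfittable (single-arm resample, separation, rank
deficiency from an empty interaction cell) are dropped and counted,
with a warning above 5%.  The outcome model itself carries no cluster
random effect — clustering enters through the resampling design only.

## The synthetic-trial generator

`synthetic_config()` defines a structural model whose defaults *are*
the study conditions the package is tested under: 432 + 880
participants, seven baseline covariates with per-site truncated-normal
or Bernoulli distributions calibrated to the trial population (for
example age 59.7 (11.0) vs 54.9 (11.5) years, baseline medication use
11.3% vs 34.9%), stratified individual randomisation in one site,
20 cluster-randomised clusters with normal random intercepts
(SD 0.3 on the log-odds scale) in the other, and the mediator chain
M1 → M2 → M3 → Y.  Model intercepts were calibrated numerically (by
root-finding against large-sample simulation) so that the
intervention-arm mediator marginals match the targets of 77.5%
understanding, a 12.2 / 64.1 / 23.7% activity split, a control-arm
three-month BADS-SF mean of 25.4, and an overall outcome rate near
47%; outcome-model slopes were set so the implied effect components
are of realistic magnitude (total about +0.03, direct about −0.19,
indirect effects about +0.08, +0.10, +0.03).  Six-month PHQ-9 scores
are back-filled consistently with the drawn binary outcome rather than
modelled as trajectories, because the analysis uses only the binary
indicator; follow-up missingness is applied to the six-month score at
rates matching 90% / 75% retention.  M2 is generated directly at its
three-level categorisation — the underlying 0–27 count never enters
the analysis.  Generated M3 scores are rounded and bounded to 0–54
like real instrument scores.

`oracle_true_effects()` computes the generator's true estimands by
brute force (default $2 \times 10^6$ simulated units, coupled draws,
reported Monte Carlo error), which gives every estimator stage a ground
truth to recover.  What the generator does *not* emulate: item-level
questionnaire structure, session-level adherence over time,
informative (non-random) missingness, and measurement error in the
mediators.  Passing recovery tests therefore demonstrate estimator
correctness under a correctly specified structural model, not
robustness to those real-data features.

## Numerical and scale choices

Monte Carlo noise of each component scales as $1/\sqrt{K}$; the test
suite verifies this empirically.  Tests and simulations run at reduced
sizes chosen to keep the full suite fast while leaving conclusions
unchanged: the enumeration comparison uses 30 records at
$K = 10^4$ against exact sums; parameter recovery uses one synthetic
trial of 5000 (complete) participants at $K = 500$ with a 40-replicate
bootstrap standard error; null-effect CI calibration uses 100 simulated
pipelines of 800 participants at $B = 150$ with a main-effects outcome
model (under the null generator every interaction coefficient is zero,
so that model is correctly specified); the per-pipeline sample size is
chosen large enough for the bootstrap asymptotics to hold for the total
and mediator-specific indirect effects.  The mediator-dependence
component is excluded from the calibration check: when every exposure
pathway is null it is a second-order degenerate functional — its
estimator's bias and standard deviation shrink at the same rate — and
percentile-type bootstrap intervals are known to be inconsistent for
such quantities at any sample size (measured coverage sits around
0.86–0.92 rather than 0.95).  Away from the null, where the component
is first-order, its intervals behave like the others; the moderated-mediation size
simulation uses 500 trials of 2000 participants.  The acceptance script
runs the full pooled analysis at the reference $K = 1000$ with
$B = 400$ bootstrap resamples at $K = 50$ inside replicates.

## Known limitations

* Indirect effects through M1 and M2 rely on the "unexposed level 0"
  convention; they are effects of shifting a mediator distribution to a
  degenerate reference, and categorising M2 may dilute its indirect
  effect.
* The outcome model is a marginal logistic regression; with cluster
  random intercepts in the generator there is a small non-collapsibility
  gap between the fitted marginal slopes and the conditional generator
  slopes.  At the calibrated cluster SD of 0.3 the attenuation is well
  under the estimator's sampling noise.
* No natural (pure) direct/indirect effects and no cross-world
  path-specific effects are computed, by design.
* Machine-learning nuisance estimation and multiple imputation for
  missing follow-up are out of scope; analyses are complete-case.
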