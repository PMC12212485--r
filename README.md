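# intervmed

Causal mediation analysis with **interventional (in)direct effects** for
a randomised digital mental-health intervention evaluated in two trials
— one individually randomised with stratification, one cluster
randomised — in adults with depression and comorbid hypertension or
diabetes.  The package decomposes the intervention's total effect on a
binary six-month outcome (an improvement of at least 50% in the PHQ-9
depression score from baseline) into pathways through three mediators
measured at three months:

* **M1** — understood session content without difficulty (binary,
  intervention arm only; unexposed level 0 in the control arm),
* **M2** — assigned activities completed (none / 1–10 / 11–27,
  intervention arm only),
* **M3** — behavioural activation, BADS-SF score 0–54 (both arms).

## The decomposition

With `G(a)` the joint counterfactual mediator distribution given
baseline covariates under exposure `a`, and `g_k(a)` the per-mediator
marginals, the package estimates

```
psi_TE  = P[1; G(1)]            - P[0; G(0)]            total effect
psi_DE  = P[1; G(0)]            - P[0; G(0)]            direct effect
psi_IE1 = P[1; g1(1),g2(0),g3(0)] - P[1; g1(0),g2(0),g3(0)]
psi_IE2 = P[1; g1(1),g2(1),g3(0)] - P[1; g1(1),g2(0),g3(0)]
psi_IE3 = P[1; g1(1),g2(1),g3(1)] - P[1; g1(1),g2(1),g3(0)]
psi_dep = (P[1; G(1)] - P[1; G(0)]) - (psi_IE1 + psi_IE2 + psi_IE3)
```

where `P[a_y; ...]` is a counterfactual outcome mean computed by Monte
Carlo integration over a K-fold expanded dataset (K = 1000 by default).
`psi_dep` is the indirect effect through the mediators' mutual
dependence.  Shared draws make the identity
`TE = DE + IE1 + IE2 + IE3 + dep` exact on every run.  Inference is a
bias-corrected nonparametric bootstrap that resamples whole clusters in
the cluster-randomised site and individuals within strata in the other.

## Worked example

```r
library(intervmed)

cfg <- synthetic_config()                    # calibrated two-site trial
dat <- generate_trial(cfg, seed = 1)
cc  <- complete_case_filter(dat)
attr(cc, "cc_counts")
#>       site enrolled retained dropped
#> 1     Lima      432      394      38
#> 2 SaoPaulo      880      658     222

scr_l <- screen_confounders(cc[cc$site == "Lima", ])
scr_s <- screen_confounders(cc[cc$site == "SaoPaulo", ])
confs <- pooled_confounders(scr_l, scr_s)    # union of sites + "site"

mm  <- fit_mediator_models(cc, confs)
om  <- fit_outcome_model(cc, confs,
                         interaction_spec = default_interaction_spec(pooled = TRUE))
dec <- decompose_effects(cc, mm, om, k_copies = 1000, rng = 12)
dec
#> Interventional effect decomposition (n = 1052 , K = 1000 )
#>   Total effect                             -0.0087
#>   Direct effect                            -0.1447
#>   Indirect: understanding sessions (M1)    -0.0443
#>   Indirect: activities completed (M2)      +0.1338
#>   Indirect: behavioural activation (M3)    +0.0443
#>   Indirect: mediator dependence            +0.0022
```

Each line is a difference in the probability of a 50%+ improvement in
depressive symptoms: here completing assigned activities mediates a
13-percentage-point improvement in this simulated trial, while the
direct pathway is negative.  Point estimates at trial size carry
substantial sampling noise — the bias-corrected bootstrap

```r
est  <- pipeline_estimator(confs, default_interaction_spec(TRUE), k_copies = 50)
boot <- bootstrap_effects(cc, est, B = 400, seed = 13)
```

gives, for example, a 95% CI of (−0.200, 0.098) for the M1 indirect
effect above.  `oracle_true_effects(cfg)` returns the generator's true
components by brute force (total +0.032, direct −0.189, indirect
+0.083 / +0.105 / +0.032, dependence +0.002), which is how the test
suite verifies parameter recovery.  `run_pipeline()` /
`sensitivity_run()` orchestrate all of this per site and pooled,
including the recovery outcome (six-month PHQ-9 < 10);
`inst/cli/intervmed.R` is a command-line wrapper.  Real trial CSVs
bind to the data model through an editable codebook
(`read_trial_dataset()`, `default_codebook()`).

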