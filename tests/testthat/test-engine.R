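test_that("dataset expansion replicates records with an index and guards memory", {
  d <- small_trial(seed = 40)[1:3, ]
  ex <- expand_dataset(d, 4)
  expect_equal(nrow(ex), 12)
  expect_equal(as.vector(table(ex$participant_id)), rep(4L, 3))
  expect_equal(ex$.copy, rep(1:4, 3))
  ex1 <- expand_dataset(d, 1)
  expect_equal(nrow(ex1), nrow(d))
  expect_error(expand_dataset(d, 10, row_budget = 20), "row budget")
  expect_error(expand_dataset(d, 0), "count")
})

test_that("an intercept-only outcome model yields 0.5 for every counterfactual regime", {
  d <- small_trial(seed = 41)
  mm <- fit_mediator_models(d, small_confounders)
  om <- fit_outcome_model(d, small_confounders, interaction_spec = character(0))
  om$fit$coefficients[] <- 0
  ex <- expand_dataset(d, 5)
  for (spec in list(cf_spec(1, 1, 1, 1, "joint"), cf_spec(0, 0, 0, 0, "joint"),
                    cf_spec(1, 1, 0, 1, "marginal"))) {
    expect_equal(counterfactual_mean(ex, mm, om, spec, rng = 7), 0.5)
  }
  dec <- decompose_effects(d, mm, om, k_copies = 5, rng = 8)
  expect_equal(unname(dec$estimates), rep(0, 6))
})

test_that("counterfactual means are deterministic given the seed and match the decomposition path", {
  d <- small_trial(seed = 42)
  mm <- fit_mediator_models(d, small_confounders)
  om <- fit_outcome_model(d, small_confounders)
  ex <- expand_dataset(d, 10)
  s <- cf_spec(1, 1, 1, 1, "joint")
  expect_identical(counterfactual_mean(ex, mm, om, s, rng = 5),
                   counterfactual_mean(ex, mm, om, s, rng = 5))
  dec <- decompose_effects(d, mm, om, k_copies = 10, rng = 5)
  expect_identical(dec$cf_means[["p1_G1"]], counterfactual_mean(ex, mm, om, s, rng = 5))
  expect_identical(dec$cf_means[["p1_111"]],
                   counterfactual_mean(ex, mm, om, cf_spec(1, 1, 1, 1, "marginal"), rng = 5))
  expect_error(cf_spec(1, 1, 0, 1, "joint"), "equal")
})

test_that("blocking the mediators in the outcome model zeroes every indirect component exactly", {
  d <- small_trial(seed = 43)
  mm <- fit_mediator_models(d, small_confounders)
  om <- fit_outcome_model(d, small_confounders, interaction_spec = character(0))
  cf <- om$fit$coefficients
  cf[grep("^m1$|^m2f|^m3$", names(cf))] <- 0
  om$fit$coefficients <- cf
  dec <- decompose_effects(d, mm, om, k_copies = 20, rng = 9)
  expect_identical(unname(dec$estimates[c("ie_m1", "ie_m2", "ie_m3", "ie_dep")]),
                   rep(0, 4))
  expect_identical(dec$estimates[["te"]], dec$estimates[["de"]])
})

test_that("decomposition is exactly additive across datasets, models and seeds", {
  for (seed in c(50, 51, 52)) {
    d <- small_trial(seed = seed)
    mm <- fit_mediator_models(d, small_confounders)
    om <- fit_outcome_model(d, small_confounders)
    dec <- decompose_effects(d, mm, om, k_copies = 25, rng = seed + 1)
    expect_lt(abs(sum(dec$estimates[-1]) - dec$estimates[["te"]]), 1e-12)
  }
})

test_that("Monte Carlo estimator agrees with exact enumeration under the fitted models", {
  cfg <- toy_binary_config()
  d <- complete_case_filter(generate_trial(cfg, seed = 60))
  mm <- fit_mediator_models(d, "medication", m3_family = "binomial")
  om <- fit_outcome_model(d, "medication", interaction_spec = "m1:m3")
  sub <- d[1:30, ]
  ex <- expand_dataset(sub, 1e4)
  tol <- 3 * 0.5 / sqrt(nrow(ex))   # conservative bound on the MC standard error
  cases <- list(list(1, 1, 1, 1, "joint"), list(0, 0, 0, 0, "joint"),
                list(1, 0, 0, 0, "marginal"), list(1, 1, 0, 0, "marginal"),
                list(1, 1, 1, 1, "marginal"))
  for (cs in cases) {
    mc <- counterfactual_mean(ex, mm, om,
                              cf_spec(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]]),
                              rng = 61)
    exact <- enum_fitted_mean(sub, mm, om, cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]])
    expect_lt(abs(mc - exact), tol)
  }
})

test_that("component Monte Carlo noise shrinks like one over the square root of K", {
  d <- small_trial(seed = 44, n_lima = 40, n_saopaulo = 60)
  mm <- fit_mediator_models(d, "bads_baseline")
  om <- fit_outcome_model(d, "bads_baseline", interaction_spec = character(0))
  sds <- sapply(c(50, 200, 800), function(K) {
    est <- sapply(1:12, function(r) {
      decompose_effects(d, mm, om, k_copies = K, rng = 1000 * K + r)$estimates[["ie_m1"]]
    })
    sd(est)
  })
  # each 4-fold K increase should roughly halve the noise
  expect_lt(sds[2] / sds[1], 0.95)
  expect_lt(sds[3] / sds[2], 0.95)
  expect_gt(sds[1] / sds[3], 2.0)
})

test_that("dependence component vanishes without interactions and conditionally independent mediators", {
  # generator with no M1 -> M2 / M2 -> M3 links and an interaction-free
  # outcome: mediators are conditionally independent given covariates
  cfg <- synthetic_config()
  cfg$m2_coefs$cat1["m1"] <- 0; cfg$m2_coefs$cat2["m1"] <- 0
  cfg$m3_coefs$coefs[c("m1", "m2_1", "m2_2")] <- 0
  cfg$y_coefs[c("m1:m3", "m3:medication", "m3:site_saopaulo")] <- 0
  cfg$missing_rate[] <- 0
  d <- complete_case_filter(generate_trial(cfg, seed = 45))
  mm <- fit_mediator_models(d, small_confounders)
  om <- fit_outcome_model(d, small_confounders, interaction_spec = character(0))
  dec <- decompose_effects(d, mm, om, k_copies = 300, rng = 46)
  expect_lt(abs(dec$estimates[["ie_dep"]]), 0.01)
})
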