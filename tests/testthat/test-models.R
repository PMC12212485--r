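test_that("sequential-joint M2 model recovers the generator's M1 coefficient", {
  cfg <- synthetic_config(n_lima = 1650, n_saopaulo = 3350,
                          missing_rate = c(lima = 0, saopaulo = 0))
  d <- complete_case_filter(generate_trial(cfg, seed = 30))
  mm <- fit_mediator_models(d, c("phone_use", "site"))
  co <- coef(mm$conditional$m2)
  se <- summary(mm$conditional$m2)$standard.errors
  # true multinomial-logit M1 coefficients: 0.8 (level 1), 1.2 (level 2)
  expect_lt(abs(co["1", "m1"] - 0.8), 3 * se["1", "m1"])
  expect_lt(abs(co["2", "m1"] - 1.2), 3 * se["2", "m1"])
})

test_that("outcome model recovers generator coefficients and nests its main-effects version", {
  cfg <- synthetic_config(n_lima = 1650, n_saopaulo = 3350,
                          missing_rate = c(lima = 0, saopaulo = 0))
  d <- complete_case_filter(generate_trial(cfg, seed = 31))
  confs <- c("age", "medication", "phq9_baseline", "education_years", "phone_use", "site")
  om <- fit_outcome_model(d, confs)
  s <- summary(om$fit)$coefficients
  truth <- c(arm = -0.9, m3 = 0.025, medication = -1.5, age = -0.010)
  for (nm in names(truth)) {
    expect_lt(abs(s[nm, "Estimate"] - truth[[nm]]), 3 * s[nm, "Std. Error"])
  }
  om0 <- fit_outcome_model(d, confs, interaction_spec = character(0))
  expect_lte(as.numeric(logLik(om0$fit)), as.numeric(logLik(om$fit)))
})

test_that("degenerate mediator input raises a separation diagnostic naming the model", {
  d <- small_trial(seed = 32)
  d$m1[d$arm == 1] <- 1
  expect_error(fit_mediator_models(d, small_confounders), "separation.*m1")
})

test_that("fast linear-predictor path matches stats::predict on every model", {
  d <- small_trial(seed = 33)
  dd <- as.data.frame(d); dd$m2f <- factor(dd$m2, levels = 0:2)
  mm <- fit_mediator_models(d, small_confounders)
  om <- fit_outcome_model(d, small_confounders)
  expect_equal(intervmed:::.fast_lp(mm$marginal$m1, dd),
               unname(predict(mm$marginal$m1, dd)), tolerance = 1e-12)
  expect_equal(intervmed:::.fast_lp(mm$conditional$m3, dd),
               unname(predict(mm$conditional$m3, dd)), tolerance = 1e-12)
  expect_equal(unname(intervmed:::.fast_probs_multinom(mm$conditional$m2, dd)),
               unname(predict(mm$conditional$m2, dd, type = "probs")), tolerance = 1e-10)
  expect_equal(stats::plogis(intervmed:::.fast_lp(om$fit, dd)),
               unname(predict(om$fit, dd, type = "response")), tolerance = 1e-12)
})

test_that("counterfactual draws respect the control-arm degeneracy rule", {
  d <- small_trial(seed = 34)
  mm <- fit_mediator_models(d, small_confounders)
  for (mode in c("joint", "marginal")) {
    dr <- draw_mediators(mm, d[1:50, ], a = 0, mode = mode, rng = 1)
    expect_true(all(dr$m1 == 0))
    expect_true(all(dr$m2 == 0))
  }
  # a = 0 draws of M3 centre on the control-arm model mean
  mm0 <- mm; mm0$residual_sd[] <- 0
  dr0 <- draw_mediators(mm0, d[1:50, ], a = 0, mode = "marginal", rng = 2)
  d0 <- as.data.frame(d[1:50, ]); d0$arm <- 0
  expect_equal(dr0$m3, unname(predict(mm$marginal$m3, d0)), tolerance = 1e-12)
  expect_error(draw_mediators(mm, d[1:5, ], a = 0, mode = "joint"), "rng")
})

test_that("joint draw frequencies match the product of fitted conditional probabilities", {
  d <- small_trial(seed = 35)
  mm <- fit_mediator_models(d, small_confounders)
  profile <- as.data.frame(d[rep(7L, 1e5), ])
  dr <- draw_mediators(mm, profile, a = 1, mode = "joint", rng = 3)
  p1 <- predict(mm$marginal$m1, profile[1, ], type = "response")
  pm2 <- predict(mm$conditional$m2, transform(profile[1, ], m1 = 1), type = "probs")
  for (k in 0:2) {
    p_cell <- p1 * pm2[k + 1]
    obs <- mean(dr$m1 == 1 & dr$m2 == k)
    expect_lt(abs(obs - p_cell), 3 * sqrt(p_cell * (1 - p_cell) / 1e5))
  }
  # marginal draws reproduce the fitted marginal distribution of M2
  drm <- draw_mediators(mm, profile, a = 1, mode = "marginal", rng = 4)
  pm2m <- predict(mm$marginal$m2, profile[1, ], type = "probs")
  for (k in 0:2) {
    expect_lt(abs(mean(drm$m2 == k) - pm2m[k + 1]),
              3 * sqrt(pm2m[k + 1] * (1 - pm2m[k + 1]) / 1e5))
  }
})

test_that("fitted category probabilities sum to one and the score equation holds", {
  d <- small_trial(seed = 36)
  dd <- as.data.frame(d); dd$m2f <- factor(dd$m2, levels = 0:2)
  mm <- fit_mediator_models(d, small_confounders)
  probs <- intervmed:::.fast_probs_multinom(mm$marginal$m2, dd)
  expect_equal(rowSums(probs), rep(1, nrow(dd)), tolerance = 1e-12)
  om <- fit_outcome_model(d, small_confounders)
  expect_lt(abs(mean(predict(om$fit, type = "response")) - mean(d$y)), 1e-6)
})

test_that("moderated-mediation Wald test matches the single-coefficient z test and flags unknown terms", {
  d <- small_trial(seed = 37, n_lima = 400, n_saopaulo = 600)
  om <- fit_outcome_model(d, small_confounders,
                          interaction_spec = c("m3:medication", "m2f:m3"))
  s <- summary(om$fit)$coefficients
  res <- moderated_mediation_test(om, "m3:medication")
  expect_equal(res$df, 1)
  expect_equal(res$p_value, s["m3:medication", "Pr(>|z|)"], tolerance = 1e-10)
  # order of components is normalised
  expect_equal(moderated_mediation_test(om, "medication:m3")$p_value, res$p_value)
  res2 <- moderated_mediation_test(om, "m2f:m3")
  expect_equal(res2$df, 2)
  expect_error(moderated_mediation_test(om, "m3:friends"), "not in the outcome model")
})

test_that("empirical-residual M3 draws resample the fitted residuals", {
  d <- small_trial(seed = 38)
  mm <- fit_mediator_models(d, small_confounders, m3_resid = "empirical")
  dr <- draw_mediators(mm, d[1:200, ], a = 0, mode = "marginal", rng = 6)
  d0 <- as.data.frame(d[1:200, ]); d0$arm <- 0
  eps <- dr$m3 - unname(predict(mm$marginal$m3, d0))
  expect_true(all(sapply(eps, function(e)
    any(abs(e - mm$residuals_m3$marginal) < 1e-9))))
  # decomposition runs and stays additive under empirical residuals
  om <- fit_outcome_model(d, small_confounders, interaction_spec = character(0))
  dec <- decompose_effects(d, mm, om, k_copies = 15, rng = 7)
  expect_lt(abs(sum(dec$estimates[-1]) - dec$estimates[["te"]]), 1e-12)
})
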