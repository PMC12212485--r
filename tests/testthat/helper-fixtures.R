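# Shared fixtures and independent oracles for the test suite.

# Small two-site trial for fast tests.
small_trial <- function(seed = 5, n_lima = 160, n_saopaulo = 240, ...) {
  cfg <- synthetic_config(n_lima = n_lima, n_saopaulo = n_saopaulo,
                          missing_rate = c(lima = 0, saopaulo = 0), ...)
  complete_case_filter(generate_trial(cfg, seed = seed))
}

small_confounders <- c("age", "medication", "bads_baseline", "site")

# Fully discrete toy instance: one active binary covariate (medication),
# binary M3, no cluster noise, so every counterfactual mean is exactly
# enumerable.
toy_binary_config <- function(med_prob = 0.4, seed = 11) {
  cp <- default_covariate_params()
  cp$lima$medication$prob <- med_prob
  cp$saopaulo$medication$prob <- med_prob
  synthetic_config(
    n_lima = 400, n_saopaulo = 400, cluster_sd = 0, covariate_params = cp,
    m1_coefs = c(intercept = 0.3, medication = 0.5),
    m2_coefs = list(cat1 = c(intercept = 0.2, m1 = 0.6, medication = -0.3),
                    cat2 = c(intercept = -0.5, m1 = 0.9)),
    m3_coefs = list(coefs = c(intercept = -0.4, arm = 0.5, m1 = 0.7,
                              m2_1 = 0.5, m2_2 = 1.0, medication = 0.3),
                    sd = 1),
    y_coefs = c(intercept = -0.3, arm = 0.4, m1 = 0.5, m2_1 = 0.3,
                m2_2 = 0.6, m3 = 0.7, medication = -0.4, `m1:m3` = 0.2),
    m3_family = "binomial", missing_rate = c(lima = 0, saopaulo = 0),
    seed = seed)
}

# Exact counterfactual means of the toy structural model, written out as
# plain arithmetic (independent of the package's coefficient machinery).
toy_true_means <- function(med_prob = 0.4) {
  p1_of <- function(med) plogis(0.3 + 0.5 * med)
  pm2_of <- function(m1, med) {
    l1 <- 0.2 + 0.6 * m1 - 0.3 * med
    l2 <- -0.5 + 0.9 * m1
    den <- 1 + exp(l1) + exp(l2)
    c(1, exp(l1), exp(l2)) / den
  }
  p3_of <- function(a, m1, m2, med) {
    plogis(-0.4 + 0.5 * a + 0.7 * m1 + 0.5 * (m2 == 1) + 1.0 * (m2 == 2) + 0.3 * med)
  }
  py_of <- function(ay, m1, m2, m3, med) {
    plogis(-0.3 + 0.4 * ay + 0.5 * m1 + 0.3 * (m2 == 1) + 0.6 * (m2 == 2) +
             0.7 * m3 - 0.4 * med + 0.2 * m1 * m3)
  }
  # joint regime: sequential sums; marginal regime: independent marginals
  mean_joint <- function(ay, a) {
    out <- 0
    for (med in 0:1) {
      wmed <- if (med == 1) med_prob else 1 - med_prob
      m1_levels <- if (a == 1) 0:1 else 0
      for (m1 in m1_levels) {
        w1 <- if (a == 1) (if (m1 == 1) p1_of(med) else 1 - p1_of(med)) else 1
        m2_levels <- if (a == 1) 0:2 else 0
        pm2 <- pm2_of(m1, med)
        for (m2 in m2_levels) {
          w2 <- if (a == 1) pm2[m2 + 1] else 1
          p3 <- p3_of(a, m1, m2, med)
          for (m3 in 0:1) {
            w3 <- if (m3 == 1) p3 else 1 - p3
            out <- out + wmed * w1 * w2 * w3 * py_of(ay, m1, m2, m3, med)
          }
        }
      }
    }
    out
  }
  mean_marginal <- function(ay, s1, s2, s3) {
    out <- 0
    for (med in 0:1) {
      wmed <- if (med == 1) med_prob else 1 - med_prob
      p1 <- p1_of(med)
      # marginal of M2 at exposure 1: mixture over M1
      pm2_marg <- pm2_of(1, med) * p1 + pm2_of(0, med) * (1 - p1)
      # marginal of M3 at exposure 1: mixture over (M1, M2)
      p3_marg1 <- 0
      for (m1 in 0:1) {
        w1 <- if (m1 == 1) p1 else 1 - p1
        pm2 <- pm2_of(m1, med)
        for (m2 in 0:2) p3_marg1 <- p3_marg1 + w1 * pm2[m2 + 1] * p3_of(1, m1, m2, med)
      }
      for (m1 in (if (s1 == 1) 0:1 else 0)) {
        w1 <- if (s1 == 1) (if (m1 == 1) p1 else 1 - p1) else 1
        for (m2 in (if (s2 == 1) 0:2 else 0)) {
          w2 <- if (s2 == 1) pm2_marg[m2 + 1] else 1
          p3 <- if (s3 == 1) p3_marg1 else p3_of(0, 0, 0, med)
          for (m3 in 0:1) {
            w3 <- if (m3 == 1) p3 else 1 - p3
            out <- out + wmed * w1 * w2 * w3 * py_of(ay, m1, m2, m3, med)
          }
        }
      }
    }
    out
  }
  c(p0_G0 = mean_joint(0, 0), p1_G0 = mean_joint(1, 0), p1_G1 = mean_joint(1, 1),
    p1_000 = mean_marginal(1, 0, 0, 0), p1_100 = mean_marginal(1, 1, 0, 0),
    p1_110 = mean_marginal(1, 1, 1, 0), p1_111 = mean_marginal(1, 1, 1, 1))
}

toy_true_components <- function(med_prob = 0.4) {
  m <- toy_true_means(med_prob)
  ie <- c(m[["p1_100"]] - m[["p1_000"]], m[["p1_110"]] - m[["p1_100"]],
          m[["p1_111"]] - m[["p1_110"]])
  c(te = m[["p1_G1"]] - m[["p0_G0"]],
    de = m[["p1_G0"]] - m[["p0_G0"]],
    ie_m1 = ie[1], ie_m2 = ie[2], ie_m3 = ie[3],
    ie_dep = (m[["p1_G1"]] - m[["p1_G0"]]) - sum(ie))
}

# Exact counterfactual mean under *fitted* models (binary-M3 toy),
# evaluated with stats::predict -- independent of the package's Monte
# Carlo path and of its fast linear-predictor evaluator.
enum_fitted_mean <- function(dataset, mm, om, a_y, s1, s2, s3, mode) {
  d <- as.data.frame(dataset)
  n <- nrow(d)
  newd <- function(m1, m2, m3, arm) {
    dd <- d
    dd$arm <- arm; dd$m1 <- m1; dd$m2f <- factor(m2, levels = 0:2); dd$m3 <- m3
    dd
  }
  p_m1 <- predict(mm$marginal$m1, d, type = "response")
  py <- function(ay, m1, m2, m3) predict(om$fit, newd(m1, m2, m3, ay), type = "response")
  total <- rep(0, n)
  if (mode == "joint") {
    a <- s1
    for (m1 in (if (a == 1) 0:1 else 0)) {
      w1 <- if (a == 1) (if (m1 == 1) p_m1 else 1 - p_m1) else rep(1, n)
      dm1 <- d; dm1$m1 <- m1
      pm2 <- predict(mm$conditional$m2, dm1, type = "probs")
      if (is.null(dim(pm2))) pm2 <- matrix(pm2, nrow = 1)
      for (m2 in (if (a == 1) 0:2 else 0)) {
        w2 <- if (a == 1) pm2[, m2 + 1] else rep(1, n)
        dd <- newd(m1, m2, 0, a)
        p3 <- predict(mm$conditional$m3, dd, type = "response")
        for (m3 in 0:1) {
          w3 <- if (m3 == 1) p3 else 1 - p3
          total <- total + w1 * w2 * w3 * py(a_y, m1, m2, m3)
        }
      }
    }
  } else {
    pm2_marg <- predict(mm$marginal$m2, d, type = "probs")
    if (is.null(dim(pm2_marg))) pm2_marg <- matrix(pm2_marg, nrow = 1)
    p3_m <- function(a) { dd <- d; dd$arm <- a; predict(mm$marginal$m3, dd, type = "response") }
    p3 <- p3_m(s3)
    for (m1 in (if (s1 == 1) 0:1 else 0)) {
      w1 <- if (s1 == 1) (if (m1 == 1) p_m1 else 1 - p_m1) else rep(1, n)
      for (m2 in (if (s2 == 1) 0:2 else 0)) {
        w2 <- if (s2 == 1) pm2_marg[, m2 + 1] else rep(1, n)
        for (m3 in 0:1) {
          w3 <- if (m3 == 1) p3 else 1 - p3
          total <- total + w1 * w2 * w3 * py(a_y, m1, m2, m3)
        }
      }
    }
  }
  mean(total)
}
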