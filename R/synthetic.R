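#' Default baseline-covariate distributions for the synthetic two-site trial
#'
#' Per-site truncated-normal / Bernoulli parameters for the seven baseline
#' covariates.  Defaults are calibrated to the pooled trial population:
#' middle-aged adults with clinically significant depressive symptoms
#' (baseline PHQ-9 >= 10) and comorbid hypertension/diabetes, with the
#' Lima site older, better educated and less medicated than Sao Paulo.
#'
#' @return Named list with elements `lima` and `saopaulo`; each is a list of
#'   per-covariate parameter lists (`mean`/`sd`/`lo`/`hi`/`integer` for
#'   truncated normals, `prob` for binary covariates).
#' @export
default_covariate_params <- function() {
  list(
    lima = list(
      age             = list(mean = 59.7, sd = 11.0, lo = 21, hi = 95, integer = TRUE),
      phq9_baseline   = list(mean = 14.1, sd = 3.8,  lo = 10, hi = 27, integer = TRUE),
      education_years = list(mean = 10.0, sd = 3.8,  lo = 0,  hi = 20, integer = TRUE),
      medication      = list(prob = 0.113),
      friends         = list(prob = 0.766),
      phone_use       = list(mean = 4.1,  sd = 3.3,  lo = 0,  hi = 10, integer = TRUE),
      bads_baseline   = list(mean = 25.7, sd = 7.8,  lo = 0,  hi = 54, integer = TRUE)
    ),
    saopaulo = list(
      age             = list(mean = 54.9, sd = 11.5, lo = 21, hi = 95, integer = TRUE),
      phq9_baseline   = list(mean = 15.9, sd = 4.3,  lo = 10, hi = 27, integer = TRUE),
      education_years = list(mean = 7.9,  sd = 3.9,  lo = 0,  hi = 20, integer = TRUE),
      medication      = list(prob = 0.349),
      friends         = list(prob = 0.852),
      phone_use       = list(mean = 4.7,  sd = 3.4,  lo = 0,  hi = 10, integer = TRUE),
      bads_baseline   = list(mean = 23.0, sd = 8.3,  lo = 0,  hi = 54, integer = TRUE)
    )
  )
}

#' Configuration of the synthetic two-site trial generator
#'
#' Defines the structural model a synthetic trial is drawn from: baseline
#' covariates, individually randomised site (Lima, stratified on health
#' facility) and cluster-randomised site (Sao Paulo, 20 clusters), a
#' mediator chain M1 (binary: session content understood without
#' difficulty) -> M2 (three-level: assigned activities completed,
#' none / 1-10 / 11-27) -> M3 (behavioural-activation score, BADS-SF
#' 0-54), and a logistic outcome model for a >= 50% reduction in PHQ-9
#' between baseline and six months.  M1 and M2 exist only under
#' intervention; the control arm holds them at the unexposed level 0.
#'
#' Coefficient vectors are named: `"intercept"`, covariate names, `"arm"`,
#' `"m1"`, `"m2_1"`/`"m2_2"` (indicators of M2 levels 1 and 2),
#' `"site_saopaulo"`, `"m3"`, and product terms such as `"m3:medication"`.
#' Default coefficients are calibrated so that pooled intervention-arm
#' mediator marginals and the outcome rate match a realistic trial of this
#' design (about 77.5% understanding sessions, activity-category split
#' 12/64/24%, three-month BADS-SF about 27.6 under intervention, outcome
#' rate near 47%).
#'
#' @param n_lima,n_saopaulo Participants per site.
#' @param n_clusters_saopaulo Number of Sao Paulo clusters (half randomised
#'   to each arm).
#' @param n_facilities_lima Health facilities used as Lima randomisation
#'   strata.
#' @param cluster_sd SD of Sao Paulo cluster random intercepts on the
#'   outcome log-odds scale.
#' @param covariate_params See [default_covariate_params()].
#' @param m1_coefs Named log-odds coefficients of the M1 model (defined
#'   given intervention).
#' @param m2_coefs List with elements `cat1` and `cat2`: multinomial-logit
#'   coefficients of M2 levels 1 and 2 against level 0 (given
#'   intervention; may include an `"m1"` term).
#' @param m3_coefs List with `coefs` (linear-model coefficients, both arms)
#'   and `sd` (residual SD); with `m3_family = "binomial"` the `coefs` are
#'   log-odds and `sd` is ignored.
#' @param y_coefs Named log-odds coefficients of the outcome model.
#' @param m3_family `"gaussian"` (default, score-valued M3 rounded and
#'   bounded to 0-54) or `"binomial"` (binary M3 variant used for exactly
#'   enumerable toy instances).
#' @param missing_rate Named vector `c(lima=, saopaulo=)`: probability that
#'   the six-month PHQ-9 (hence the outcome) is missing.  Defaults match
#'   about 90% / 75% six-month retention.
#' @param seed Default seed used by [generate_trial()].
#' @return Object of class `synthetic_config`.
#' @seealso [generate_trial()], [oracle_true_effects()]
#' @export
synthetic_config <- function(n_lima = 432,
                             n_saopaulo = 880,
                             n_clusters_saopaulo = 20,
                             n_facilities_lima = 7,
                             cluster_sd = 0.3,
                             covariate_params = default_covariate_params(),
                             m1_coefs = NULL,
                             m2_coefs = NULL,
                             m3_coefs = NULL,
                             y_coefs = NULL,
                             m3_family = c("gaussian", "binomial"),
                             missing_rate = c(lima = 0.0995, saopaulo = 0.2545),
                             seed = 20260901) {
  m3_family <- match.arg(m3_family)
  if (is.null(m1_coefs)) {
    m1_coefs <- c(intercept = 0.7722, education_years = 0.05, phone_use = 0.10,
                  phq9_baseline = -0.03, site_saopaulo = 0.10)
  }
  if (is.null(m2_coefs)) {
    m2_coefs <- list(
      cat1 = c(intercept = 2.3044, m1 = 0.8, site_saopaulo = -1.9, phone_use = 0.05),
      cat2 = c(intercept = -0.1663, m1 = 1.2, site_saopaulo = -0.5, phone_use = 0.08)
    )
  }
  if (is.null(m3_coefs)) {
    m3_coefs <- list(
      coefs = c(intercept = 14.3459, arm = 0, m1 = 1.5, m2_1 = 1.0, m2_2 = 2.5,
                bads_baseline = 0.45, site_saopaulo = 0.40),
      sd = 8.1
    )
  }
  if (is.null(y_coefs)) {
    y_coefs <- c(intercept = -0.8094, arm = -0.9, m1 = -0.05, m2_1 = 0.45,
                 m2_2 = 0.85, m3 = 0.025, medication = -1.5,
                 `m3:medication` = 0.025, phq9_baseline = 0.02, age = -0.010,
                 education_years = 0.02, phone_use = 0.03,
                 site_saopaulo = -0.30, `m3:site_saopaulo` = 0.020,
                 `m1:m3` = 0.022)
  }
  cfg <- list(n_lima = n_lima, n_saopaulo = n_saopaulo,
              n_clusters_saopaulo = n_clusters_saopaulo,
              n_facilities_lima = n_facilities_lima,
              cluster_sd = cluster_sd,
              covariate_params = covariate_params,
              m1_coefs = m1_coefs, m2_coefs = m2_coefs, m3_coefs = m3_coefs,
              y_coefs = y_coefs, m3_family = m3_family,
              missing_rate = missing_rate, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!.is_count(cfg$n_lima) || cfg$n_lima <= 0) stop("n_lima must be a positive count")
  if (!.is_count(cfg$n_saopaulo) || cfg$n_saopaulo <= 0) stop("n_saopaulo must be a positive count")
  if (!.is_count(cfg$n_clusters_saopaulo) || cfg$n_clusters_saopaulo < 2) {
    stop("n_clusters_saopaulo must be a count >= 2")
  }
  if (cfg$n_clusters_saopaulo %% 2 != 0) stop("n_clusters_saopaulo must be even (half per arm)")
  if (cfg$n_saopaulo < cfg$n_clusters_saopaulo) {
    stop("n_saopaulo smaller than the number of clusters: empty clusters")
  }
  if (!.is_count(cfg$n_facilities_lima) || cfg$n_facilities_lima < 1) {
    stop("n_facilities_lima must be a positive count")
  }
  if (!is.finite(cfg$cluster_sd) || cfg$cluster_sd < 0) stop("cluster_sd must be >= 0")
  if (cfg$m3_family == "gaussian" && (!is.finite(cfg$m3_coefs$sd) || cfg$m3_coefs$sd <= 0)) {
    stop("m3 residual sd must be > 0")
  }
  if (any(cfg$missing_rate < 0) || any(cfg$missing_rate >= 1)) {
    stop("missing_rate entries must be in [0, 1)")
  }
  invisible(cfg)
}

#' Null-effect generator configuration
#'
#' The default configuration with every exposure-related coefficient set to
#' zero: the intervention moves neither the mediators' effect on the
#' outcome nor the outcome directly, so all six interventional effects are
#' exactly zero in truth.  Baseline-covariate effects on M3 and the outcome
#' are retained so the fitted models are non-degenerate.
#'
#' @inheritParams synthetic_config
#' @param ... Passed through to [synthetic_config()].
#' @return `synthetic_config` with null exposure pathways.
#' @export
synthetic_config_null <- function(...) {
  cfg <- synthetic_config(...)
  cfg$m3_coefs$coefs[c("arm", "m1", "m2_1", "m2_2")] <- 0
  drop_y <- intersect(names(cfg$y_coefs),
                      c("arm", "m1", "m2_1", "m2_2", "m3:medication",
                        "m3:site_saopaulo", "m1:m3"))
  cfg$y_coefs[drop_y] <- 0
  cfg
}

.gen_covariates <- function(n, params, site) {
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!is.null(p$prob)) {
      out[[nm]] <- stats::rbinom(n, 1L, p$prob)
    } else {
      x <- .rtnorm(n, p$mean, p$sd, p$lo, p$hi)
      if (isTRUE(p$integer)) x <- pmin(pmax(round(x), p$lo), p$hi)
      out[[nm]] <- x
    }
  }
  out$site_saopaulo <- as.numeric(site == "SaoPaulo")
  out
}

.m2_probs <- function(m2_coefs, data) {
  lp1 <- .lp_from_coefs(m2_coefs$cat1, data)
  lp2 <- .lp_from_coefs(m2_coefs$cat2, data)
  den <- 1 + exp(lp1) + exp(lp2)
  cbind(1 / den, exp(lp1) / den, exp(lp2) / den)
}

.draw_m3_value <- function(cfg, data, u) {
  lp <- .lp_from_coefs(cfg$m3_coefs$coefs, data)
  if (cfg$m3_family == "binomial") {
    as.numeric(u < stats::plogis(lp))
  } else {
    x <- lp + stats::qnorm(u) * cfg$m3_coefs$sd
    pmin(pmax(round(x), 0), 54)
  }
}

.generate_site <- function(cfg, site) {
  n <- if (site == "Lima") cfg$n_lima else cfg$n_saopaulo
  params <- cfg$covariate_params[[if (site == "Lima") "lima" else "saopaulo"]]
  dat <- .gen_covariates(n, params, site)
  dat$site <- factor(site, levels = c("Lima", "SaoPaulo"))

  if (site == "Lima") {
    # individually randomised 1:1 within health-facility strata
    facility <- sample.int(cfg$n_facilities_lima, n, replace = TRUE)
    arm <- integer(n)
    for (f in unique(facility)) {
      idx <- which(facility == f)
      arm[idx] <- sample(rep_len(c(0L, 1L), length(idx)))
    }
    dat$arm <- arm
    dat$cluster_id <- sprintf("L%04d", seq_len(n))
    b_cluster <- rep(0, n)
  } else {
    # cluster randomised: half the clusters to each arm
    cluster <- sample(rep_len(seq_len(cfg$n_clusters_saopaulo), n))
    int_clusters <- sample.int(cfg$n_clusters_saopaulo, cfg$n_clusters_saopaulo / 2)
    dat$arm <- as.integer(cluster %in% int_clusters)
    dat$cluster_id <- sprintf("SP%02d", cluster)
    b <- stats::rnorm(cfg$n_clusters_saopaulo, 0, cfg$cluster_sd)
    b_cluster <- b[cluster]
  }

  # mediators: M1 and M2 exist under intervention only (unexposed level 0)
  p1 <- stats::plogis(.lp_from_coefs(cfg$m1_coefs, dat))
  dat$m1 <- ifelse(dat$arm == 1L, stats::rbinom(n, 1L, p1), 0L)
  probs2 <- .m2_probs(cfg$m2_coefs, dat)
  u2 <- stats::runif(n)
  dat$m2 <- ifelse(dat$arm == 1L, .cat_from_u(u2, probs2), 0L)
  ind <- .m2_indicators(dat$m2)
  dat$m2_1 <- ind$m2_1; dat$m2_2 <- ind$m2_2
  dat$m3 <- .draw_m3_value(cfg, dat, stats::runif(n))

  lp_y <- .lp_from_coefs(cfg$y_coefs, dat) + b_cluster
  dat$y <- stats::rbinom(n, 1L, stats::plogis(lp_y))

  # back-fill a six-month PHQ-9 consistent with the drawn outcome:
  # y = 1 iff phq9_6m <= floor(phq9_baseline / 2)
  half <- floor(dat$phq9_baseline / 2)
  lo <- ifelse(dat$y == 1L, 0L, half + 1L)
  hi <- ifelse(dat$y == 1L, half, 27L)
  dat$phq9_6m <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  dat$phq9_6m <- pmin(dat$phq9_6m, hi)
  dat$y_sens <- as.integer(dat$phq9_6m < 10)

  rate <- cfg$missing_rate[[if (site == "Lima") "lima" else "saopaulo"]]
  miss <- stats::runif(n) < rate
  dat$phq9_6m[miss] <- NA_integer_
  dat$y[miss] <- NA_integer_
  dat$y_sens[miss] <- NA_integer_
  dat
}

#' Generate a synthetic two-site trial dataset
#'
#' Draws one trial from the structural model in `config`: covariates, arm
#' assignment honouring each site's design (individual stratified
#' randomisation in Lima, cluster randomisation in Sao Paulo), the mediator
#' chain, the binary outcome, and a six-month PHQ-9 back-filled to be
#' consistent with the drawn outcome so the outcome-derivation stage can be
#' exercised.  Follow-up missingness is applied to the six-month PHQ-9.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`.  The same
#'   (config, seed) pair reproduces the dataset exactly.
#' @return A `trial_dataset` data frame (see [read_trial_dataset()] for the
#'   column contract).
#' @export
generate_trial <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  dat <- .with_seed(seed, {
    rbind(.generate_site(config, "Lima"), .generate_site(config, "SaoPaulo"))
  })
  dat$participant_id <- sprintf("P%05d", seq_len(nrow(dat)))
  for (s in levels(dat$site)) {
    arms <- unique(dat$arm[dat$site == s])
    if (length(arms) < 2L) stop("degenerate design: site ", s, " has a single arm")
  }
  cols <- c("participant_id", "site", "cluster_id", "arm",
            "age", "education_years", "medication", "friends", "phone_use",
            "phq9_baseline", "bads_baseline", "m1", "m2", "m3",
            "phq9_6m", "y", "y_sens")
  dat <- dat[, cols]
  rownames(dat) <- NULL
  class(dat) <- c("trial_dataset", "data.frame")
  dat
}

#' Ground-truth interventional effects of a generator configuration
#'
#' Computes the six interventional estimands implied by the structural
#' model by brute force: simulates a large covariate population, draws
#' mediators from the *true* distributions under each exposure regime
#' (joint sequential draws and independent per-mediator marginal draws),
#' and averages the true outcome probability.  Shared uniform draws couple
#' the regimes, so the decomposition is exactly additive and the Monte
#' Carlo error of each contrast is small.
#'
#' @param config A [synthetic_config()].
#' @param n_oracle Simulated population size (>= 1e5; default 2e6 keeps the
#'   truth error well below estimator tolerances in recovery tests).
#' @param seed Integer seed for the oracle simulation.
#' @return Object of class `generator_truth`: list with `estimates` (named
#'   vector `te`, `de`, `ie_m1`, `ie_m2`, `ie_m3`, `ie_dep`), per-component
#'   Monte Carlo standard errors `se`, their maximum `mc_error`, and
#'   `n_oracle`.
#' @export
oracle_true_effects <- function(config, n_oracle = 2e6, seed = config$seed + 1L) {
  validate_synthetic_config(config)
  if (!.is_count(n_oracle) || n_oracle < 1e5) stop("n_oracle must be a count >= 1e5")
  n <- as.integer(n_oracle)
  .with_seed(seed, {
    p_sp <- config$n_saopaulo / (config$n_lima + config$n_saopaulo)
    n_sp <- stats::rbinom(1L, n, p_sp)
    cov_l <- .gen_covariates(n - n_sp, config$covariate_params$lima, "Lima")
    cov_s <- .gen_covariates(n_sp, config$covariate_params$saopaulo, "SaoPaulo")
    dat <- rbind(cov_l, cov_s)
    b_cluster <- c(rep(0, n - n_sp), stats::rnorm(n_sp, 0, config$cluster_sd))

    u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
    u1f <- stats::runif(n); u2f <- stats::runif(n)

    dat$arm <- 1
    p1 <- stats::plogis(.lp_from_coefs(config$m1_coefs, dat))

    m2_draw <- function(u, m1) {
      d <- dat; d$m1 <- m1
      .cat_from_u(u, .m2_probs(config$m2_coefs, d))
    }
    m3_draw <- function(a, m1, m2) {
      d <- dat; d$arm <- a; d$m1 <- m1
      ind <- .m2_indicators(m2); d$m2_1 <- ind$m2_1; d$m2_2 <- ind$m2_2
      .draw_m3_value(config, d, u3)
    }
    y_prob <- function(a_y, m1, m2, m3) {
      d <- dat; d$arm <- a_y; d$m1 <- m1; d$m3 <- m3
      ind <- .m2_indicators(m2); d$m2_1 <- ind$m2_1; d$m2_2 <- ind$m2_2
      stats::plogis(.lp_from_coefs(config$y_coefs, d) + b_cluster)
    }

    zero <- rep(0, n)
    m1_1 <- as.numeric(u1 < p1)
    m2_j1 <- m2_draw(u2, m1_1)              # joint draw given drawn M1
    m3_j1 <- m3_draw(1, m1_1, m2_j1)
    m3_j0 <- m3_draw(0, zero, zero)

    # independent marginal draws: M2 from its mixture over M1; M3 from a
    # fresh chain so it is a draw from the M3 marginal, not the joint
    d1 <- dat; d1$m1 <- 1
    d0 <- dat; d0$m1 <- 0
    pr2_1 <- .m2_probs(config$m2_coefs, d1)
    pr2_0 <- .m2_probs(config$m2_coefs, d0)
    pr2_marg <- pr2_1 * p1 + pr2_0 * (1 - p1)
    m2_m1 <- .cat_from_u(u2, pr2_marg)
    m1_f <- as.numeric(u1f < p1)
    m2_f <- m2_draw(u2f, m1_f)
    m3_m1 <- m3_draw(1, m1_f, m2_f)

    pY <- list(
      p0_G0  = y_prob(0, zero, zero, m3_j0),
      p1_G0  = y_prob(1, zero, zero, m3_j0),
      p1_G1  = y_prob(1, m1_1, m2_j1, m3_j1),
      p1_000 = y_prob(1, zero, zero, m3_j0),
      p1_100 = y_prob(1, m1_1, zero, m3_j0),
      p1_110 = y_prob(1, m1_1, m2_m1, m3_j0),
      p1_111 = y_prob(1, m1_1, m2_m1, m3_m1)
    )

    diffs <- list(
      te     = pY$p1_G1 - pY$p0_G0,
      de     = pY$p1_G0 - pY$p0_G0,
      ie_m1  = pY$p1_100 - pY$p1_000,
      ie_m2  = pY$p1_110 - pY$p1_100,
      ie_m3  = pY$p1_111 - pY$p1_110,
      ie_dep = (pY$p1_G1 - pY$p1_G0) - (pY$p1_111 - pY$p1_000)
    )
    est <- vapply(diffs, mean, numeric(1))
    se <- vapply(diffs, function(d) stats::sd(d) / sqrt(length(d)), numeric(1))
    structure(list(estimates = est, se = se, mc_error = max(se),
                   n_oracle = n, cf_means = vapply(pY, mean, numeric(1))),
              class = "generator_truth")
  })
}

#' @export
print.generator_truth <- function(x, ...) {
  cat("Ground-truth interventional effects (oracle n =", x$n_oracle, ")\n")
  tab <- data.frame(estimate = round(x$estimates, 4), mc_se = signif(x$se, 3))
  print(tab)
  invisible(x)
}

#' Write a generator truth object as a key-value text file
#'
#' @param truth An [oracle_true_effects()] result.
#' @param path Output file; one `name = value` line per quantity.
#' @export
write_generator_truth <- function(truth, path) {
  stopifnot(inherits(truth, "generator_truth"))
  lines <- c(
    sprintf("%s = %.10g", names(truth$estimates), truth$estimates),
    sprintf("se_%s = %.10g", names(truth$se), truth$se),
    sprintf("mc_error = %.10g", truth$mc_error),
    sprintf("n_oracle = %d", truth$n_oracle))
  writeLines(lines, path)
  invisible(path)
}
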