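# Mediator and outcome models for the interventional-effects estimator.
#
# M1 (binary) and M2 (three-level) are measured under intervention only
# and fitted on intervention-arm records; under no intervention their
# counterfactual draw is the constant unexposed level 0.  M3 (the
# behavioural-activation score) is measured in both arms and fitted with
# an arm term.  The joint mediator distribution is factorised in the
# theorised order M1 -> M2 -> M3 by default; the order is configurable
# since interventional decompositions depend on it.

.med_info <- function(med) {
  switch(med,
    m1 = list(kind = "binary",      col = "m1",  int_arm_only = TRUE),
    m2 = list(kind = "categorical", col = "m2f", int_arm_only = TRUE),
    m3 = list(kind = "m3",          col = "m3",  int_arm_only = FALSE),
    stop("unknown mediator: ", med))
}

.check_binary_fit <- function(fit, label) {
  if (!fit$converged) stop("model for ", label, " failed to converge")
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || max(abs(cf)) > 15) {
    stop("separation detected in model for ", label,
         " (coefficient diverged: ",
         names(cf)[which.max(abs(cf))], ")")
  }
  fit
}

.fit_one_mediator <- function(med, rhs_meds, dataset, confounders, m3_family) {
  info <- .med_info(med)
  d <- dataset
  rhs_cols <- vapply(rhs_meds, function(m) .med_info(m)$col, character(1))
  if (info$int_arm_only) {
    d <- d[d$arm == 1, , drop = FALSE]
    rhs <- c(confounders, rhs_cols)
  } else {
    rhs <- c("arm", confounders, rhs_cols)
  }
  if (!length(rhs)) rhs <- "1"
  fml <- stats::reformulate(rhs, info$col)
  if (info$kind == "binary") {
    if (length(unique(d$m1)) < 2L) {
      stop("separation: m1 is constant in the intervention arm; ",
           "its model cannot be fitted")
    }
    .check_binary_fit(stats::glm(fml, family = stats::binomial(), data = d), med)
  } else if (info$kind == "categorical") {
    if (length(unique(d$m2)) < 2L) {
      stop("degenerate input: m2 is constant in the intervention arm")
    }
    fit <- nnet::multinom(fml, data = d, trace = FALSE, maxit = 200)
    if (fit$convergence != 0) stop("multinomial model for ", med, " failed to converge")
    fit
  } else if (m3_family == "gaussian") {
    stats::lm(fml, data = d)
  } else {
    .check_binary_fit(stats::glm(fml, family = stats::binomial(), data = d), med)
  }
}

#' Fit the mediator models (marginal and sequential-joint factorisation)
#'
#' Fits, for each mediator, a marginal model (confounders only, plus arm
#' for M3) and a conditional model given its predecessors in the
#' factorisation order.  Marginal models supply independent per-mediator
#' counterfactual draws; the conditional chain supplies draws from the
#' joint distribution.  Both carry the control-arm degeneracy rule: under
#' no intervention M1 and M2 are the constant 0.
#'
#' @param dataset Complete-case `trial_dataset`.
#' @param confounders Confounder names from screening (may include
#'   `"site"` for pooled fits).
#' @param m3_family `"gaussian"` (linear model with residual SD) or
#'   `"binomial"` (binary M3 variant).
#' @param order Factorisation order of the joint distribution, a
#'   permutation of `c("m1", "m2", "m3")`.
#' @param m3_resid `"normal"` draws counterfactual M3 as model mean plus
#'   normal noise with the fitted residual SD; `"empirical"` resamples
#'   the fitted residuals instead (inverse-CDF over the empirical
#'   distribution), which preserves skew at the cost of support limited
#'   to observed residuals.
#' @return `mediator_models` object: `marginal` and `conditional` model
#'   lists, `residual_sd` (named: marginal/joint, gaussian M3 only),
#'   `confounders`, `order`, `m3_family`, `m3_resid`.
#' @export
fit_mediator_models <- function(dataset, confounders,
                                m3_family = c("gaussian", "binomial"),
                                order = c("m1", "m2", "m3"),
                                m3_resid = c("normal", "empirical")) {
  m3_family <- match.arg(m3_family)
  m3_resid <- match.arg(m3_resid)
  if (!setequal(order, c("m1", "m2", "m3"))) {
    stop("order must be a permutation of m1, m2, m3")
  }
  d <- as.data.frame(dataset)
  d$m2f <- factor(d$m2, levels = 0:2)
  marginal <- conditional <- list()
  for (k in seq_along(order)) {
    med <- order[k]
    marginal[[med]] <- .fit_one_mediator(med, character(0), d, confounders, m3_family)
    conditional[[med]] <- if (k == 1L) marginal[[med]] else
      .fit_one_mediator(med, order[seq_len(k - 1L)], d, confounders, m3_family)
  }
  residual_sd <- residuals_m3 <- NULL
  if (m3_family == "gaussian") {
    residual_sd <- c(marginal = stats::sigma(marginal$m3),
                     joint = stats::sigma(conditional$m3))
    residuals_m3 <- list(marginal = sort(stats::residuals(marginal$m3)),
                         joint = sort(stats::residuals(conditional$m3)))
  }
  structure(list(marginal = marginal, conditional = conditional,
                 residual_sd = residual_sd, residuals_m3 = residuals_m3,
                 confounders = confounders, order = order,
                 m3_family = m3_family, m3_resid = m3_resid),
            class = "mediator_models")
}

.predict_probs_m2 <- function(fit, newdata) {
  .fast_probs_multinom(fit, newdata)
}

# One mediator draw via inverse-CDF from a uniform vector, so that common
# random numbers can be reused across counterfactual regimes.
.draw_one <- function(models, med, d, source, u, joint) {
  info <- .med_info(med)
  fit <- if (joint) models$conditional[[med]] else models$marginal[[med]]
  if (info$int_arm_only && source == 0) {
    return(if (med == "m2") rep(0L, nrow(d)) else rep(0, nrow(d)))
  }
  if (med == "m1") {
    as.numeric(u < stats::plogis(.fast_lp(fit, d)))
  } else if (med == "m2") {
    .cat_from_u(u, .predict_probs_m2(fit, d))
  } else {
    d$arm <- source
    if (models$m3_family == "binomial") {
      as.numeric(u < stats::plogis(.fast_lp(fit, d)))
    } else {
      .fast_lp(fit, d) + .m3_noise(models, u, joint)
    }
  }
}

# Draw all three mediators for each row of `data` given per-mediator
# exposure sources; `U` is a named list of uniforms.
.draw_mediator_set <- function(models, data, sources, mode, U) {
  d <- data
  if (mode == "joint") {
    if (length(unique(sources)) != 1L) stop("joint mode requires equal sources")
    out <- list()
    for (med in models$order) {
      val <- .draw_one(models, med, d, sources[[med]], U[[med]], joint = TRUE)
      out[[med]] <- val
      d[[.med_info(med)$col]] <- if (med == "m2") factor(val, levels = 0:2) else val
    }
    out
  } else {
    lapply(stats::setNames(c("m1", "m2", "m3"), c("m1", "m2", "m3")), function(med) {
      .draw_one(models, med, data, sources[[med]], U[[med]], joint = FALSE)
    })
  }
}

#' Draw counterfactual mediator values
#'
#' Draws `(m1, m2, m3)` for each covariate row at exposure level `a`.
#' Under `a = 0` the intervention-only mediators are the constant
#' unexposed level 0 and M3 is drawn from its model at arm 0.  Under
#' `a = 1`, `mode = "marginal"` draws each mediator independently from its
#' marginal model and `mode = "joint"` draws sequentially along the
#' factorisation order.  Gaussian M3 draws are model mean plus normal
#' noise with the fitted residual SD (untruncated).
#'
#' @param models A [fit_mediator_models()] result.
#' @param covariates Data frame of covariate rows (one draw per row).
#' @param a Exposure level, 0 or 1.
#' @param mode `"joint"` or `"marginal"`.
#' @param rng Integer seed; required so no hidden global RNG state is
#'   consumed.
#' @return Data frame with columns `m1`, `m2`, `m3`.
#' @export
draw_mediators <- function(models, covariates, a, mode = c("joint", "marginal"), rng) {
  mode <- match.arg(mode)
  if (missing(rng) || is.null(rng)) stop("an integer seed `rng` is required")
  if (!a %in% c(0, 1)) stop("a must be 0 or 1")
  n <- nrow(covariates)
  U <- .with_seed(rng, list(m1 = stats::runif(n), m2 = stats::runif(n), m3 = stats::runif(n)))
  src <- c(m1 = a, m2 = a, m3 = a)
  out <- .draw_mediator_set(models, covariates, src, mode, U)
  data.frame(m1 = out$m1, m2 = out$m2, m3 = out$m3)
}

#' Default outcome-model interaction specification
#'
#' All pairwise mediator-mediator interactions, the moderated-mediation
#' term M3 x baseline medication, and M3 x site in pooled runs.
#'
#' @param pooled Include the site moderation terms?
#' @return Character vector of interaction term labels.
#' @export
default_interaction_spec <- function(pooled = FALSE) {
  spec <- c("m1:m2f", "m1:m3", "m2f:m3", "m3:medication")
  if (pooled) spec <- c(spec, "m3:site")
  spec
}

#' Fit the logistic outcome model
#'
#' Regresses the binary outcome on arm, the three mediators (M2 as two
#' indicator contrasts against "no activities"), the selected confounders
#' and the configured interaction terms.  Clustering is not modelled here;
#' it is handled by the bootstrap resampling design.
#'
#' @param dataset Complete-case `trial_dataset`.
#' @param confounders Confounder names (include `"site"` for pooled fits).
#' @param interaction_spec Interaction term labels
#'   (see [default_interaction_spec()]); `character(0)` for main effects
#'   only.
#' @param outcome `"y"` (>= 50% PHQ-9 improvement) or `"y_sens"`
#'   (recovery, six-month PHQ-9 < 10).
#' @return `outcome_model` object wrapping the glm fit.
#' @export
fit_outcome_model <- function(dataset, confounders,
                              interaction_spec = default_interaction_spec("site" %in% confounders),
                              outcome = c("y", "y_sens")) {
  outcome <- match.arg(outcome)
  d <- as.data.frame(dataset)
  d$m2f <- factor(d$m2, levels = 0:2)
  rhs <- c("arm", "m1", "m2f", "m3", confounders, interaction_spec)
  fml <- stats::reformulate(rhs, outcome)
  fit <- stats::glm(fml, family = stats::binomial(), data = d)
  if (!fit$converged) stop("outcome model failed to converge")
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    stop("outcome model design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  structure(list(fit = fit, interaction_spec = interaction_spec,
                 confounders = confounders, outcome = outcome),
            class = "outcome_model")
}

.predict_outcome <- function(object, newdata) {
  stats::plogis(.fast_lp(object$fit, newdata))
}

#' Wald test for a moderated-mediation (or any) interaction term
#'
#' Tests the coefficients belonging to one interaction term of the fitted
#' outcome model (joint Wald chi-square when the term spans several
#' columns, e.g. interactions with the three-level mediator).
#'
#' @param model An [fit_outcome_model()] result.
#' @param interaction_term Term label, e.g. `"m3:medication"`; component
#'   order is normalised.
#' @return List with `p_value`, `statistic`, `df`, `term`.
#' @export
moderated_mediation_test <- function(model, interaction_term) {
  fit <- model$fit
  labels <- attr(stats::terms(fit), "term.labels")
  key <- function(x) paste(sort(strsplit(x, ":", fixed = TRUE)[[1]]), collapse = ":")
  hit <- which(vapply(labels, key, character(1)) == key(interaction_term))
  if (length(hit) != 1L) {
    stop("term '", interaction_term, "' is not in the outcome model")
  }
  assign <- attr(stats::model.matrix(fit), "assign")
  idx <- which(assign == hit)
  b <- stats::coef(fit)[idx]
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(b)
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, term = interaction_term)
}


# Residual noise for gaussian counterfactual M3 draws, from a uniform.
.m3_noise <- function(models, u, joint) {
  which <- if (joint) "joint" else "marginal"
  if (identical(models$m3_resid, "empirical")) {
    r <- models$residuals_m3[[which]]
    r[pmax(1L, ceiling(u * length(r)))]
  } else {
    stats::qnorm(u) * models$residual_sd[[which]]
  }
}
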