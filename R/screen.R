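# Mediator-outcome confounder screening: a baseline candidate is retained
# when it is associated (p < 0.10) with any mediator or with the outcome.

.screen_one <- function(dataset, candidate, target) {
  # M1/M2 are structurally zero under control, so their screens use the
  # intervention arm only; M3 and Y use both arms.
  if (target %in% c("m1", "m2")) dataset <- dataset[dataset$arm == 1, , drop = FALSE]
  x <- dataset[[candidate]]
  if (length(unique(x[!is.na(x)])) < 2L) {
    return(list(p = NA_real_, flag = "constant"))
  }
  p <- switch(target,
    m1 = {
      fit <- stats::glm(stats::reformulate(candidate, "m1"),
                        family = stats::binomial(), data = dataset)
      summary(fit)$coefficients[2, 4]
    },
    m2 = {
      # three-level mediator: likelihood-ratio joint test
      d <- dataset
      d$m2f <- factor(d$m2, levels = 0:2)
      full <- nnet::multinom(stats::reformulate(candidate, "m2f"), data = d, trace = FALSE)
      null <- nnet::multinom(m2f ~ 1, data = d, trace = FALSE)
      lr <- null$deviance - full$deviance
      df <- length(stats::coef(full)) - length(stats::coef(null))
      stats::pchisq(lr, df = df, lower.tail = FALSE)
    },
    m3 = {
      fit <- stats::lm(stats::reformulate(candidate, "m3"), data = dataset)
      summary(fit)$coefficients[2, 4]
    },
    y = {
      fit <- stats::glm(stats::reformulate(candidate, "y"),
                        family = stats::binomial(), data = dataset)
      summary(fit)$coefficients[2, 4]
    },
    stop("unknown screening target: ", target)
  )
  list(p = p, flag = "")
}

#' Screen baseline candidates for mediator-outcome confounding
#'
#' Fits, for every candidate x target pair, a univariable association
#' model matched to the target's type (logistic for the binary mediator
#' and the outcome, linear for the continuous mediator, multinomial logit
#' with a likelihood-ratio joint test for the three-level mediator) and
#' keeps any candidate whose p-value falls below `alpha` for at least one
#' target.  Candidates must be baseline variables; constant candidates are
#' reported unselected with a diagnostic flag.
#'
#' @param dataset Complete-case `trial_dataset` for one site (or pooled).
#' @param candidates Baseline variable names; defaults to the trial's
#'   baseline covariate set.
#' @param alpha Screening threshold (default 0.10).
#' @param targets Targets to test against.
#' @return `screening_result` data frame: one row per candidate x target
#'   with `p_value`, `selected` (candidate-level), `flag`.
#' @export
screen_confounders <- function(dataset, candidates = .trial_covariates(),
                               alpha = 0.10,
                               targets = c("m1", "m2", "m3", "y")) {
  bad <- intersect(candidates, c("m1", "m2", "m3", "y", "y_sens", "phq9_6m", "arm"))
  if (length(bad)) {
    stop("candidates must be baseline variables; remove: ", paste(bad, collapse = ", "))
  }
  rows <- list()
  for (cand in candidates) {
    res <- lapply(targets, function(tg) .screen_one(dataset, cand, tg))
    ps <- vapply(res, `[[`, numeric(1), "p")
    flags <- vapply(res, `[[`, character(1), "flag")
    sel <- any(!is.na(ps) & ps < alpha)
    rows[[cand]] <- data.frame(candidate = cand, target = targets,
                               p_value = ps, selected = sel, flag = flags,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "alpha") <- alpha
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Selected confounders from a screening result
#' @param screening A `screening_result`.
#' @return Character vector of selected candidate names (input order).
#' @export
selected_confounders <- function(screening) {
  unique(screening$candidate[screening$selected])
}

#' Pooled confounder set: union of the per-site selections plus site
#'
#' Pooled-analysis models adjust for every confounder selected in either
#' site, plus an indicator of study site.
#'
#' @param site_results_lima,site_results_saopaulo `screening_result`
#'   objects computed on the same candidate list.
#' @return Character vector of variable names, order-stable (Lima order,
#'   then new Sao Paulo selections, then `"site"`).
#' @export
pooled_confounders <- function(site_results_lima, site_results_saopaulo) {
  cl <- unique(site_results_lima$candidate)
  cs <- unique(site_results_saopaulo$candidate)
  if (!identical(sort(cl), sort(cs))) {
    stop("site screening results use different candidate lists")
  }
  sel <- union(selected_confounders(site_results_lima),
               selected_confounders(site_results_saopaulo))
  c(sel, "site")
}
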