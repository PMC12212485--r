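# Orchestration: configuration, end-to-end runs per site and pooled,
# sensitivity analysis with the recovery outcome, and report output.

#' Pipeline configuration
#'
#' Bundles everything a fully reproducible analysis run needs.  Exactly
#' one of `input` (CSV path read through `codebook`) or `synthetic`
#' (generator configuration) must be supplied.
#'
#' @param input Path to a participant-level CSV, or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param codebook Codebook for `input` (default [default_codebook()]).
#' @param sites Runs to perform: subset of `"lima"`, `"saopaulo"`,
#'   `"pooled"`.
#' @param candidates Baseline confounder candidates for screening.
#' @param alpha Screening threshold (default 0.10).
#' @param k_copies Monte Carlo copies per record for point estimates
#'   (default 1000).
#' @param k_copies_boot Copies per record inside bootstrap replicates
#'   (defaults to `k_copies`; lower it to trade CI Monte Carlo noise for
#'   speed).
#' @param resamples Bootstrap resamples B (default 1000).
#' @param outcome `"y"` (improvement >= 50%) or `"y_sens"` (recovery).
#' @param interaction_spec Outcome-model interaction terms, or `NULL` for
#'   [default_interaction_spec()] per run.
#' @param order Joint-factorisation order of the mediators.
#' @param lima_strata Lima bootstrap stratification column.
#' @param seed Mandatory integer seed; (config, seed) reproduces every
#'   number.
#' @return `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            codebook = default_codebook(),
                            sites = c("lima", "saopaulo", "pooled"),
                            candidates = .trial_covariates(),
                            alpha = 0.10,
                            k_copies = 1000, k_copies_boot = k_copies,
                            resamples = 1000,
                            outcome = c("y", "y_sens"),
                            interaction_spec = NULL,
                            order = c("m1", "m2", "m3"),
                            lima_strata = "arm",
                            seed) {
  outcome <- match.arg(outcome)
  sites <- match.arg(sites, several.ok = TRUE)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.null(input) == is.null(synthetic)) {
    stop("supply exactly one of `input` or `synthetic`")
  }
  if (k_copies < 1 || resamples < 2) stop("k_copies and resamples must be positive")
  structure(list(input = input, synthetic = synthetic, codebook = codebook,
                 sites = sites, candidates = candidates, alpha = alpha,
                 k_copies = k_copies, k_copies_boot = k_copies_boot,
                 resamples = resamples, outcome = outcome,
                 interaction_spec = interaction_spec, order = order,
                 lima_strata = lima_strata, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' End-to-end estimator closure for one analysis run
#'
#' Returns a `function(dataset, seed)` that refits the mediator and
#' outcome models on `dataset` (confounders held fixed, as screening is
#' done once on the original sample) and re-runs the Monte Carlo
#' decomposition.  This is the unit the bootstrap repeats per resample.
#'
#' @param confounders Fixed confounder set for the run.
#' @param interaction_spec Outcome-model interaction terms.
#' @param k_copies Monte Carlo copies per record.
#' @param outcome Outcome variable name.
#' @param order Mediator factorisation order.
#' @param m3_family M3 model family.
#' @return Estimator function for [bootstrap_effects()].
#' @export
pipeline_estimator <- function(confounders, interaction_spec, k_copies,
                               outcome = "y", order = c("m1", "m2", "m3"),
                               m3_family = "gaussian") {
  force(confounders); force(interaction_spec); force(k_copies)
  force(outcome); force(order); force(m3_family)
  function(dataset, seed) {
    mm <- fit_mediator_models(dataset, confounders, m3_family = m3_family,
                              order = order)
    om <- fit_outcome_model(dataset, confounders,
                            interaction_spec = interaction_spec,
                            outcome = outcome)
    decompose_effects(dataset, mm, om, k_copies = k_copies, rng = seed)$estimates
  }
}

.site_subset <- function(dataset, site) {
  out <- switch(site,
    lima = dataset[dataset$site == "Lima", , drop = FALSE],
    saopaulo = dataset[dataset$site == "SaoPaulo", , drop = FALSE],
    pooled = dataset)
  class(out) <- c("trial_dataset", "data.frame")
  out
}

#' Run the full mediation pipeline
#'
#' Executes read/generate, outcome derivation, complete-case filtering,
#' per-site confounder screening, model fitting, Monte Carlo effect
#' decomposition, design-aware bias-corrected bootstrap, and the
#' moderated-mediation tests, for every requested run (each site
#' separately and/or pooled).  Fully reproducible from (config, seed).
#'
#' @param config A [pipeline_config()].
#' @return `run_report`: complete-case counts, screening results, and one
#'   result set per run (`confounders`, `decomposition`, `bootstrap`,
#'   `moderation`, `descriptives`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dat <- wrap("input", {
    if (!is.null(config$input)) {
      read_trial_dataset(config$input, config$codebook)
    } else {
      generate_trial(config$synthetic, seed = config$seed)
    }
  })
  outcome_var <- config$outcome
  cc_vars <- unique(c("arm", config$candidates, "m1", "m2", "m3", outcome_var))
  cc <- wrap("complete_case_filter", complete_case_filter(dat, cc_vars))
  cc_counts <- attr(cc, "cc_counts")

  screening <- list()
  for (s in c("lima", "saopaulo")) {
    d_s <- .site_subset(cc, s)
    if (nrow(d_s)) {
      screening[[s]] <- wrap(paste0("screening_", s),
        screen_confounders(d_s, config$candidates, config$alpha))
    }
  }

  runs <- list()
  offsets <- c(lima = 100L, saopaulo = 200L, pooled = 300L)
  for (s in config$sites) {
    d_s <- .site_subset(cc, s)
    if (!nrow(d_s)) stop("pipeline stage 'subset' failed: no records for run '", s, "'")
    confs <- if (s == "pooled") {
      if (is.null(screening$lima) || is.null(screening$saopaulo)) {
        stop("pooled run needs both sites present for screening")
      }
      pooled_confounders(screening$lima, screening$saopaulo)
    } else {
      selected_confounders(screening[[s]])
    }
    ispec <- if (is.null(config$interaction_spec)) {
      sp <- default_interaction_spec(pooled = (s == "pooled"))
      if (!"medication" %in% config$candidates) sp <- setdiff(sp, "m3:medication")
      sp
    } else config$interaction_spec
    est <- pipeline_estimator(confs, ispec, config$k_copies,
                              outcome = outcome_var, order = config$order)
    est_boot <- pipeline_estimator(confs, ispec, config$k_copies_boot,
                                   outcome = outcome_var, order = config$order)
    seed_run <- config$seed + offsets[[s]]
    mm <- wrap(paste0("fit_", s),
               fit_mediator_models(d_s, confs, order = config$order))
    om <- wrap(paste0("fit_outcome_", s),
               fit_outcome_model(d_s, confs, interaction_spec = ispec,
                                 outcome = outcome_var))
    dec <- wrap(paste0("decompose_", s),
                decompose_effects(d_s, mm, om, k_copies = config$k_copies,
                                  rng = seed_run + 1L))
    boot <- wrap(paste0("bootstrap_", s),
                 bootstrap_effects(d_s, est_boot, B = config$resamples,
                                   seed = seed_run + 2L,
                                   lima_strata = config$lima_strata))
    # align the bootstrap table's point estimates with the full-K run
    boot$estimate <- dec$estimates[boot$component]
    moderation <- lapply(ispec[grepl("medication|site", ispec)], function(tm) {
      wrap(paste0("moderation_", s), moderated_mediation_test(om, tm))
    })
    runs[[s]] <- list(site = s, confounders = confs, interaction_spec = ispec,
                      n = nrow(d_s), decomposition = dec, bootstrap = boot,
                      moderation = moderation,
                      descriptives = list(
                        by_arm = descriptive_table(d_s, "arm"),
                        by_outcome = if (outcome_var == "y")
                          descriptive_table(d_s, "outcome") else NULL))
  }
  structure(list(cc_counts = cc_counts, screening = screening, runs = runs,
                 meta = list(seed = config$seed, k_copies = config$k_copies,
                             k_copies_boot = config$k_copies_boot,
                             B = config$resamples, outcome = outcome_var,
                             sites = config$sites)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  m <- x$meta
  cat("Interventional mediation analysis (outcome =", m$outcome,
      ", K =", m$k_copies, ", B =", m$B, ", seed =", m$seed, ")\n")
  cat("Complete cases:\n")
  print(x$cc_counts, row.names = FALSE)
  lab <- c(te = "Total effect",
           de = "Direct effect",
           ie_m1 = "Indirect: understanding sessions (M1)",
           ie_m2 = "Indirect: activities completed (M2)",
           ie_m3 = "Indirect: behavioural activation (M3)",
           ie_dep = "Indirect: mediator dependence")
  for (r in x$runs) {
    cat("\n--", r$site, "(n =", r$n, "); confounders:",
        paste(r$confounders, collapse = ", "), "\n")
    b <- r$bootstrap
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %-40s %+.2f (%+.2f, %+.2f)\n",
                  lab[[b$component[i]]], b$estimate[i],
                  b$ci_lower[i], b$ci_upper[i]))
    }
    for (md in r$moderation) {
      cat(sprintf("  moderation %-29s p = %.3f\n", md$term, md$p_value))
    }
  }
  invisible(x)
}

#' Sensitivity analysis with the recovery outcome
#'
#' Re-runs the identical pipeline with the outcome switched to recovery
#' from depression (six-month PHQ-9 < 10) and tabulates both runs side by
#' side.
#'
#' @param config A [pipeline_config()] (its `outcome` setting is ignored;
#'   both outcomes are run).
#' @return `sensitivity_report`: the two `run_report`s plus a side-by-side
#'   `comparison` data frame.
#' @export
sensitivity_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg1 <- config; cfg1$outcome <- "y"
  cfg2 <- config; cfg2$outcome <- "y_sens"
  rep1 <- run_pipeline(cfg1)
  rep2 <- run_pipeline(cfg2)
  comparison <- do.call(rbind, lapply(names(rep1$runs), function(s) {
    b1 <- rep1$runs[[s]]$bootstrap
    b2 <- rep2$runs[[s]]$bootstrap
    data.frame(site = s, component = b1$component,
               improved50 = b1$estimate,
               improved50_lower = b1$ci_lower, improved50_upper = b1$ci_upper,
               recovery = b2$estimate,
               recovery_lower = b2$ci_lower, recovery_upper = b2$ci_upper)
  }))
  structure(list(improved50 = rep1, recovery = rep2, comparison = comparison),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity comparison: improvement >= 50% vs recovery (PHQ-9 < 10)\n")
  tab <- x$comparison
  tab[-(1:2)] <- lapply(tab[-(1:2)], function(v) sprintf("%+.3f", v))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits per-run decomposition CSVs (component, estimate, z0, CI bounds),
#' screening CSVs, complete-case counts, and a machine-readable JSON
#' mirror of the whole report.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "complete_case_counts.csv")
  utils::write.csv(report$cc_counts, p, row.names = FALSE); paths <- c(paths, p)
  for (s in names(report$screening)) {
    p <- file.path(dir, paste0("screening_", s, ".csv"))
    utils::write.csv(as.data.frame(report$screening[[s]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (s in names(report$runs)) {
    p <- file.path(dir, paste0("effects_", s, ".csv"))
    utils::write.csv(as.data.frame(report$runs[[s]]$bootstrap), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  json <- list(meta = report$meta, cc_counts = report$cc_counts,
               runs = lapply(report$runs, function(r) {
                 list(site = r$site, n = r$n, confounders = r$confounders,
                      estimates = as.list(r$decomposition$estimates),
                      bootstrap = as.data.frame(r$bootstrap),
                      moderation = lapply(r$moderation, function(m)
                        m[c("term", "p_value", "statistic", "df")]))
               }))
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
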