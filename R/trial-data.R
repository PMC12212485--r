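# Data model and ingestion for the two-site trial analysis dataset.

.trial_covariates <- function() {
  c("age", "education_years", "medication", "friends", "phone_use",
    "phq9_baseline", "bads_baseline")
}

#' Analysis variables required for the mediation pipeline
#' @return Character vector of column names that must be non-missing in a
#'   complete-case analysis dataset.
#' @export
analysis_variables <- function() {
  c("arm", .trial_covariates(), "m1", "m2", "m3", "y")
}

#' Default codebook binding CSV columns to the analysis data model
#'
#' A codebook is a data frame with columns `field` (canonical name),
#' `column` (header in the CSV), `type` (`id`, `site`, `integer`,
#' `numeric`, `binary`, `categorical`), `min`, `max` (range for numeric
#' types; `NA` = unchecked) and `required`.  The default maps identically
#' named columns; deposited datasets with different headers bind by
#' editing `column`.
#'
#' @return Codebook data frame.
#' @export
default_codebook <- function() {
  data.frame(
    field = c("participant_id", "site", "cluster_id", "arm",
              "age", "education_years", "medication", "friends", "phone_use",
              "phq9_baseline", "bads_baseline", "m1", "m2", "m3",
              "phq9_6m", "y", "y_sens"),
    column = c("participant_id", "site", "cluster_id", "arm",
               "age", "education_years", "medication", "friends", "phone_use",
               "phq9_baseline", "bads_baseline", "m1", "m2", "m3",
               "phq9_6m", "y", "y_sens"),
    type = c("id", "site", "id", "binary",
             "numeric", "numeric", "binary", "binary", "integer",
             "integer", "numeric", "binary", "categorical", "numeric",
             "integer", "binary", "binary"),
    min = c(NA, NA, NA, 0,  18, 0, 0, 0, 0, 10, 0, 0, 0, 0,  0, 0, 0),
    max = c(NA, NA, NA, 1,  NA, 30, 1, 1, 10, 27, 54, 1, 2, 54, 27, 1, 1),
    required = c(FALSE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

.coerce_column <- function(x, type, column) {
  if (type %in% c("id", "site")) return(as.character(x))
  raw_na <- is.na(x) | (is.character(x) & trimws(x) == "")
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) & !raw_na)
  if (length(bad)) {
    stop("unparseable value in column '", column, "' at row ", bad[1],
         ": '", x[bad[1]], "'")
  }
  num
}

#' Read a trial dataset from CSV through a codebook
#'
#' Reads a participant-level CSV, maps columns to the canonical data model
#' via the codebook, type-checks every cell, flags out-of-range values
#' (attribute `range_flags`), applies the unexposed convention (control-arm
#' M1 and M2 set to level 0), and derives the binary outcomes from the
#' PHQ-9 scores wherever the six-month score is present.
#'
#' @param path CSV file (comma separated, header row, UTF-8).
#' @param codebook See [default_codebook()].
#' @return A `trial_dataset` data frame.  Attribute `range_flags` lists
#'   rows whose values fall outside the codebook range.
#' @export
read_trial_dataset <- function(path, codebook = default_codebook()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  flags <- list()
  for (i in seq_len(nrow(codebook))) {
    cb <- codebook[i, ]
    if (!cb$column %in% names(raw)) {
      if (isTRUE(cb$required)) stop("mandatory column missing from CSV: '", cb$column, "'")
      out[[cb$field]] <- if (cb$type %in% c("id", "site")) NA_character_ else NA_real_
      next
    }
    x <- .coerce_column(raw[[cb$column]], cb$type, cb$column)
    if (!cb$type %in% c("id", "site")) {
      viol <- which(!is.na(x) & ((!is.na(cb$min) & x < cb$min) | (!is.na(cb$max) & x > cb$max)))
      if (length(viol)) {
        flags[[cb$field]] <- data.frame(row = viol, field = cb$field, value = x[viol])
      }
    }
    out[[cb$field]] <- x
  }
  if (all(is.na(out$participant_id))) out$participant_id <- sprintf("P%05d", seq_len(nrow(out)))
  site_map <- c(lima = "Lima", saopaulo = "SaoPaulo", `sao paulo` = "SaoPaulo")
  key <- tolower(gsub("[^a-z ]", "", tolower(out$site)))
  mapped <- site_map[key]
  if (any(is.na(mapped))) {
    stop("unrecognised site value at row ", which(is.na(mapped))[1], ": '",
         out$site[which(is.na(mapped))[1]], "'")
  }
  out$site <- factor(unname(mapped), levels = c("Lima", "SaoPaulo"))
  # unexposed convention: mediators measured under intervention only are
  # held at level 0 in the control arm
  ctrl <- !is.na(out$arm) & out$arm == 0
  out$m1[ctrl] <- 0
  out$m2[ctrl] <- 0
  out <- derive_outcomes(out)
  attr(out, "range_flags") <- if (length(flags)) do.call(rbind, c(flags, make.row.names = FALSE)) else NULL
  class(out) <- c("trial_dataset", "data.frame")
  out
}

#' Write a trial dataset as CSV
#' @param dataset A `trial_dataset`.
#' @param path Output file.
#' @export
write_trial_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive the binary outcomes from baseline and six-month PHQ-9
#'
#' The primary outcome is an improvement of at least 50% in the PHQ-9
#' score between baseline and six months (the boundary counts as
#' improved); the sensitivity outcome is recovery, a six-month PHQ-9
#' below 10.  Records without a six-month score get missing outcomes and
#' are removed later by [complete_case_filter()].  Recomputation is
#' idempotent.
#'
#' @param dataset A `trial_dataset` (or data frame with `phq9_baseline`,
#'   `phq9_6m`).
#' @return The dataset with `y` and `y_sens` (re)computed.
#' @export
derive_outcomes <- function(dataset) {
  b <- dataset$phq9_baseline
  f <- dataset$phq9_6m
  ok <- !is.na(b) & !is.na(f)
  if (any(!is.na(b) & b < 10)) {
    stop("phq9_baseline below 10 violates trial eligibility (row ",
         which(!is.na(b) & b < 10)[1], ")")
  }
  y <- ifelse(ok, as.integer((b - f) / b >= 0.5), NA_integer_)
  y_sens <- ifelse(ok, as.integer(f < 10), NA_integer_)
  dataset$y <- y
  dataset$y_sens <- y_sens
  dataset
}

#' Restrict to complete cases on the analysis variables
#'
#' @param dataset A `trial_dataset`.
#' @param variables Variables that must be non-missing; defaults to
#'   [analysis_variables()].
#' @return The retained records, with attribute `cc_counts`: a per-site
#'   data frame of enrolled / retained / dropped counts.
#' @export
complete_case_filter <- function(dataset, variables = analysis_variables()) {
  missing_vars <- setdiff(variables, names(dataset))
  if (length(missing_vars)) {
    stop("variables not present in dataset: ", paste(missing_vars, collapse = ", "))
  }
  keep <- stats::complete.cases(as.data.frame(dataset)[, variables, drop = FALSE])
  counts <- do.call(rbind, lapply(levels(droplevels(dataset$site)), function(s) {
    in_site <- dataset$site == s
    data.frame(site = s, enrolled = sum(in_site),
               retained = sum(in_site & keep), dropped = sum(in_site & !keep))
  }))
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("complete-case filter removed every record")
  rownames(out) <- NULL
  attr(out, "cc_counts") <- counts
  attr(out, "complete_case") <- TRUE
  class(out) <- c("trial_dataset", "data.frame")
  out
}

.summary_cell <- function(x, type) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(n = NA_real_, prop = NA_real_, mean = NA_real_, sd = NA_real_))
  if (type == "binary") {
    c(n = sum(x == 1), prop = mean(x == 1), mean = NA_real_, sd = NA_real_)
  } else {
    c(n = length(x), prop = NA_real_, mean = mean(x), sd = stats::sd(x))
  }
}

#' Descriptive comparison of mediators and confounders across strata
#'
#' Summarises the three mediators and the baseline confounders by trial
#' arm (unadjusted exposed/unexposed comparison) or by outcome status.
#' Categorical rows report count (proportion); continuous rows mean (SD).
#' M1 and M2 are measured under intervention only, so their summaries are
#' restricted to intervention-arm records within each stratum; strata with
#' no eligible records yield `NA` cells.
#'
#' @param dataset A complete-case `trial_dataset` (one site or pooled).
#' @param stratifier `"arm"` or `"outcome"`.
#' @return Long-format `descriptive_table` data frame with columns
#'   `variable`, `level`, `stratum`, `n`, `prop`, `mean`, `sd`.
#' @export
descriptive_table <- function(dataset, stratifier = c("arm", "outcome")) {
  stratifier <- match.arg(stratifier)
  strat_var <- if (stratifier == "arm") dataset$arm else dataset$y
  strata <- if (stratifier == "arm") {
    list(control = strat_var == 0, intervention = strat_var == 1)
  } else {
    list(no_improvement = strat_var %in% 0, improvement = strat_var %in% 1)
  }
  int_only <- dataset$arm == 1
  rows <- list()
  add <- function(variable, level, values_by_stratum, type) {
    for (s in names(values_by_stratum)) {
      cell <- .summary_cell(values_by_stratum[[s]], type)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = level, stratum = s,
        n = cell[["n"]], prop = cell[["prop"]],
        mean = cell[["mean"]], sd = cell[["sd"]])
    }
  }
  pick <- function(mask, x) lapply(strata, function(sel) x[sel & mask])
  all_mask <- rep(TRUE, nrow(dataset))

  add("m1", "understood", pick(int_only, dataset$m1), "binary")
  for (lv in 0:2) {
    add("m2", c("none", "1-10", "11-27")[lv + 1L],
        pick(int_only, as.numeric(dataset$m2 == lv)), "binary")
  }
  add("m3", NA, pick(all_mask, dataset$m3), "continuous")
  cont <- c("phq9_baseline", "age", "education_years", "phone_use", "bads_baseline")
  for (v in cont) add(v, NA, pick(all_mask, dataset[[v]]), "continuous")
  for (v in c("medication", "friends")) add(v, "yes", pick(all_mask, dataset[[v]]), "binary")

  out <- do.call(rbind, rows)
  attr(out, "stratifier") <- stratifier
  attr(out, "n_total") <- nrow(dataset)
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, digits = 1, ...) {
  cat("Descriptive table stratified by", attr(x, "stratifier"),
      "(n =", attr(x, "n_total"), ")\n")
  fmt <- ifelse(is.na(x$mean),
                sprintf("%d (%.1f%%)", ifelse(is.na(x$n), 0L, as.integer(x$n)), 100 * x$prop),
                sprintf("%.1f (%.1f)", x$mean, x$sd))
  fmt[is.na(x$mean) & is.na(x$prop)] <- "n/a"
  wide <- stats::reshape(
    data.frame(variable = paste(x$variable, ifelse(is.na(x$level), "", x$level)),
               stratum = x$stratum, cell = fmt, stringsAsFactors = FALSE),
    idvar = "variable", timevar = "stratum", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE, right = FALSE)
  invisible(x)
}
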