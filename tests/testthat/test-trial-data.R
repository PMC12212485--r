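test_that("a generated dataset round-trips through CSV unchanged", {
  d <- generate_trial(synthetic_config(n_lima = 60, n_saopaulo = 90), seed = 8)
  f <- tempfile(fileext = ".csv")
  write_trial_dataset(d, f)
  d2 <- read_trial_dataset(f)
  for (v in setdiff(names(d), "site")) {
    expect_equal(unname(d2[[v]]), unname(d[[v]]), info = v)
  }
  expect_equal(as.character(d2$site), as.character(d$site))
  expect_null(attr(d2, "range_flags"))
})

test_that("outcome derivation honours the closed 50% boundary and the recovery cut", {
  d <- data.frame(phq9_baseline = c(20, 10, 14), phq9_6m = c(10, 9, 7))
  out <- derive_outcomes(d)
  expect_equal(out$y, c(1L, 0L, 1L))        # boundary counts as improved
  expect_equal(out$y_sens, c(0L, 1L, 1L))
  # idempotent and consistent under recomputation
  expect_equal(derive_outcomes(out)$y, out$y)
  d$phq9_6m[2] <- NA
  expect_true(is.na(derive_outcomes(d)$y[2]))
  expect_error(derive_outcomes(data.frame(phq9_baseline = 5, phq9_6m = 2)), "eligibility")
})

test_that("reader flags out-of-range cells and errors on broken input", {
  d <- generate_trial(synthetic_config(n_lima = 40, n_saopaulo = 60), seed = 9)
  f <- tempfile(fileext = ".csv")
  raw <- as.data.frame(d)
  raw$bads_baseline[3] <- 60                       # BADS-SF range is 0-54
  utils::write.csv(raw, f, row.names = FALSE)
  d2 <- read_trial_dataset(f)
  flags <- attr(d2, "range_flags")
  expect_equal(flags$row, 3)
  expect_equal(flags$field, "bads_baseline")
  expect_equal(flags$value, 60)

  raw2 <- as.data.frame(d); raw2$m3 <- NULL
  utils::write.csv(raw2, f, row.names = FALSE)
  expect_error(read_trial_dataset(f), "mandatory column missing.*m3")

  raw3 <- as.data.frame(d); raw3$age <- as.character(raw3$age); raw3$age[5] <- "old"
  utils::write.csv(raw3, f, row.names = FALSE)
  expect_error(read_trial_dataset(f), "row 5")
})

test_that("reader applies the unexposed convention to control-arm mediators", {
  d <- as.data.frame(generate_trial(synthetic_config(n_lima = 40, n_saopaulo = 60), seed = 10))
  d$m1[d$arm == 0] <- 1
  d$m2[d$arm == 0] <- 2
  f <- tempfile(fileext = ".csv")
  utils::write.csv(d, f, row.names = FALSE)
  d2 <- read_trial_dataset(f)
  expect_true(all(d2$m1[d2$arm == 0] == 0))
  expect_true(all(d2$m2[d2$arm == 0] == 0))
})

test_that("complete-case filter reports per-site counts and is the identity without missingness", {
  d <- generate_trial(synthetic_config(n_lima = 300, n_saopaulo = 500), seed = 11)
  cc <- complete_case_filter(d)
  counts <- attr(cc, "cc_counts")
  expect_equal(counts$enrolled, c(300, 500))
  expect_equal(counts$retained + counts$dropped, counts$enrolled)
  expect_equal(nrow(cc), sum(counts$retained))
  expect_true(all(stats::complete.cases(as.data.frame(cc)[, analysis_variables()])))
  # no missingness -> identity
  d0 <- generate_trial(synthetic_config(n_lima = 50, n_saopaulo = 80,
                                        missing_rate = c(lima = 0, saopaulo = 0)), seed = 12)
  cc0 <- complete_case_filter(d0)
  expect_equal(nrow(cc0), nrow(d0))
  expect_error(complete_case_filter(d, "not_a_column"), "not present")
  d_allna <- d; d_allna$m3 <- NA_real_
  expect_error(complete_case_filter(d_allna), "every record")
})

test_that("complete-case retention matches the configured follow-up rates", {
  d <- generate_trial(synthetic_config(n_lima = 4320, n_saopaulo = 8800), seed = 13)
  counts <- attr(complete_case_filter(d), "cc_counts")
  # about 90% retained in Lima and about 75% in Sao Paulo
  p <- counts$retained / counts$enrolled
  expect_lt(abs(p[1] - 0.9005), 3 * sqrt(0.9 * 0.1 / 4320))
  expect_lt(abs(p[2] - 0.7455), 3 * sqrt(0.75 * 0.25 / 8800))
})

test_that("descriptive table matches hand-computed summaries on a toy dataset", {
  d <- data.frame(
    participant_id = sprintf("P%d", 1:4),
    site = factor(c("Lima", "Lima", "SaoPaulo", "SaoPaulo"), c("Lima", "SaoPaulo")),
    cluster_id = c("a", "b", "c", "c"), arm = c(1, 0, 1, 0),
    age = c(50, 60, 70, 40), education_years = c(5, 10, 8, 12),
    medication = c(1, 0, 0, 0), friends = c(1, 1, 0, 1), phone_use = c(2, 4, 6, 8),
    phq9_baseline = c(20, 16, 12, 18), bads_baseline = c(20, 25, 30, 35),
    m1 = c(1, 0, 0, 0), m2 = c(2, 0, 1, 0), m3 = c(30, 20, 28, 22),
    phq9_6m = c(8, 10, 5, 17), y = c(1, 0, 1, 0), y_sens = c(1, 0, 1, 0))
  class(d) <- c("trial_dataset", "data.frame")
  tab <- descriptive_table(d, "arm")
  cell <- function(v, lv, s) tab[tab$variable == v & (is.na(lv) | tab$level %in% lv) & tab$stratum == s, ]
  expect_equal(cell("m3", NA, "intervention")$mean, 29)
  expect_equal(cell("m3", NA, "control")$mean, 21)
  expect_equal(cell("m3", NA, "control")$sd, sd(c(20, 22)))
  expect_equal(cell("m1", "understood", "intervention")$n, 1)
  expect_equal(cell("m1", "understood", "intervention")$prop, 0.5)
  expect_equal(cell("medication", "yes", "intervention")$prop, 0.5)
  # M1/M2 restricted to the intervention arm when stratified by arm
  expect_true(is.na(cell("m1", "understood", "control")$n))
  tab2 <- descriptive_table(d, "outcome")
  expect_equal(cell2 <- tab2[tab2$variable == "m3" & tab2$stratum == "improvement", ]$mean, 29)
})

test_that("descriptive row totals equal the dataset size for fully observed variables", {
  d <- small_trial(seed = 14)
  tab <- descriptive_table(d, "arm")
  m3_rows <- tab[tab$variable == "m3", ]
  expect_equal(sum(m3_rows$n), nrow(d))
  m2_rows <- tab[tab$variable == "m2" & tab$stratum == "intervention", ]
  expect_equal(sum(m2_rows$n), sum(d$arm == 1))
})
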