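make_record <- function(samples, sampling_rate = 1,
                        bounds = c(0, 480, 1020, 1920),
                        parameter = "SC", subject = "S01") {
  time_series_record(subject, "blue", parameter, sampling_rate,
                     samples, bounds)
}

test_that("baseline level averages the trailing window", {
  const <- make_record(rep(5, 1921))
  expect_equal(baseline_level(const, 60), 5)
  ramp <- make_record(c(0:480, rep(480, 1440)))
  # last 60 s of baseline: t = 420..480, mean of that arithmetic sequence
  expect_equal(baseline_level(ramp, 60), 450)
  expect_error(baseline_level(ramp, 600), "exceeds the baseline")
  expect_error(baseline_level(ramp, 0), "positive")
})

test_that("task-phase AUC matches closed forms and preserves sign", {
  # constant 2 over a 540 s task: rectangle
  r <- make_record(rep(2, 1921))
  expect_equal(auc_task_phase(r, baseline = 0), 1080)
  expect_equal(auc_task_phase(r, baseline = 2), 0)
  # linear ramp 0..10 over a 10 s task at 1 Hz: trapezoid = 50
  ramp <- make_record(c(rep(0, 5), 0:10, rep(10, 10)), bounds = c(0, 5, 15, 25))
  expect_equal(auc_task_phase(ramp, baseline = 0), 50)
  neg <- make_record(rep(-1, 1921))
  expect_equal(auc_task_phase(neg, baseline = 0), -540)
})

test_that("AUC is linear, shift-invariant and refinement-stable", {
  base <- withr::with_seed(4, stats::approx(seq(0, 40, by = 4),
                                            rnorm(11), xout = 0:40)$y)
  r1 <- make_record(base, bounds = c(0, 10, 30, 40))
  a <- auc_task_phase(r1, baseline = 0.3)
  # linearity in (signal, baseline)
  r2 <- make_record(3 * base, bounds = c(0, 10, 30, 40))
  expect_equal(auc_task_phase(r2, baseline = 0.9), 3 * a)
  # common shift cancels
  r3 <- make_record(base + 7, bounds = c(0, 10, 30, 40))
  expect_equal(auc_task_phase(r3, baseline = 7.3), a)
  # doubling the sampling rate of a piecewise-linear signal changes nothing
  fine <- stats::approx(0:40, base, xout = seq(0, 40, by = 0.5))$y
  r4 <- make_record(fine, sampling_rate = 2, bounds = c(0, 10, 30, 40))
  expect_equal(auc_task_phase(r4, baseline = 0.3), a)
})

test_that("noise-free AUC recovers amplitude within the onset transient", {
  zero <- setNames(rep(0, 14), spa_parameters())
  tpl <- group_template("clean", response_amplitude = c(SC = 4, MAP = -2),
                        noise_sd = zero, drift_sd = zero,
                        amplitude_sd = zero)
  s <- generate_subject(tpl, seed = 1)
  tau <- tpl$onset_time_constant
  for (p in c("SC", "MAP")) {
    rec <- s$records[[p]]
    amp <- tpl$response_amplitude[[p]]
    auc <- auc_task_phase(rec, baseline_level(rec))
    # onset transient tau*amp, plus the trapezoid discretization error
    # bound h^2/(12 tau) per unit amplitude (h = 1 s)
    expect_lt(abs(auc - amp * 540), abs(amp) * (tau + 1 / (6 * tau)))
  }
})

test_that("feature tables assemble completely or fail loudly", {
  coh <- generate_cohort(cohort_spec(n_subjects = 6, seed = 2))
  co <- coh$conditions$blue
  ft <- build_feature_table(co$records, co$task_performance)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft$values), c(6, 15))
  expect_equal(ft$provenance, "raw_auc")
  # order independence: permuted records give the same table
  flat <- unlist(co$records, recursive = FALSE, use.names = FALSE)
  perm <- withr::with_seed(1, sample(flat))
  ft2 <- build_feature_table(perm, co$task_performance)
  expect_equal(ft$values, ft2$values)
  # a dropped channel is named in the error
  broken <- co$records
  broken[["S02"]][["SC"]] <- NULL
  expect_error(build_feature_table(broken, co$task_performance),
               "S02, SC")
})

test_that("pearson correlation matches closed form and rejects degeneracy", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), manual)
  expect_equal(pearson_correlation(x, y), pearson_correlation(y, x))
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero-variance")
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
})

test_that("feature_correlations tabulates r and p for feature pairs", {
  ft <- generate_feature_table(cohort_spec(n_subjects = 20, seed = 6))
  tab <- feature_correlations(ft$blue$table, c("HHb-PFC", "O2Hb-VC"),
                              c("SC", "SpO2"))
  expect_equal(nrow(tab), 4)
  expect_true(all(abs(tab$r) <= 1))
  ct <- cor.test(ft$blue$table$values[, "HHb-PFC"],
                 ft$blue$table$values[, "SC"])
  row <- tab[tab$feature_a == "HHb-PFC" & tab$feature_b == "SC", ]
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p, ct$p.value)
})
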