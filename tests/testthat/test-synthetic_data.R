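small_spec <- function(seed = 1, n = 8)
  cohort_spec(n_subjects = n, seed = seed)

test_that("noise-free subjects plateau at the template amplitude", {
  tpl <- group_template(
    "quiet", response_amplitude = c(SC = 5),
    onset_time_constant = 1e-6,
    noise_sd = setNames(rep(0, 14), spa_parameters()),
    drift_sd = setNames(rep(0, 14), spa_parameters()),
    amplitude_sd = setNames(rep(0, 14), spa_parameters()))
  s <- generate_subject(tpl, seed = 1)
  rec <- s$records[["SC"]]
  pb <- rec$phase_bounds
  task <- rec$samples[rec$time > pb[["task_start"]] + 1 &
                        rec$time <= pb[["task_end"]]]
  base <- rec$samples[rec$time < pb[["task_start"]]]
  expect_equal(unique(round(task - mean(base), 9)), 5)

  # zero amplitudes everywhere: every channel constant across phases
  flat <- group_template(
    "flat", response_amplitude = setNames(rep(0, 14), spa_parameters()),
    noise_sd = setNames(rep(0, 14), spa_parameters()),
    drift_sd = setNames(rep(0, 14), spa_parameters()),
    amplitude_sd = setNames(rep(0, 14), spa_parameters()))
  s2 <- generate_subject(flat, seed = 2)
  for (r in s2$records) expect_equal(length(unique(r$samples)), 1L)
})

test_that("cohort generation is seed-deterministic and label-conserving", {
  a <- generate_cohort(small_spec(seed = 7))
  b <- generate_cohort(small_spec(seed = 7))
  expect_identical(a, b)
  c3 <- generate_cohort(small_spec(seed = 8))
  expect_false(identical(a$conditions$blue$records, c3$conditions$blue$records))

  expect_lte(length(unique(a$conditions$blue$labels)), 3L)
  expect_lte(length(unique(a$conditions$red$labels)), 5L)
  expect_identical(names(a$conditions$blue$records),
                   names(a$conditions$red$records))
})

test_that("early subjects are unchanged when the cohort grows", {
  a <- generate_cohort(small_spec(seed = 3, n = 6))
  b <- generate_cohort(small_spec(seed = 3, n = 9))
  expect_identical(a$conditions$blue$records[["S03"]],
                   b$conditions$blue$records[["S03"]])
})

test_that("cohort rejects fewer subjects than groups", {
  expect_error(cohort_spec(n_subjects = 4), "number of groups")
})

test_that("degenerate proportions plant a single label", {
  spec <- cohort_spec(
    n_subjects = 6,
    group_proportions_per_condition = list(blue = c(1, 0, 0),
                                           red = c(1, 0, 0, 0, 0)),
    seed = 2)
  coh <- generate_cohort(spec)
  expect_identical(unique(unname(coh$conditions$blue$labels)), 1L)
})

test_that("fast-mode tables have 15 features and planted mixture labels", {
  ft <- generate_feature_table(small_spec(seed = 5, n = 10))
  expect_named(ft, c("blue", "red"))
  expect_equal(dim(ft$blue$table$values), c(10, 15))
  expect_identical(ft$blue$table$features,
                   c(spa_parameters(), task_performance_feature()))
  # labels coincide with the time-series mode's planted labels
  coh <- generate_cohort(small_spec(seed = 5, n = 10))
  expect_identical(ft$blue$labels, coh$conditions$blue$labels)
  expect_identical(generate_feature_table(small_spec(seed = 5, n = 10)), ft)
})

test_that("zero separation collapses groups to one distribution", {
  spec <- small_spec(seed = 9, n = 24)
  ft <- generate_feature_table(spec, separation = 0)
  v <- ft$blue$table$values[, "SC"]
  g <- unname(ft$blue$labels)
  # group means indistinguishable: classic one-way F test stays quiet
  expect_gt(stats::anova(stats::lm(v ~ factor(g)))[["Pr(>F)"]][1], 1e-4)
})

test_that("clustering recovery on unseparated cohorts sits at chance", {
  aris <- vapply(1:50, function(s) {
    ft <- generate_feature_table(cohort_spec(n_subjects = 15, seed = s),
                                 separation = 0)
    scores <- pca_project(
      min_max_normalize(ft$blue$table)$values[, informative_combo],
      0.8)$scores
    res <- run_method(scores, "kmeans", k = 3, seed = s)
    adjusted_rand_index(res$labels, unname(ft$blue$labels))
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("large separation makes k-means recovery exact", {
  for (s in 1:20) {
    ft <- generate_feature_table(cohort_spec(n_subjects = 18, seed = s),
                                 separation = 2)
    scores <- pca_project(
      min_max_normalize(ft$red$table)$values[, informative_combo],
      0.8)$scores
    res <- run_method(scores, "kmeans", k = 5, seed = s)
    expect_equal(adjusted_rand_index(res$labels, unname(ft$red$labels)), 1)
  }
})

test_that("template validation catches bad input", {
  expect_error(group_template("x", response_amplitude = c(XX = 1)),
               "unknown parameter")
  expect_error(group_template("x", noise_sd = c(SC = -1)), ">= 0")
  expect_error(default_templates("blue", separation = -1), ">= 0")
})
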