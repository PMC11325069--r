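test_that("plant_partition places the requested counts and is seed-deterministic", {
  p <- plant_partition(c(4, 4, 4), seed = 3)
  expect_length(p$labels, 12)
  expect_equal(unname(tabulate(p$labels)), c(4, 4, 4))

  expect_equal(plant_partition(c(12), seed = 1)$labels, rep(1L, 12))
  expect_identical(plant_partition(c(5, 7), seed = 9)$labels,
                   plant_partition(c(5, 7), seed = 9)$labels)
  expect_error(plant_partition(integer(0)), "non-empty")
  expect_error(plant_partition(c(3, 0, 2)), "community_sizes")
})

test_that("jitter_membership honors the boundary rates and leaves non-targets alone", {
  p <- plant_partition(c(10, 10, 10), seed = 2)
  expect_identical(jitter_membership(p, 1, rate = 0, seed = 5)$labels, p$labels)

  j1 <- jitter_membership(p, 2, rate = 1, seed = 5)
  expect_true(all(j1$labels[p$labels == 2] != 2))
  expect_identical(j1$labels[p$labels != 2], p$labels[p$labels != 2])

  expect_error(jitter_membership(p, 1, rate = 1.2), "rate")
  expect_error(jitter_membership(p, 99, rate = 0.5), "community label")
  one <- plant_partition(c(8), seed = 1)
  expect_error(jitter_membership(one, 1, rate = 1, seed = 1), "single community")
})

test_that("jitter reassignment count follows Binomial(|target|, rate)", {
  # mean over 200 seeds of Binomial(1000, 0.5) draws: 99% band for the mean
  p <- plant_partition(c(1000, 200), seed = 1)
  target_nodes <- which(p$labels == 1)
  counts <- vapply(1:200, function(s) {
    sum(jitter_membership(p, 1, rate = 0.5, seed = s)$labels[target_nodes] != 1)
  }, numeric(1))
  band <- 2.576 * sqrt(1000 * 0.25 / 200)
  expect_gt(mean(counts), 500 - band)
  expect_lt(mean(counts), 500 + band)
})

test_that("simulate_bold reproduces the planted correlation structure", {
  p <- plant_partition(c(8, 8, 8), seed = 4)
  within_mask <- outer(p$labels, p$labels, "==") & upper.tri(diag(24))
  cross_mask <- !outer(p$labels, p$labels, "==") & upper.tri(diag(24))

  ts <- simulate_bold(p, 20000, within_corr = 0.5, seed = 11)
  cm <- cor(t(ts))
  expect_equal(mean(cm[within_mask]), 0.5, tolerance = 0.02)
  expect_equal(mean(cm[cross_mask]), 0, tolerance = 0.02)

  ts2 <- simulate_bold(plant_partition(c(5, 5), seed = 1), 10000, 0.999, seed = 2)
  cm2 <- cor(t(ts2))
  p2 <- plant_partition(c(5, 5), seed = 1)
  wm <- outer(p2$labels, p2$labels, "==") & upper.tri(diag(10))
  expect_gt(mean(cm2[wm]), 0.99)

  ts0 <- simulate_bold(p, 2000, 0, seed = 3)
  cm0 <- cor(t(ts0))
  expect_lt(abs(mean(cm0[within_mask]) - mean(cm0[cross_mask])), 0.05)

  expect_error(simulate_bold(p, 2, 0.5), "n_timepoints")
  expect_error(simulate_bold(p, 100, 1), "within_corr")
})

test_that("generate_cohort draws covariates as configured and links jitter to CS", {
  cfg <- cohort_config(n_subjects = 500, n_nodes = 12,
                       community_sizes = c(4, 4, 4), n_timepoints = 5,
                       within_corr = 0.3, seed = 7)
  cohort <- generate_cohort(cfg)
  cs <- vapply(cohort$subjects, function(s) s$covariates$cs, numeric(1))
  expect_lt(abs(mean(cs) - 1.71), 0.02)
  expect_true(all(cs >= 0 & cs <= 2.4))

  # null link: identical jitter rate regardless of CS
  cfg0 <- cohort_config(n_subjects = 5, n_nodes = 12,
                        community_sizes = c(4, 4, 4), n_timepoints = 5,
                        jitter_slope = 0, jitter_intercept = 0.25)
  expect_equal(jitter_rate(cfg0, c(0.5, 1.7, 2.4)), rep(0.25, 3))

  # positive link: lower CS -> larger realized mislabeled fraction
  cfg1 <- cohort_config(n_subjects = 200, n_nodes = 60,
                        community_sizes = c(20, 20, 20), n_timepoints = 5,
                        jitter_slope = 1.2, jitter_intercept = 0.35, seed = 21)
  ch <- generate_cohort(cfg1)
  target_nodes <- which(ch$base_partition$labels == 1)
  mis <- vapply(ch$subjects, function(s) {
    mean(s$true_partition$labels[target_nodes] != 1)
  }, numeric(1))
  cs1 <- vapply(ch$subjects, function(s) s$covariates$cs, numeric(1))
  expect_lt(cor(cs1, mis, method = "spearman"), 0)
})

test_that("covariate draws pass a mean z-test in nearly all repeated runs", {
  pass <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_subjects = 500, n_nodes = 12,
                         community_sizes = c(4, 4, 4), n_timepoints = 5,
                         seed = 100 + s)
    cs <- vapply(generate_cohort(cfg)$subjects,
                 function(x) x$covariates$cs, numeric(1))
    z <- (mean(cs) - 1.71) / (0.14 / sqrt(500))
    abs(z) < qnorm(0.995)
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("identical config and seed serialize byte-identically", {
  cfg <- cohort_config(n_subjects = 4, n_nodes = 24,
                       community_sizes = c(8, 8, 8), n_timepoints = 20,
                       seed = 42)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  back <- read_cohort(d1)
  expect_equal(length(back$subjects), 4)
  expect_equal(back$base_partition$labels,
               generate_cohort(cfg)$base_partition$labels)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("Pelli-Robson letter counts convert at 0.05 log units per letter", {
  expect_identical(pelli_robson_to_logcs(0), 0)
  expect_equal(pelli_robson_to_logcs(34), 1.70)
  expect_equal(pelli_robson_to_logcs(48), 2.40)
  expect_error(pelli_robson_to_logcs(49), "48")
  expect_error(pelli_robson_to_logcs(-1), "48")
})
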