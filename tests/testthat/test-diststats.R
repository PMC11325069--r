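test_that("Ruzicka similarity is min-sum over max-sum", {
  x <- c(0.5, 1.0)
  expect_equal(ruzicka_similarity(x, c(1.0, 0.5)), 0.5)
  expect_equal(ruzicka_similarity(x, x), 1)
  expect_equal(ruzicka_similarity(c(1, 0, 2), c(0, 3, 0)), 0)
  set.seed(41)
  for (rep in 1:10) {
    a <- runif(20)
    b <- runif(20)
    expect_equal(ruzicka_similarity(a, b), ruzicka_ref(a, b), tolerance = 1e-15)
  }
  expect_error(ruzicka_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_error(ruzicka_similarity(c(1, -1), c(1, 1)), "nonnegative")
  expect_error(ruzicka_similarity(1:3, 1:2), "length")
})

test_that("brain distances form a semimetric matching the two-loop reference", {
  set.seed(42)
  maps <- random_si_maps(5, 30)
  d <- brain_distance_matrix(maps)
  expect_equal(d$values, t(d$values))
  expect_equal(diag(d$values), rep(0, 5))
  expect_true(all(d$values >= 0 & d$values <= 1))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(d$values[i, j],
                   1 - ruzicka_ref(maps[[i]]$values, maps[[j]]$values),
                   tolerance = 1e-15)
    }
  }
  # zero distance iff identical maps
  maps2 <- maps
  maps2[[2]] <- maps[[1]]
  maps2[[2]]$subject_id <- "S002"
  d2 <- brain_distance_matrix(maps2)
  expect_equal(d2$values[1, 2], 0)
  expect_true(all(d$values[upper.tri(d$values)] > 0))
})

test_that("covariate distances use absolute difference and mismatch coding", {
  d <- covariate_distance_matrix(c(1.8, 1.6, 1.6), "abs_numeric")
  expect_equal(d$values[1, 2], 0.2)
  expect_equal(d$values[2, 3], 0)

  s <- covariate_distance_matrix(c(0, 1, 1), "binary_mismatch")
  expect_equal(s$values[1, 2], 1)
  expect_equal(s$values[2, 3], 0)
  expect_equal(covariate_distance_matrix(rep(2, 4), "abs_numeric")$values,
               matrix(0, 4, 4))
  expect_error(covariate_distance_matrix(c(0, 2), "binary_mismatch"), "0/1")
  expect_error(covariate_distance_matrix(c(1, NA), "abs_numeric"), "missing")
})

test_that("fixed-effects fit equals explicit-dummy least squares", {
  set.seed(43)
  m <- 12
  maps <- random_si_maps(m, 40)
  y <- brain_distance_matrix(maps)
  xs <- list(cs = covariate_distance_matrix(runif(m, 1.4, 2.0), "abs_numeric",
                                            y$subject_ids),
             motion = covariate_distance_matrix(rpois(m, 5), "abs_numeric",
                                                y$subject_ids),
             sex = covariate_distance_matrix(rbinom(m, 1, 0.5), "binary_mismatch",
                                             y$subject_ids))
  fit <- fit_distance_regression(y, xs, names(xs))
  ref <- lm_dummy_fit(y, xs)
  expect_equal(fit$terms$estimate, ref$estimate, tolerance = 1e-8)
  expect_equal(fit$terms$se, ref$se, tolerance = 1e-8)
  expect_equal(fit$terms$t, ref$t, tolerance = 1e-8)
  expect_equal(fit$terms$p, ref$p, tolerance = 1e-8)

  # covariate estimates invariant to which subject dummy is dropped
  fit1 <- fit_distance_regression(y, xs, names(xs), drop_subject = 1)
  expect_equal(fit$terms$estimate, fit1$terms$estimate, tolerance = 1e-10)
  expect_equal(fit$terms$se, fit1$terms$se, tolerance = 1e-10)

  # errors: rank deficiency and subject-order mismatch
  xs_bad <- c(xs, list(cs_copy = xs$cs))
  expect_error(fit_distance_regression(y, xs_bad, names(xs_bad)), "rank deficient")
  y_scrambled <- pair_distance(y$values, rev(y$subject_ids), "brain_jaccard")
  expect_error(fit_distance_regression(y_scrambled, xs, names(xs)), "mismatched")
})

test_that("the permutation path reproduces the full-refit T exactly", {
  set.seed(44)
  m <- 12
  y <- random_pair_distance(m)
  xs <- list(cs = covariate_distance_matrix(runif(m), "abs_numeric", y$subject_ids),
             sex = covariate_distance_matrix(rbinom(m, 1, 0.5), "binary_mismatch",
                                             y$subject_ids))
  fit <- fit_distance_regression(y, xs, names(xs), permutations = 200, seed = 7)
  expect_equal(fit$t_perm_obs, fit$terms$t[1], tolerance = 1e-10)
  expect_true(fit$p_perm > 0 && fit$p_perm <= 1)
  # deterministic given the seed
  fit2 <- fit_distance_regression(y, xs, names(xs), permutations = 200, seed = 7)
  expect_identical(fit$p_perm, fit2$p_perm)
  # relabeling the subjects of a distance matrix equals rebuilding it from
  # relabeled covariate values
  v <- runif(m)
  pm <- sample(m)
  a <- covariate_distance_matrix(v, "abs_numeric")$values[pm, pm]
  b <- covariate_distance_matrix(v[pm], "abs_numeric")$values
  expect_equal(a, b)
})

test_that("step-up FDR matches the reference implementation and its contract", {
  expect_equal(adapted_fdr(rep(1, 5)), rep(1, 5))
  set.seed(45)
  for (rep in 1:10) {
    p <- runif(sample(3:30, 1))
    q <- adapted_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-15)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(adapted_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # two-stage variant is never less powerful than plain BH
  p <- c(0.001, 0.004, 0.02, 0.3, 0.6, 0.9)
  expect_true(all(adapted_fdr(p, method = "two-stage") <= adapted_fdr(p) + 1e-15))
})

test_that("the focal-term permutation test is calibrated under the null", {
  # exactness of the subject-relabeling test does not depend on cohort
  # scale, so small cohorts keep 300 replicates affordable; the band is
  # +/- ~2.4 binomial SDs around the nominal 0.05
  cfg <- cohort_config(n_subjects = 40, n_nodes = 60,
                       community_sizes = rep(15L, 4), n_timepoints = 60,
                       within_corr = 0.4, jitter_slope = 0)
  pv <- vapply(1:300, function(s) {
    run_synthetic_replicate(cfg, s_value = 2.5, n_runs = 2,
                            permutations = 300, seed = 900000 + 17 * s)$p_perm
  }, numeric(1))
  rate <- mean(pv <= 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
  expect_lt(abs(mean(pv) - 0.5), 0.05)  # uniform null p-values
})

test_that("the bundled reference table reproduces its own printed columns", {
  tab <- reference_model_table()
  expect_equal(nrow(tab), 16)
  q <- adapted_fdr(tab$p)
  row <- which(tab$p == 0.1306)
  expect_equal(q[row], 0.5224, tolerance = 1e-12)
  expect_lt(abs(2 * pnorm(-abs(tab$t[tab$network == "SMN" & tab$condition == "rest"])) -
                  0.0008), 1e-4)
})
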