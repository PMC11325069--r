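test_that("framewise displacement follows the translation + arc-length formula", {
  mp <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(mp), rep(0, 10))

  # 0.2 mm step on one translation axis, returning two frames later
  mp[4:5, 1] <- 0.2
  fd <- framewise_displacement(mp)
  expect_equal(fd[4], 0.2)
  expect_equal(fd[5], 0)
  expect_equal(fd[6], 0.2)

  # 0.004 rad step at 50 mm radius contributes 0.2 mm of arc length
  mp2 <- matrix(0, 5, 6)
  mp2[3, 5] <- 0.004
  expect_equal(framewise_displacement(mp2, head_radius_mm = 50)[3], 0.2)

  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
  expect_error(framewise_displacement(matrix(0, 1, 6)), "2 frames")
})

test_that("DVARS is RMS frame change in percent of global mean", {
  const <- matrix(50, 8, 12)
  expect_equal(dvars(const), rep(0, 12))

  ts <- matrix(100, 10, 6)
  ts[, 4] <- 101  # every node jumps by 1% of the global mean
  gm <- mean(ts)
  expect_equal(dvars(ts)[4], sqrt(mean((ts[, 4] - ts[, 3])^2)) / gm * 100)
  expect_equal(dvars(ts)[4], 1.0, tolerance = 0.01)

  set.seed(41)
  rnd <- matrix(runif(200, 90, 110), 10, 20)
  expect_equal(dvars(rnd), dvars_ref(rnd), tolerance = 1e-12)

  expect_error(dvars(matrix(0, 4, 10)), "not positive")
})

test_that("scrubbing drops exactly the frames over either threshold", {
  ts <- matrix(rnorm(5 * 20, mean = 100), 5, 20)
  fd <- rep(0.1, 20)
  dv <- rep(0.1, 20)
  out <- scrub_volumes(ts, fd, dv)
  expect_equal(out$volumes_removed, 0)
  expect_identical(out$timeseries, ts)

  fd[7] <- 0.6  # just over the 0.5 mm rule
  out <- scrub_volumes(ts, fd, dv)
  expect_equal(out$kept_frame_indices, setdiff(1:20, 7))
  expect_equal(out$volumes_removed + ncol(out$timeseries), 20)

  set.seed(5)
  fd_r <- runif(20, 0, 1)
  dv_r <- runif(20, 0, 1)
  out <- scrub_volumes(ts, fd_r, dv_r)
  expect_equal(out$volumes_removed, length(union(which(fd_r > 0.5), which(dv_r > 0.5))))

  expect_error(scrub_volumes(ts, rep(9, 20), dv), "every frame")
  expect_error(scrub_volumes(ts, fd[1:10], dv), "align")
})

test_that("band-pass keeps in-band sinusoids, kills out-of-band ones and DC", {
  tr <- 2
  t_idx <- seq_len(512)
  in_band <- matrix(sin(2 * pi * 0.04 * tr * t_idx), 1)
  out_band <- matrix(sin(2 * pi * 0.2 * tr * t_idx), 1)

  y_in <- bandpass(in_band, tr)
  expect_equal(sd(y_in), sd(in_band), tolerance = 0.1)

  y_out <- bandpass(out_band, tr)
  expect_lt(sd(y_out), 0.1 * sd(out_band))

  y_const <- bandpass(matrix(7, 1, 512), tr)
  expect_equal(max(abs(y_const)), 0, tolerance = 1e-10)

  expect_error(bandpass(in_band, tr = 10), "Nyquist")
  expect_error(bandpass(in_band[, 1:20, drop = FALSE], tr), "30 frames")
})

test_that("confound regression leaves residuals orthogonal to confounds", {
  set.seed(8)
  ts <- matrix(rnorm(6 * 50), 6, 50)
  conf <- cbind(intercept = 1, a = rnorm(50), b = rnorm(50))
  res <- regress_confounds(ts, conf)
  expect_lt(max(abs(res %*% conf)) / max(abs(ts)), 1e-8)
  expect_true(all(apply(res, 1, var) <= apply(ts, 1, var) + 1e-12))

  self <- regress_confounds(ts[1, , drop = FALSE],
                            cbind(intercept = 1, ts[1, ]))
  expect_equal(max(abs(self)), 0, tolerance = 1e-10)

  dup <- cbind(intercept = 1, a = conf[, 2], a_copy = conf[, 2])
  expect_error(regress_confounds(ts, dup), "a_copy|collinear")
  expect_error(regress_confounds(ts, conf[, 2:3]), "intercept")
})

test_that("clean_series runs scrub -> band-pass -> confound regression", {
  set.seed(9)
  n_frames <- 120
  ts <- matrix(100 + 0.3 * rnorm(20 * n_frames), 20, n_frames)
  mp <- cbind(matrix(rnorm(n_frames * 3, sd = 0.01), n_frames, 3),
              matrix(rnorm(n_frames * 3, sd = 1e-4), n_frames, 3))
  mp[50, 1] <- mp[50, 1] + 2  # one large spike
  out <- clean_series(ts, mp, tr_seconds = 2)
  expect_s3_class(out, "cleaned_series")
  expect_equal(out$volumes_removed + ncol(out$timeseries), n_frames)
  expect_gte(out$volumes_removed, 1)  # the spike frames went
  expect_false(50 %in% out$kept_frame_indices)
  # residuals orthogonal to the filtered motion confounds
  kept_mp <- mp[out$kept_frame_indices, , drop = FALSE]
  filt <- bandpass(t(kept_mp), 2)
  expect_lt(max(abs(out$timeseries %*% t(filt))), 1e-6)

  out2 <- clean_series(ts, mp, tr_seconds = 2, scrub_first = FALSE)
  expect_equal(out2$volumes_removed, out$volumes_removed)
})
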