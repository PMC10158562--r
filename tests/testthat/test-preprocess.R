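montage32 <- make_montage(32)
fs <- 512

test_that("zero-phase band-pass removes DC and retains the passband", {
  n <- 3L * fs
  d <- array(0, c(1, 2, n))
  d[1, 1, ] <- 5                      # pure DC offset
  t <- (seq_len(n) - 1) / fs
  d[1, 2, ] <- sin(2 * pi * 10 * t)   # 10 Hz, inside the passband
  es <- epoch_set(d, "s", fs = fs, pre_lock_tf = 0)
  f <- bandpass_filter(es, hp = 0.2, lp = 30)
  mid <- fs:(2L * fs)                 # trim the filter transients
  expect_lt(mean(abs(f$data[1, 1, mid])) / 5, 0.01)
  expect_lt(abs(max(f$data[1, 2, mid]) - 1), 0.05)
  expect_error(bandpass_filter(es, hp = 30, lp = 0.2), "corner frequencies")
})

test_that("average reference removes the per-TF electrode mean and is idempotent", {
  es <- epoch_set(array(5, c(1, 4, 3)), "s", fs = fs, pre_lock_tf = 0)
  expect_equal(rereference_average(es)$data, array(0, c(1, 4, 3)))
  set.seed(1)
  es2 <- epoch_set(array(rnorm(2 * 8 * 20), c(2, 8, 20)), "s", fs = fs,
                   pre_lock_tf = 0)
  r1 <- rereference_average(es2)
  # brute-force check over all trials and TFs
  expect_lt(max(abs(apply(r1$data, c(1, 3), mean))), 1e-10)
  r2 <- rereference_average(r1)
  expect_equal(r2$data, r1$data, tolerance = 1e-12)
})

test_that("baseline correction subtracts the pre-lock mean per trial and electrode", {
  set.seed(2)
  d <- array(rnorm(2 * 4 * 30), c(2, 4, 30))
  d[1, 2, ] <- d[1, 2, ] + 7          # constant offset survives in baseline
  es <- epoch_set(d, "s", fs = fs, pre_lock_tf = 10)
  b <- baseline_correct(es)
  base_means <- apply(b$data[, , 1:10, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-10)
  # zero-mean baseline leaves the data unchanged
  d0 <- d
  for (tr in 1:2) for (e in 1:4) d0[tr, e, ] <- d0[tr, e, ] - mean(d0[tr, e, 1:10])
  es0 <- epoch_set(d0, "s", fs = fs, pre_lock_tf = 10)
  expect_equal(baseline_correct(es0)$data, d0, tolerance = 1e-12)
  expect_error(baseline_correct(es, window = c(1, 31)), "outside the epoch")
})

test_that("artifact rejection removes exactly the planted spike and error trials", {
  set.seed(3)
  d <- array(rnorm(10, sd = 5) * 0, c(10, 4, 20)) + rnorm(10 * 4 * 20, sd = 5)
  dim(d) <- c(10, 4, 20)
  spiked <- c(2, 7, 9)
  for (tr in spiked) d[tr, 1, 5] <- 150
  meta <- data.frame(trial = 1:10, rt_ms = 800, correct = rep(TRUE, 10))
  meta$correct[4] <- FALSE
  es <- epoch_set(d, "s", fs = fs, pre_lock_tf = 0, meta = meta)
  r <- reject_artifacts(es, abs_threshold = 100)
  expect_identical(unname(r$report["artifact"]), 3L)
  expect_identical(unname(r$report["error"]), 1L)
  expect_identical(r$epochs$meta$trial, setdiff(1:10, c(spiked, 4)))
  # all-quiet trials are untouched
  quiet <- epoch_set(array(rnorm(5 * 4 * 20, sd = 5), c(5, 4, 20)), "s",
                     fs = fs, pre_lock_tf = 0)
  expect_identical(unname(reject_artifacts(quiet, 100)$report["artifact"]), 0L)
})

test_that("spherical-spline interpolation recovers a deep dipolar field and enforces the 20% limit", {
  m128 <- make_montage(128)
  v <- erpmicro:::dipole_field(m128, c(0.05, 0.05, 0.3), c(1, 0.5, 2))
  v <- v - mean(v)
  es <- epoch_set(array(v, c(1, 128, 1)), "s", fs = fs, pre_lock_tf = 0)
  # empty bad set is the identity
  expect_identical(interpolate_bad_electrodes(es, m128, integer(0)), es)
  for (bad in c(1L, 3L, 17L, 40L, 64L, 90L, 110L, 128L)) {
    out <- interpolate_bad_electrodes(es, m128, bad)
    expect_lt(abs(out$data[1, bad, 1] - v[bad]) / gfp(v), 0.1)
  }
  es128 <- epoch_set(array(rnorm(128 * 2), c(1, 128, 2)), "s", fs = fs,
                     pre_lock_tf = 0)
  expect_error(interpolate_bad_electrodes(es128, m128, 1:27), "20%")
  expect_silent(interpolate_bad_electrodes(es128, m128, 1:25))
})

test_that("averaging enforces the trial minimum and has the expected noise scaling", {
  one <- matrix(rnorm(4 * 20), 4)
  es <- epoch_set(aperm(array(one, c(4, 20, 60)), c(3, 1, 2)), "s", fs = fs,
                  pre_lock_tf = 0)
  avg <- average_erp(es, min_trials = 55)
  expect_equal(avg$data, one, tolerance = 1e-12)
  expect_identical(avg$n_trials_averaged, 60L)
  es54 <- epoch_set(es$data[1:54, , , drop = FALSE], "s", fs = fs,
                    pre_lock_tf = 0)
  expect_error(average_erp(es54, min_trials = 55),
               class = "erpmicro_too_few_trials")
  # Monte-Carlo: sd of the average of n iid-noise trials is sigma/sqrt(n)
  set.seed(4)
  n <- 100L; sigma <- 2
  noise <- epoch_set(array(rnorm(n * 4 * 400, sd = sigma), c(n, 4, 400)), "s",
                     fs = fs, pre_lock_tf = 0)
  a <- average_erp(noise, min_trials = 50)
  expect_lt(abs(sd(a$data) - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.1)
})

test_that("the preprocessing chain runs in the canonical order and logs it", {
  set.seed(5)
  d <- synthetic_design(n_groups = 1, n_subjects_per_group = 1,
                        n_trials_per_condition = 5, n_electrodes = 32,
                        noise_sd = 0.5, group_latency_shift = 0,
                        group_amplitude_scale = 1, rt_location = 900, seed = 6)
  syn <- simulate_epochs(d, montage32)
  pp <- preprocess_epochs(syn$stim_epochs[[1]], montage32, bad = 4L)
  expect_match(pp$log[1], "bandpass")
  expect_match(pp$log[2], "average reference")
  expect_match(pp$log[3], "baseline")
  expect_match(pp$log[4], "rejection")
  expect_match(pp$log[5], "interpolated")
  # average reference still holds after the full chain
  expect_lt(max(abs(apply(pp$epochs$data, c(1, 3), mean))), 1e-8)
})
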