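# The synthetic generator plants known microstate structure; these tests
# verify that the planted ground truth is actually realized in the data.

montage32 <- make_montage(32)

test_that("template maps are unit-GFP, average-referenced, separated and seeded", {
  tm <- make_template_maps(4, montage32, min_separation = 0.5, seed = 7)
  expect_equal(colMeans(tm), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(tm, 2, function(v) sqrt(mean(v^2))), rep(1, 4),
               tolerance = 1e-10, ignore_attr = TRUE)
  # brute force over all 6 pairs
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lte(abs(mean(tm[, i] * tm[, j])), 0.5)
  }
  expect_identical(tm, make_template_maps(4, montage32, min_separation = 0.5,
                                          seed = 7))
  # single map is normalization-forced
  one <- make_template_maps(1, montage32, seed = 2)
  expect_equal(sqrt(mean(one^2)), 1, tolerance = 1e-10)
  # unachievable separation fails after a bounded number of attempts
  expect_error(make_template_maps(10, montage32, min_separation = 0.01,
                                  seed = 1, max_attempts = 50),
               "could not draw")
})

test_that("noise-free epochs realize the planted templates exactly", {
  d <- synthetic_design(n_groups = 2, n_subjects_per_group = 1,
                        n_trials_per_condition = 2, n_electrodes = 32,
                        noise_sd = 0, group_latency_shift = c(0, 0),
                        group_amplitude_scale = c(1, 2), seed = 3)
  syn <- simulate_epochs(d, montage32)
  st <- erpmicro:::effective_states(d, 1, 1)
  stim <- st[st$lock == "stimulus", ]
  for (k in seq_len(nrow(stim))) {
    ctr <- d$pre_lock_tf +
      ms_to_tf((stim$onset_ms[k] + stim$offset_ms[k]) / 2, d$fs)
    u <- syn$stim_epochs[[1]]$data[1, , ctr]
    expect_equal(spatial_correlation(u, syn$templates[, stim$map[k]]), 1,
                 tolerance = 1e-9)
  }
  # amplitude scaling is linear: GFP ratio equals the planted scale
  ctr <- d$pre_lock_tf + ms_to_tf((stim$onset_ms[1] + stim$offset_ms[1]) / 2, d$fs)
  g1 <- gfp(syn$stim_epochs[[1]]$data[1, , ctr])
  g2 <- gfp(syn$stim_epochs[[2]]$data[1, , ctr])
  expect_equal(g2 / g1, 2, tolerance = 1e-9)
  # epochs are average-referenced at every TF
  mx <- max(abs(apply(syn$stim_epochs[[1]]$data, c(1, 3), mean)))
  expect_lt(mx, 1e-10)
})

test_that("planted group latency shifts are recovered from grand averages", {
  d <- synthetic_design(n_groups = 2, n_subjects_per_group = 10,
                        n_trials_per_condition = 2, n_electrodes = 32,
                        n_template_maps = 2,
                        state_seq = data.frame(map = 1L, onset_ms = 70,
                                               offset_ms = 150, amplitude = 4,
                                               lock = "stimulus", ramp_ms = 40),
                        noise_sd = 0.5, group_latency_shift = c(40, 0),
                        group_amplitude_scale = c(1, 1),
                        rt_location = c(950, 900),
                        condition_effect = NULL, seed = 21)
  syn <- simulate_epochs(d, montage32)
  grand <- function(grp) {
    subs <- Filter(function(s) s$group == grp, syn$stim_epochs)
    avg <- Reduce(`+`, lapply(subs, function(e) apply(e$data, c(2, 3), mean))) /
      length(subs)
    erp(avg, fs = d$fs, lock = "stimulus", pre_lock_tf = d$pre_lock_tf)
  }
  l1 <- as.numeric(p1_peak_latency(grand("G1"), window = c(60, 220)))
  l2 <- as.numeric(p1_peak_latency(grand("G2"), window = c(60, 220)))
  expect_lte(abs((l1 - l2) - 40), 1000 / d$fs + 1e-9)
})

test_that("sampled RTs respect the truncation bounds and converge to the design moments", {
  # the trial-level sampler at n = 10,000 against closed-form moments
  rt <- erpmicro:::with_seed(17, erpmicro:::rtrunc_norm(10000, 900, 150, 500, 2000))
  expect_true(all(rt >= 500 & rt <= 2000))
  mom <- oracle_truncnorm_moments(900, 150, 500, 2000)
  expect_lt(abs(mean(rt) - mom["mean"]), 3 * mom["sd"] / sqrt(10000))
  expect_lt(abs(sd(rt) - mom["sd"]), 3 * mom["sd"] / sqrt(2 * 10000))
  # and the generator's behavior table respects the bounds
  d <- synthetic_design(n_groups = 1, n_subjects_per_group = 2,
                        n_trials_per_condition = 30, n_electrodes = 32,
                        noise_sd = 0, group_latency_shift = 0,
                        group_amplitude_scale = 1, rt_location = 900,
                        rt_min = 600, rt_max = 1300, seed = 9)
  syn <- simulate_epochs(d, montage32, keep_continuous = FALSE)
  expect_true(all(syn$behavior$rt_ms >= 600 & syn$behavior$rt_ms <= 1300))
})

test_that("equal seeds reproduce the realization bit-exactly, distinct seeds do not", {
  d1 <- synthetic_design(n_groups = 1, n_subjects_per_group = 1,
                         n_trials_per_condition = 2, n_electrodes = 32,
                         seed = 5, group_latency_shift = 0,
                         group_amplitude_scale = 1, rt_location = 900)
  d2 <- d1; d2$seed <- 6L
  s1 <- simulate_epochs(d1, montage32)
  s1b <- simulate_epochs(d1, montage32)
  s2 <- simulate_epochs(d2, montage32)
  expect_identical(s1$stim_epochs[[1]]$data, s1b$stim_epochs[[1]]$data)
  expect_false(identical(s1$stim_epochs[[1]]$data, s2$stim_epochs[[1]]$data))
})

test_that("response-locked re-windowing is consistent with the stimulus-locked data", {
  # all RTs equal: the response-locked average equals the stimulus-locked
  # average over the overlapping window (noise-free)
  d <- synthetic_design(n_groups = 1, n_subjects_per_group = 1,
                        n_trials_per_condition = 3, n_electrodes = 32,
                        noise_sd = 0, group_latency_shift = 0,
                        group_amplitude_scale = 1,
                        rt_location = 800, rt_scale = 1e-9,
                        rt_condition_delta = 0, condition_effect = NULL,
                        seed = 4)
  syn <- simulate_epochs(d, montage32)
  resp <- simulate_response_locked(syn)[[1]]
  expect_identical(attr(resp, "dropped"), 0L)
  rt_f <- ms_to_tf(syn$behavior$rt_ms[1], d$fs)
  # response window covers frames [rt_f - 300, rt_f - 50) relative to onset
  start_col <- d$pre_lock_tf + rt_f - 300L
  stim_avg <- apply(syn$subjects[[1]]$continuous[, , start_col + 1:250], c(2, 3),
                    mean)
  resp_avg <- apply(resp$data, c(2, 3), mean)
  expect_equal(resp_avg, stim_avg, tolerance = 1e-12)
})

test_that("response-locked averaging preserves a response-aligned state that stimulus-locking smears", {
  d <- synthetic_design(n_groups = 1, n_subjects_per_group = 1,
                        n_trials_per_condition = 15, n_electrodes = 32,
                        n_template_maps = 2,
                        state_seq = data.frame(
                          map = c(1L, 2L),
                          onset_ms = c(-420, -220),
                          offset_ms = c(-220, -100),
                          amplitude = c(3, 3),
                          lock = "response", ramp_ms = 10),
                        noise_sd = 0, group_latency_shift = 0,
                        group_amplitude_scale = 1,
                        rt_location = 900, rt_scale = 140,
                        rt_condition_delta = 0, condition_effect = NULL,
                        seed = 8)
  syn <- simulate_epochs(d, montage32)
  resp <- simulate_response_locked(syn)[[1]]
  resp_avg <- apply(resp$data, c(2, 3), mean)
  # center of the first response-locked state: -320 ms before vocal onset,
  # i.e. TF 300 - 164 in the 250-TF epoch starting 300 TFs before onset
  ctr_tf <- 300L + ms_to_tf(-320, d$fs)
  r_resp <- spatial_correlation(resp_avg[, ctr_tf], syn$templates[, 1])
  expect_equal(r_resp, 1, tolerance = 1e-6)
  # the stimulus-locked average at the corresponding mean latency mixes maps
  mean_rt_f <- ms_to_tf(mean(syn$behavior$rt_ms), d$fs)
  stim_avg <- apply(syn$subjects[[1]]$continuous, c(2, 3), mean)
  col <- d$pre_lock_tf + mean_rt_f + ms_to_tf(-320, d$fs)
  r_stim <- abs(spatial_correlation(stim_avg[, col], syn$templates[, 1]))
  expect_lt(r_stim, r_resp - 0.001)
})

test_that("designs whose shifted states exceed the epoch are rejected", {
  expect_error(
    synthetic_design(n_groups = 2, group_latency_shift = c(120, 0),
                     group_amplitude_scale = c(1, 1),
                     rt_location = c(900, 900),
                     accuracy_group = c(0, 0)),
    "exceeds the epoch window")
})
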