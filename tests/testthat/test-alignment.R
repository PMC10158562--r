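fs <- 512

test_that("RT filtering keeps correct trials inside the inclusive bounds", {
  tr <- data.frame(rt_ms = c(450, 500, 1999, 2001), correct = TRUE)
  r <- rt_filter(tr)
  expect_identical(r$trials$rt_ms, c(500, 1999))
  expect_identical(unname(r$report), c(0L, 1L, 1L, 2L))
  # all in range and correct: identity
  tr2 <- data.frame(rt_ms = c(600, 900, 1500), correct = TRUE)
  expect_identical(rt_filter(tr2)$trials, tr2)
  # planted outliers and errors are counted by reason
  set.seed(1)
  tr3 <- data.frame(rt_ms = runif(50, 600, 1900), correct = TRUE)
  tr3$rt_ms[c(3, 9)] <- 400
  tr3$rt_ms[c(20, 21, 22)] <- 2100
  tr3$correct[c(5, 30)] <- FALSE
  r3 <- rt_filter(tr3)
  expect_identical(unname(r3$report["too_fast"]), 2L)
  expect_identical(unname(r3$report["too_slow"]), 3L)
  expect_identical(unname(r3$report["error"]), 2L)
  expect_identical(unname(r3$report["retained"]), 43L)
})

test_that("response-locked epoching uses the round(RT*fs/1000) - 50 convention", {
  # frame-valued data so window positions can be read off directly
  n_cont <- 600L
  cont <- array(0, c(2, 2, n_cont))
  cont[1, 1, ] <- seq_len(n_cont)       # value = column index
  cont[2, 1, ] <- seq_len(n_cont)
  es <- epoch_response_locked(cont, rts = c(800, 800), fs = fs,
                              pre_onset_tf = 50L)
  # RT 800 ms -> end frame 360, start frame 110 (post-onset), columns 161:410
  expect_equal(es$data[1, 1, 1], 161)
  expect_equal(es$data[1, 1, 250], 410)
  expect_identical(attr(es, "dropped"), 0L)
  # RT 500 ms: start frame 256 - 50 - 250 < 0, trial dropped
  es2 <- epoch_response_locked(cont, rts = c(500, 800), fs = fs,
                               pre_onset_tf = 50L)
  expect_identical(attr(es2, "dropped"), 1L)
  expect_identical(dim(es2$data)[1], 1L)
  expect_error(epoch_response_locked(cont, rts = c(500, 500), fs = fs,
                                     pre_onset_tf = 50L), "no trial")
})

test_that("overlap removal obeys the frame-count contract", {
  stim <- erp(matrix(rnorm(4 * 300), 4), fs = fs, lock = "stimulus",
              pre_lock_tf = 50)
  resp <- erp(matrix(rnorm(4 * 250), 4), fs = fs, lock = "response",
              pre_lock_tf = 300)
  ce <- remove_overlap_concatenate(stim, resp, 800)
  expect_identical(ncol(ce$data), 360L)     # 110 stimulus + 250 response
  expect_identical(ce$boundary_tf, 110L)
  expect_equal(ce$data[, 111:360], resp$data)
  expect_equal(ce$data[, 1:110], stim$data[, 51:160])
  # boundary case: RT of exactly 300 TFs leaves no stimulus portion
  rt300 <- 300 * 1000 / fs
  ce2 <- remove_overlap_concatenate(stim, resp, rt300)
  expect_identical(ce2$boundary_tf, 0L)
  expect_identical(ncol(ce2$data), 250L)
  expect_error(remove_overlap_concatenate(stim, resp, 500),
               "minimum supportable RT")
  expect_error(remove_overlap_concatenate(stim, resp, 1500),
               "post-onset frames")
})

test_that("the length contract holds for every synthetic subject and reference is preserved", {
  m <- make_montage(32)
  d <- synthetic_design(n_groups = 2, n_subjects_per_group = 3,
                        n_trials_per_condition = 4, n_electrodes = 32,
                        noise_sd = 0.5, group_latency_shift = c(10, 0),
                        group_amplitude_scale = c(1.1, 1),
                        rt_location = c(950, 900), seed = 31)
  syn <- simulate_epochs(d, m)
  resp_all <- simulate_response_locked(syn)
  for (subj in names(syn$subjects)) {
    stim <- average_erp(syn$stim_epochs[[subj]], min_trials = 1)
    resp <- average_erp(resp_all[[subj]], min_trials = 1)
    rt <- mean(syn$subjects[[subj]]$meta$rt_ms)
    ce <- remove_overlap_concatenate(stim, resp, rt)
    expect_identical(ncol(ce$data), as.integer(ms_to_tf(rt, fs) - 50L))
    expect_identical(ce$boundary_tf, as.integer(ncol(ce$data) - 250L))
    expect_lt(max(abs(colMeans(ce$data))), 1e-8)
  }
})

test_that("noise-free concatenation is continuous at the stimulus/response boundary", {
  m <- make_montage(32)
  d <- synthetic_design(n_groups = 1, n_subjects_per_group = 1,
                        n_trials_per_condition = 5, n_electrodes = 32,
                        noise_sd = 0, group_latency_shift = 0,
                        group_amplitude_scale = 1, rt_location = 900,
                        rt_scale = 1e-9, rt_condition_delta = 0,
                        condition_effect = NULL, seed = 32)
  syn <- simulate_epochs(d, m)
  stim <- average_erp(syn$stim_epochs[[1]], min_trials = 1)
  resp <- average_erp(simulate_response_locked(syn)[[1]], min_trials = 1)
  rt <- syn$behavior$rt_ms[1]
  ce <- remove_overlap_concatenate(stim, resp, rt)
  b <- ce$boundary_tf
  jump <- sqrt(mean((ce$data[, b + 1] - ce$data[, b])^2))
  typical <- mean(sqrt(colMeans(diff(t(ce$data))^2)))
  expect_lt(jump, typical * 3 + 1e-9)
})
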