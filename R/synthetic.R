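# Synthetic multi-group, multi-condition epoched EEG with planted microstate
# structure. The generator writes down the ground truth (template maps, state
# windows, latency shifts, amplitude scalings, RT/accuracy model) so that
# every downstream stage of the pipeline can be verified against it.

#' Generate synthetic template maps
#'
#' Draws unit-GFP, average-referenced scalp maps that are smooth over the
#' montage: each map is the potential field of one or two randomly placed
#' dipolar sources projected to the electrodes. Rejection sampling enforces a
#' maximal pairwise spatial correlation.
#'
#' @param n_maps Number of maps (>= 1).
#' @param montage A [make_montage()] object.
#' @param min_separation Maximal allowed pairwise `|spatial correlation|`
#'   between maps, in `[0, 1)`.
#' @param seed Integer seed (the operation is deterministic given the seed).
#' @param max_attempts Rejection-sampling budget before giving up.
#' @return Electrodes x `n_maps` matrix of unit-GFP maps, columns named
#'   `A`, `B`, ...
#' @export
make_template_maps <- function(n_maps, montage, min_separation = 0.7,
                               seed = 1L, max_attempts = 200L * n_maps) {
  stopifnot(n_maps >= 1, min_separation >= 0, min_separation < 1)
  validate_montage(montage)
  ne <- nrow(montage$pos)
  maps <- matrix(NA_real_, ne, 0L)
  with_seed(seed, {
    attempts <- 0L
    while (ncol(maps) < n_maps) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf("could not draw %d maps with pairwise |r| <= %g on this montage (%d attempts)",
                     n_maps, min_separation, max_attempts))
      }
      nd <- sample(1:2, 1L)
      # dipoles in the upper part of the head volume
      dp <- matrix(stats::rnorm(3L * nd), nd, 3L)
      dp <- dp / sqrt(rowSums(dp^2)) * stats::runif(nd, 0.35, 0.75)
      dp[, 3L] <- abs(dp[, 3L]) * sign(stats::runif(nd, -0.2, 1))
      dm <- matrix(stats::rnorm(3L * nd), nd, 3L)
      v <- dipole_field(montage, dp, dm)
      v <- v - mean(v)
      g <- sqrt(mean(v^2))
      if (g <= .field_eps) next
      v <- v / g
      ok <- TRUE
      if (ncol(maps) > 0L) {
        r <- abs(crossprod(maps, v) / ne)
        ok <- all(r <= min_separation)
      }
      if (ok) maps <- cbind(maps, v)
    }
  })
  colnames(maps) <- LETTERS[seq_len(n_maps)]
  rownames(maps) <- montage$labels
  maps
}

#' Describe a synthetic picture-naming study
#'
#' Builds the full description of a multi-group, multi-condition synthetic
#' experiment: planted microstate sequence, group latency shifts and
#' amplitude scaling, a condition (age-of-acquisition-like) amplitude effect
#' in a late window, spatially smooth noise, and truncated RT plus logistic
#' accuracy models. The defaults mirror a four-group developmental design
#' (children, young adolescents, older adolescents, adults) with 20 subjects
#' per group, two word conditions, a 128-electrode montage and 512 Hz
#' sampling; `n_electrodes` can be reduced (e.g. 32) for speed.
#'
#' State windows are given in ms: stimulus-locked states relative to picture
#' onset, response-locked states relative to vocal onset (negative times).
#' Raised-cosine ramps (`ramp_ms`) avoid instantaneous switches.
#'
#' @param n_groups Number of groups.
#' @param n_subjects_per_group Subjects per group.
#' @param n_trials_per_condition Trials per condition and subject.
#' @param n_electrodes Montage size.
#' @param fs Sampling rate (Hz).
#' @param n_template_maps Number of planted template maps (when
#'   `template_maps` is `NULL` they are generated from the seed).
#' @param template_maps Optional electrodes x k matrix of planted maps.
#' @param min_separation Maximal pairwise `|r|` between generated maps.
#' @param state_seq Data frame with columns `map` (template index),
#'   `onset_ms`, `offset_ms`, `amplitude` (microvolts), `lock`
#'   (`"stimulus"`/`"response"`), `ramp_ms`.
#' @param group_latency_shift Per-group shift (ms) applied to the onsets of
#'   stimulus-locked states.
#' @param group_amplitude_scale Per-group multiplicative amplitude scale.
#' @param condition_effect `NULL`, or a list with `window_ms` (2-vector),
#'   and either `delta` (additive microvolts on the amplitude of stimulus-
#'   locked states overlapping the window, condition 2 only) or `map`
#'   (template index substituted in condition 2 for overlapping states).
#' @param noise_sd Per-electrode noise standard deviation (microvolts) after
#'   spatial smoothing.
#' @param spatial_noise_smoothness Correlation length (chord distance on the
#'   unit sphere) of the Gaussian smoothing kernel applied to electrode
#'   noise.
#' @param rt_location Per-group location (ms) of the truncated-normal RT
#'   distribution.
#' @param rt_scale RT scale (ms).
#' @param rt_min,rt_max Truncation bounds (ms).
#' @param rt_condition_delta Added to the RT location for condition 2.
#' @param accuracy_intercept,accuracy_group,accuracy_condition Logit model
#'   of response accuracy: intercept, per-group offsets, condition-2 offset.
#' @param epoch_tf,pre_lock_tf Stimulus-locked epoch geometry (total TFs and
#'   pre-stimulus TFs).
#' @param resp_epoch_tf,resp_end_offset_tf Response-locked epoch geometry:
#'   length, and the gap between the epoch end and the vocal onset.
#' @param seed Integer seed driving all randomness of the realization.
#' @return Object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_groups = 4L,
                             n_subjects_per_group = 20L,
                             n_trials_per_condition = 60L,
                             n_electrodes = 128L,
                             fs = 512,
                             n_template_maps = 6L,
                             template_maps = NULL,
                             min_separation = 0.6,
                             state_seq = NULL,
                             group_latency_shift = c(30, 10, 0, 0)[seq_len(n_groups)],
                             group_amplitude_scale = c(1.4, 1.2, 1, 1)[seq_len(n_groups)],
                             condition_effect = list(window_ms = c(350, 450), delta = 0.8),
                             noise_sd = 1,
                             spatial_noise_smoothness = 0.5,
                             rt_location = c(980, 950, 925, 900)[seq_len(n_groups)],
                             rt_scale = 110,
                             rt_min = 500, rt_max = 2000,
                             rt_condition_delta = 20,
                             accuracy_intercept = 3.3,
                             accuracy_group = c(-0.65, -0.35, -0.1, 0)[seq_len(n_groups)],
                             accuracy_condition = -0.3,
                             epoch_tf = 300L, pre_lock_tf = 50L,
                             resp_epoch_tf = 250L, resp_end_offset_tf = 50L,
                             seed = 1L) {
  if (is.null(state_seq)) {
    state_seq <- data.frame(
      map = c(1L, 2L, 3L, 4L, 5L, 6L),
      onset_ms  = c(70, 150, 230, 330, -420, -220),
      offset_ms = c(150, 230, 330, 450, -220, -100),
      amplitude = c(4, 3.5, 3, 2.5, 2.5, 3),
      lock = c("stimulus", "stimulus", "stimulus", "stimulus",
               "response", "response"),
      ramp_ms = c(40, 30, 20, 20, 20, 20),
      stringsAsFactors = FALSE
    )
    state_seq <- state_seq[state_seq$map <= n_template_maps, , drop = FALSE]
  }
  d <- structure(list(
    n_groups = as.integer(n_groups),
    groups = paste0("G", seq_len(n_groups)),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    n_electrodes = as.integer(n_electrodes),
    fs = fs,
    n_template_maps = as.integer(n_template_maps),
    template_maps = template_maps,
    min_separation = min_separation,
    state_seq = state_seq,
    group_latency_shift = group_latency_shift,
    group_amplitude_scale = group_amplitude_scale,
    condition_effect = condition_effect,
    noise_sd = noise_sd,
    spatial_noise_smoothness = spatial_noise_smoothness,
    rt_location = rt_location, rt_scale = rt_scale,
    rt_min = rt_min, rt_max = rt_max,
    rt_condition_delta = rt_condition_delta,
    accuracy_intercept = accuracy_intercept,
    accuracy_group = accuracy_group,
    accuracy_condition = accuracy_condition,
    epoch_tf = as.integer(epoch_tf), pre_lock_tf = as.integer(pre_lock_tf),
    resp_epoch_tf = as.integer(resp_epoch_tf),
    resp_end_offset_tf = as.integer(resp_end_offset_tf),
    seed = as.integer(seed)), class = "synthetic_design")
  validate_design(d)
}

validate_design <- function(d) {
  stopifnot(inherits(d, "synthetic_design"))
  if (d$rt_min < 0 || d$rt_max <= d$rt_min) {
    stop("require rt_min >= 0 and rt_max > rt_min")
  }
  if (length(d$group_latency_shift) != d$n_groups ||
      length(d$group_amplitude_scale) != d$n_groups ||
      length(d$rt_location) != d$n_groups ||
      length(d$accuracy_group) != d$n_groups) {
    stop("per-group parameter vectors must have length n_groups")
  }
  s <- d$state_seq
  for (lk in unique(s$lock)) {
    w <- s[s$lock == lk, , drop = FALSE]
    w <- w[order(w$onset_ms), , drop = FALSE]
    if (any(w$offset_ms <= w$onset_ms)) {
      stop("state windows must have offset > onset")
    }
    if (nrow(w) > 1L && any(w$onset_ms[-1L] < w$offset_ms[-nrow(w)])) {
      stop(sprintf("%s-locked state windows must be non-overlapping and ordered", lk))
    }
  }
  # shifted stimulus states must fit in the stimulus-locked epoch
  stim <- s[s$lock == "stimulus", , drop = FALSE]
  if (nrow(stim) > 0L) {
    post_ms <- (d$epoch_tf - d$pre_lock_tf) * 1000 / d$fs
    if (max(stim$offset_ms) + max(d$group_latency_shift) > post_ms) {
      stop("shifted stimulus-locked state sequence exceeds the epoch window")
    }
    if (min(stim$onset_ms) + min(d$group_latency_shift) < -d$pre_lock_tf * 1000 / d$fs) {
      stop("shifted stimulus-locked state sequence precedes the epoch window")
    }
  }
  resp <- s[s$lock == "response", , drop = FALSE]
  if (nrow(resp) > 0L) {
    lo <- -(d$resp_epoch_tf + d$resp_end_offset_tf) * 1000 / d$fs
    hi <- -d$resp_end_offset_tf * 1000 / d$fs
    if (min(resp$onset_ms) < lo || max(resp$offset_ms) > hi) {
      stop("response-locked states must fall inside the response-locked epoch window")
    }
  }
  invisible(d)
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("<synthetic_design> %d groups x %d subjects x 2 conditions, %d trials/condition, %d electrodes @ %g Hz, %d planted states, seed %d\n",
              x$n_groups, x$n_subjects_per_group, x$n_trials_per_condition,
              x$n_electrodes, x$fs, nrow(x$state_seq), x$seed))
  invisible(x)
}

# Truncated-normal sampler by inverse CDF (deterministic under set.seed).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Closed-form mean and sd of the truncated normal (used by tests as well).
trunc_norm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Spatial smoothing operator for electrode noise: Gaussian kernel in chord
# distance, rows rescaled so the smoothed noise keeps unit marginal sd, then
# average-referenced downstream.
noise_operator <- function(montage, smoothness) {
  d <- as.matrix(stats::dist(montage$pos))
  w <- exp(-d^2 / (2 * smoothness^2))
  w / sqrt(rowSums(w^2))
}

# Raised-cosine amplitude envelope of one state over continuous frames
# 0..(n_frames-1) (frame 0 = first continuous sample).
state_envelope <- function(n_frames, onset_f, offset_f, ramp_f) {
  env <- numeric(n_frames)
  len <- offset_f - onset_f
  if (len <= 0L) return(env)
  ramp_f <- min(ramp_f, floor(len / 2))
  prof <- rep(1, len)
  if (ramp_f > 0L) {
    up <- 0.5 * (1 - cos(pi * (seq_len(ramp_f) - 0.5) / ramp_f))
    prof[seq_len(ramp_f)] <- up
    prof[len + 1L - seq_len(ramp_f)] <- up
  }
  idx <- onset_f + seq_len(len)   # 1-based columns for frames onset_f..offset_f-1
  keep <- idx >= 1L & idx <= n_frames
  env[idx[keep]] <- prof[keep]
  env
}

#' Simulate the synthetic experiment
#'
#' Realizes a [synthetic_design()]: each trial is simulated as one continuous
#' segment (from 50 TFs before picture onset to beyond the latest possible
#' response window) so that stimulus- and response-locked epochs are
#' mutually consistent re-windowings of the same data. The signal at each TF
#' is an amplitude envelope times the assigned template map plus spatially
#' smoothed, average-referenced Gaussian noise. RTs are drawn per trial from
#' the truncated distribution and accuracy from the logistic model.
#'
#' @param design A [synthetic_design()].
#' @param montage Optional [make_montage()]; defaults to a generated montage
#'   with `design$n_electrodes` electrodes.
#' @param keep_continuous Keep the continuous per-trial segments (needed by
#'   [simulate_response_locked()]).
#' @return Object of class `synth_data`: `montage`, `design`, `templates`
#'   (electrodes x k unit-GFP maps), `subjects` (per-subject list with
#'   `continuous` trials x electrodes x frames array and `meta`),
#'   `stim_epochs` (list of stimulus-locked [epoch_set()]), `behavior`
#'   (per-trial RT/accuracy table), and `truth` (planted state windows in
#'   frames, per group and condition).
#' @export
simulate_epochs <- function(design, montage = NULL, keep_continuous = TRUE) {
  validate_design(design)
  if (is.null(montage)) montage <- make_montage(design$n_electrodes)
  validate_montage(montage)
  ne <- nrow(montage$pos)
  if (ne != design$n_electrodes) {
    stop("montage size does not match design$n_electrodes")
  }
  fs <- design$fs
  templates <- design$template_maps
  if (is.null(templates)) {
    templates <- make_template_maps(design$n_template_maps, montage,
                                    design$min_separation,
                                    seed = design$seed + 1000L)
  } else {
    templates <- apply(as.matrix(templates), 2L, normalize_map)
    if (is.null(colnames(templates))) {
      colnames(templates) <- LETTERS[seq_len(ncol(templates))]
    }
  }
  n_cont <- design$pre_lock_tf + ms_to_tf(design$rt_max, fs)
  smooth_op <- if (design$noise_sd > 0) {
    noise_operator(montage, design$spatial_noise_smoothness)
  } else NULL

  n_trials <- 2L * design$n_trials_per_condition
  cond_lab <- rep(c("early", "late"), each = design$n_trials_per_condition)

  subjects <- list()
  stim_epochs <- list()
  behavior <- list()
  truth <- list()
  with_seed(design$seed, {
    sid <- 0L
    for (g in seq_len(design$n_groups)) {
      shift <- design$group_latency_shift[g]
      scale <- design$group_amplitude_scale[g]
      for (cc in 1:2) {
        states <- effective_states(design, g, cc)
        truth[[paste0(design$groups[g], ".", c("early", "late")[cc])]] <- states
      }
      for (s in seq_len(design$n_subjects_per_group)) {
        sid <- sid + 1L
        subj <- sprintf("S%03d", sid)
        rt <- rtrunc_norm(n_trials,
                          design$rt_location[g] +
                            design$rt_condition_delta * (cond_lab == "late"),
                          design$rt_scale, design$rt_min, design$rt_max)
        p_correct <- stats::plogis(design$accuracy_intercept +
                                     design$accuracy_group[g] +
                                     design$accuracy_condition * (cond_lab == "late"))
        correct <- stats::runif(n_trials) < p_correct
        dat <- array(0, c(n_trials, ne, n_cont))
        for (tr in seq_len(n_trials)) {
          cc <- if (cond_lab[tr] == "late") 2L else 1L
          states <- effective_states(design, g, cc)
          sig <- matrix(0, ne, n_cont)
          rt_f <- ms_to_tf(rt[tr], fs)
          for (k in seq_len(nrow(states))) {
            st <- states[k, ]
            if (st$lock == "stimulus") {
              on_f <- design$pre_lock_tf + ms_to_tf(st$onset_ms, fs)
              off_f <- design$pre_lock_tf + ms_to_tf(st$offset_ms, fs)
            } else {
              on_f <- design$pre_lock_tf + rt_f + ms_to_tf(st$onset_ms, fs)
              off_f <- design$pre_lock_tf + rt_f + ms_to_tf(st$offset_ms, fs)
            }
            env <- state_envelope(n_cont, on_f, off_f, ms_to_tf(st$ramp_ms, fs))
            sig <- sig + st$amplitude * tcrossprod(templates[, st$map], env)
          }
          if (design$noise_sd > 0) {
            noise <- design$noise_sd *
              (smooth_op %*% matrix(stats::rnorm(ne * n_cont), ne, n_cont))
            sig <- sig + center_cols(as.matrix(noise))
          }
          dat[tr, , ] <- sig
        }
        meta <- data.frame(trial = seq_len(n_trials), condition = cond_lab,
                           rt_ms = rt, correct = correct)
        subjects[[subj]] <- list(subject = subj, group = design$groups[g],
                                 group_idx = g,
                                 continuous = if (keep_continuous) dat else NULL,
                                 meta = meta)
        stim_cols <- seq_len(design$epoch_tf)
        stim_epochs[[subj]] <- epoch_set(dat[, , stim_cols, drop = FALSE],
                                         subject = subj,
                                         group = design$groups[g],
                                         lock = "stimulus", fs = fs,
                                         pre_lock_tf = design$pre_lock_tf,
                                         meta = meta)
        behavior[[subj]] <- data.frame(subject = subj, group = design$groups[g],
                                       meta)
      }
    }
  })
  structure(list(montage = montage, design = design, templates = templates,
                 subjects = subjects, stim_epochs = stim_epochs,
                 behavior = do.call(rbind, c(behavior, make.row.names = FALSE)),
                 truth = truth),
            class = "synth_data")
}

# Planted state table for one group x condition, with group latency shift,
# amplitude scaling and the condition effect applied.
effective_states <- function(design, g, cond_idx) {
  states <- design$state_seq
  stim <- states$lock == "stimulus"
  states$onset_ms[stim] <- states$onset_ms[stim] + design$group_latency_shift[g]
  states$offset_ms[stim] <- states$offset_ms[stim] + design$group_latency_shift[g]
  states$amplitude <- states$amplitude * design$group_amplitude_scale[g]
  ce <- design$condition_effect
  if (!is.null(ce) && cond_idx == 2L) {
    hit <- stim & states$offset_ms > ce$window_ms[1L] &
      states$onset_ms < ce$window_ms[2L]
    if (!is.null(ce$delta)) states$amplitude[hit] <- states$amplitude[hit] + ce$delta
    if (!is.null(ce$map)) states$map[hit] <- ce$map
  }
  states
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("<synth_data> %d subjects, %d electrodes, %d templates, %d trials/subject\n",
              length(x$subjects), nrow(x$montage$pos), ncol(x$templates),
              nrow(x$subjects[[1L]]$meta)))
  invisible(x)
}

#' Re-window simulated trials into response-locked epochs
#'
#' For each trial the epoch ends `end_offset_tf` time-frames before the
#' vocal onset (at `round(RT * fs / 1000)` frames after picture onset) and
#' spans `length_tf` frames. Trials whose window would precede picture onset
#' are dropped and counted in the `dropped` attribute.
#'
#' @param synth A [simulate_epochs()] result with continuous segments.
#' @param length_tf Epoch length (TFs).
#' @param end_offset_tf Gap between epoch end and vocal onset (TFs).
#' @return Named list of response-locked [epoch_set()] objects (one per
#'   subject), each with a `dropped` attribute counting removed trials.
#' @export
simulate_response_locked <- function(synth,
                                     length_tf = synth$design$resp_epoch_tf,
                                     end_offset_tf = synth$design$resp_end_offset_tf) {
  stopifnot(inherits(synth, "synth_data"))
  lapply(synth$subjects, function(su) {
    if (is.null(su$continuous)) stop("continuous segments were not kept")
    es <- epoch_response_locked(su$continuous, su$meta$rt_ms,
                                fs = synth$design$fs,
                                pre_onset_tf = synth$design$pre_lock_tf,
                                length_tf = length_tf,
                                end_offset_tf = end_offset_tf,
                                meta = su$meta)
    es$subject <- su$subject
    es$group <- su$group
    es
  })
}
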