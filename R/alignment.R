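# RT-based trial filtering, response-locked epoching, and removal of the
# stimulus/response overlap to produce combined per-subject ERPs covering
# picture onset to 50 TFs before articulation.

#' Filter trials on reaction time and accuracy
#'
#' Retains correct trials with `lo <= RT <= hi` (defaults 500 and 2000 ms;
#' RTs strictly shorter than `lo` or strictly longer than `hi` are outliers).
#'
#' @param trials Data frame with columns `rt_ms` and `correct`.
#' @param lo,hi RT bounds in ms.
#' @return List with `trials` (retained rows) and `report` (counts by
#'   exclusion reason: `error`, `too_fast`, `too_slow`, `retained`).
#' @export
rt_filter <- function(trials, lo = 500, hi = 2000) {
  stopifnot(all(c("rt_ms", "correct") %in% names(trials)))
  err <- !trials$correct
  fast <- trials$correct & trials$rt_ms < lo
  slow <- trials$correct & trials$rt_ms > hi
  keep <- trials$correct & trials$rt_ms >= lo & trials$rt_ms <= hi
  list(trials = trials[keep, , drop = FALSE],
       report = c(error = sum(err), too_fast = sum(fast),
                  too_slow = sum(slow), retained = sum(keep)))
}

#' Extract response-locked epochs from continuous trial segments
#'
#' Each trial's window ends at `round(RT * fs / 1000) - end_offset_tf`
#' frames after picture onset (i.e. `end_offset_tf` TFs before the vocal
#' onset, which removes pre-articulatory motor activity) and spans
#' `length_tf` frames. Trials whose window would precede picture onset are
#' dropped and counted.
#'
#' @param continuous Trials x electrodes x frames array; frame
#'   `pre_onset_tf + 1` is picture onset.
#' @param rts Per-trial RT in ms.
#' @param fs Sampling rate (Hz).
#' @param pre_onset_tf Frames before picture onset in `continuous`.
#' @param length_tf Epoch length in TFs (default 250).
#' @param end_offset_tf Gap between epoch end and vocal onset (default 50).
#' @param meta Optional per-trial metadata carried through (subset to the
#'   surviving trials).
#' @return A response-locked [epoch_set()] with attribute `dropped` (number
#'   of removed trials). Its `pre_lock_tf` equals
#'   `length_tf + end_offset_tf`, so time 0 is the vocal onset.
#' @export
epoch_response_locked <- function(continuous, rts, fs, pre_onset_tf,
                                  length_tf = 250L, end_offset_tf = 50L,
                                  meta = NULL) {
  stopifnot(length(dim(continuous)) == 3L, dim(continuous)[1L] == length(rts))
  n_cont <- dim(continuous)[3L]
  end_f <- ms_to_tf(rts, fs) - end_offset_tf
  start_f <- end_f - length_tf
  ok <- start_f >= 0L & (pre_onset_tf + end_f) <= n_cont
  dropped <- sum(!ok)
  if (!any(ok)) stop("no trial supports the requested response-locked window")
  keep <- which(ok)
  out <- array(NA_real_, c(length(keep), dim(continuous)[2L], length_tf))
  for (i in seq_along(keep)) {
    tr <- keep[i]
    cols <- pre_onset_tf + start_f[tr] + seq_len(length_tf)
    out[i, , ] <- continuous[tr, , cols]
  }
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  es <- epoch_set(out, subject = NA_character_, lock = "response", fs = fs,
                  pre_lock_tf = length_tf + end_offset_tf, meta = meta)
  attr(es, "dropped") <- dropped
  es
}

#' Remove the stimulus/response overlap and concatenate ERPs
#'
#' Keeps the first `round(mean_rt * fs / 1000) - (length_tf + end_offset_tf)`
#' post-onset frames of the stimulus-locked ERP and appends the full
#' response-locked ERP, so that the combined signal covers the exact
#' interval from picture onset to `end_offset_tf` TFs before articulation:
#' its length is `round(mean_rt * fs / 1000) - end_offset_tf` frames.
#' Applied per group (group-average RT) for grand averages and per subject
#' (individual mean RT) for the fitting procedure.
#'
#' @param stim Stimulus-locked [erp()].
#' @param resp Response-locked [erp()] (its `pre_lock_tf` encodes
#'   `length_tf + end_offset_tf`).
#' @param mean_rt Mean RT (ms) used to place the cut.
#' @return Object of class `combined_erp`: `data`, `times` (ms from picture
#'   onset), `boundary_tf` (last stimulus-locked frame; the response-locked
#'   portion starts at `boundary_tf + 1`), `rt_ms`, `fs`.
#' @export
remove_overlap_concatenate <- function(stim, resp, mean_rt) {
  stopifnot(inherits(stim, "erp"), inherits(resp, "erp"),
            stim$lock == "stimulus", resp$lock == "response",
            stim$fs == resp$fs)
  fs <- stim$fs
  n_resp <- ncol(resp$data)
  end_offset_tf <- resp$pre_lock_tf - n_resp
  stopifnot(end_offset_tf >= 0L)
  n_total <- ms_to_tf(mean_rt, fs) - end_offset_tf
  n_stim <- n_total - n_resp
  if (n_stim < 0L) {
    stop(sprintf("mean RT %.1f ms is too short: minimum supportable RT is %.1f ms",
                 mean_rt, (n_resp + end_offset_tf) * 1000 / fs))
  }
  avail <- ncol(stim$data) - stim$pre_lock_tf
  if (n_stim > avail) {
    stop(sprintf("stimulus-locked ERP provides only %d post-onset frames but %d are required before the cut",
                 avail, n_stim))
  }
  dat <- cbind(
    if (n_stim > 0L) stim$data[, stim$pre_lock_tf + seq_len(n_stim), drop = FALSE],
    resp$data
  )
  structure(list(data = dat,
                 times = (seq_len(n_total) - 1L) * 1000 / fs,
                 boundary_tf = n_stim, rt_ms = mean_rt, fs = fs,
                 subject = stim$subject, group = stim$group,
                 condition = stim$condition),
            class = "combined_erp")
}

#' @export
print.combined_erp <- function(x, ...) {
  cat(sprintf("<combined_erp> %d electrodes x %d TFs (stimulus portion %d + response portion %d), RT %.1f ms\n",
              nrow(x$data), ncol(x$data), x$boundary_tf,
              ncol(x$data) - x$boundary_tf, x$rt_ms))
  invisible(x)
}
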