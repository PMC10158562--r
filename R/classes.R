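# S3 containers for epoched data and averaged ERPs.

#' Construct an epoch set
#'
#' An `epoch_set` holds one subject's epoched EEG as a
#' trials x electrodes x time-frames array in microvolts, together with the
#' lock convention (stimulus or response), the sampling rate, the number of
#' pre-lock time-frames and per-trial metadata (reaction time, accuracy).
#'
#' @param data Numeric array, trials x electrodes x time-frames (microvolts).
#' @param subject Subject identifier.
#' @param group Group label.
#' @param condition Condition label.
#' @param lock Either `"stimulus"` or `"response"`.
#' @param fs Sampling rate in Hz.
#' @param pre_lock_tf Number of time-frames before the lock event.
#' @param meta Data frame with one row per trial; columns `rt_ms` and
#'   `correct` are used by downstream filtering.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, subject, group = NA_character_,
                      condition = NA_character_,
                      lock = c("stimulus", "response"), fs, pre_lock_tf,
                      meta = NULL) {
  lock <- match.arg(lock)
  stopifnot(length(dim(data)) == 3L, fs > 0, pre_lock_tf >= 0)
  if (anyNA(data)) stop("epoch data must not contain missing values")
  if (is.null(meta)) {
    meta <- data.frame(trial = seq_len(dim(data)[1L]),
                       rt_ms = NA_real_, correct = TRUE)
  }
  if (nrow(meta) != dim(data)[1L]) {
    stop("meta must have one row per trial")
  }
  structure(list(data = data, subject = subject, group = group,
                 condition = condition, lock = lock, fs = fs,
                 pre_lock_tf = as.integer(pre_lock_tf), meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s (%s/%s), %s-locked: %d trials x %d electrodes x %d TFs @ %g Hz (%d pre-lock TFs)\n",
              x$subject, x$group, x$condition, x$lock,
              d[1L], d[2L], d[3L], x$fs, x$pre_lock_tf))
  invisible(x)
}

#' Construct an averaged ERP
#'
#' An `erp` is an electrodes x time-frames matrix (microvolts) averaged over
#' trials, with a millisecond time axis relative to the lock event.
#'
#' @param data Numeric matrix, electrodes x time-frames.
#' @param fs Sampling rate in Hz.
#' @param lock Either `"stimulus"` or `"response"`.
#' @param pre_lock_tf Time-frames before the lock event (defines time zero).
#' @param n_trials Number of trials averaged.
#' @param subject,group,condition Optional labels carried along.
#' @return An object of class `erp` with a `times` component in ms.
#' @export
erp <- function(data, fs, lock = c("stimulus", "response"), pre_lock_tf,
                n_trials = NA_integer_, subject = NA_character_,
                group = NA_character_, condition = NA_character_) {
  lock <- match.arg(lock)
  stopifnot(is.matrix(data), fs > 0)
  times <- (seq_len(ncol(data)) - 1L - pre_lock_tf) * 1000 / fs
  structure(list(data = data, times = times, fs = fs, lock = lock,
                 pre_lock_tf = as.integer(pre_lock_tf),
                 n_trials_averaged = n_trials, subject = subject,
                 group = group, condition = condition),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> %s-locked, %d electrodes x %d TFs @ %g Hz, t = [%.1f, %.1f] ms, %s trials averaged\n",
              x$lock, nrow(x$data), ncol(x$data), x$fs,
              min(x$times), max(x$times),
              ifelse(is.na(x$n_trials_averaged), "?", x$n_trials_averaged)))
  invisible(x)
}

# Extract the electrodes x TFs matrix from an erp / combined_erp / matrix.
erp_matrix <- function(x) {
  if (inherits(x, "erp") || inherits(x, "combined_erp")) x$data
  else if (is.matrix(x)) x
  else stop("expected an erp, combined_erp or matrix")
}

#' Stack per-subject ERPs into a subject x condition x electrode x TF array
#'
#' Helper used by the point-wise ANOVA, tANOVA and consistency tests. All
#' ERPs must share electrode count and length; every subject must contribute
#' one ERP per condition.
#'
#' @param erps List of [erp()] objects (or plain matrices).
#' @param subject,group,condition Vectors parallel to `erps`. `group` is a
#'   per-entry group label (constant within subject).
#' @return List with `x` (4-d array), `subjects`, `group` (per subject),
#'   `conditions`.
#' @export
stack_erps <- function(erps, subject, group, condition) {
  mats <- lapply(erps, erp_matrix)
  ne <- unique(vapply(mats, nrow, 0L))
  nt <- unique(vapply(mats, ncol, 0L))
  if (length(ne) != 1L || length(nt) != 1L) {
    stop("all ERPs must share electrode count and number of TFs")
  }
  subjects <- unique(subject)
  conds <- sort(unique(condition))
  x <- array(NA_real_, c(length(subjects), length(conds), ne, nt))
  grp <- character(length(subjects))
  for (i in seq_along(subjects)) {
    for (j in seq_along(conds)) {
      k <- which(subject == subjects[i] & condition == conds[j])
      if (length(k) != 1L) {
        stop(sprintf("subject %s must contribute exactly one ERP for condition %s (found %d)",
                     subjects[i], conds[j], length(k)))
      }
      x[i, j, , ] <- mats[[k]]
      grp[i] <- as.character(group[k])
    }
  }
  list(x = x, subjects = subjects, group = factor(grp), conditions = conds)
}
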