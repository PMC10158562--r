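# Preprocessing: filtering, average reference, baseline correction,
# artifact rejection, bad-electrode interpolation, single-subject averages.
# The canonical stage order is filter -> re-reference -> reject ->
# interpolate -> average; preprocess_epochs() enforces and logs it.

# Zero-phase (forward-backward) IIR filtering with odd reflection padding at
# both edges; realizes an acausal filter without committing to a toolbox's
# padding default.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  p <- n - 1L
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(p + 1L):(p + n)]
}

#' Band-pass filter an epoch set
#'
#' Second-order Butterworth high-pass and low-pass filters (12 dB/octave
#' roll-off each), applied forward-backward (zero-phase, acausal) per trial
#' and electrode. Defaults: 0.2-30 Hz.
#'
#' @param epochs An [epoch_set()].
#' @param hp High-pass corner (Hz); 0 disables the high-pass.
#' @param lp Low-pass corner (Hz).
#' @return The filtered [epoch_set()].
#' @export
bandpass_filter <- function(epochs, hp = 0.2, lp = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (!(hp >= 0 && hp < lp && lp < fs / 2)) {
    stop("invalid corner frequencies: require 0 <= hp < lp < fs/2")
  }
  bhp <- if (hp > 0) signal::butter(2, hp / (fs / 2), type = "high") else NULL
  blp <- signal::butter(2, lp / (fs / 2), type = "low")
  d <- epochs$data
  nt <- dim(d)[1L]; ne <- dim(d)[2L]
  for (tr in seq_len(nt)) {
    for (e in seq_len(ne)) {
      x <- d[tr, e, ]
      if (!is.null(bhp)) x <- filtfilt_refl(bhp$b, bhp$a, x)
      x <- filtfilt_refl(blp$b, blp$a, x)
      d[tr, e, ] <- x
    }
  }
  epochs$data <- d
  epochs
}

#' Recalculate an epoch set against the average reference
#'
#' Subtracts the across-electrode mean at every trial and time-frame.
#' Idempotent.
#'
#' @param epochs An [epoch_set()].
#' @return The re-referenced [epoch_set()].
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[2L] < 2L) stop("average reference needs >= 2 electrodes")
  m <- apply(epochs$data, c(1L, 3L), mean)       # trials x TFs
  epochs$data <- epochs$data - aperm(array(m, c(dim(m), dim(epochs$data)[2L])),
                                     c(1L, 3L, 2L))
  epochs
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and electrode, the mean over a baseline window. The
#' default window is the pre-lock period; by convention this is applied to
#' stimulus-locked epochs only (response-locked epochs are left
#' uncorrected).
#'
#' @param epochs An [epoch_set()].
#' @param window Integer TF interval `c(first, last)` (1-based columns);
#'   default `c(1, pre_lock_tf)`.
#' @return The baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- dim(epochs$data)[3L]
  if (is.null(window)) window <- c(1L, epochs$pre_lock_tf)
  if (window[1L] < 1L || window[2L] > nt || window[2L] < window[1L]) {
    stop("baseline window lies outside the epoch")
  }
  idx <- window[1L]:window[2L]
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - array(base, dim = c(dim(base), nt))
  epochs
}

#' Reject artifact and error trials
#'
#' Removes trials containing any sample exceeding `abs_threshold` in
#' absolute value (a deterministic amplitude criterion standing in for
#' visual artifact screening) and, when the metadata carries accuracy,
#' trials with incorrect responses.
#'
#' @param epochs An [epoch_set()].
#' @param abs_threshold Amplitude criterion in microvolts (default 100).
#' @param drop_errors Remove trials with `correct == FALSE`.
#' @return List with `epochs` (surviving trials) and `report` (counts:
#'   `artifact`, `error`, `retained`).
#' @export
reject_artifacts <- function(epochs, abs_threshold = 100, drop_errors = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"), abs_threshold > 0)
  peak <- apply(abs(epochs$data), 1L, max)
  artifact <- peak > abs_threshold
  error <- if (drop_errors && "correct" %in% names(epochs$meta)) {
    !epochs$meta$correct
  } else rep(FALSE, length(peak))
  keep <- !artifact & !error
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$meta <- epochs$meta[keep, , drop = FALSE]
  list(epochs = out,
       report = c(artifact = sum(artifact), error = sum(error & !artifact),
                  retained = sum(keep)))
}

#' Interpolate contaminated electrodes by spherical splines
#'
#' Replaces bad channels with an order-4 spherical-spline interpolation
#' (regularization 1e-5) from the good channels, per trial and time-frame.
#' At most 20% of the electrodes may be interpolated.
#'
#' @param epochs An [epoch_set()].
#' @param montage The [make_montage()] the data were recorded with.
#' @param bad Electrode labels or indices to interpolate.
#' @param max_bad_fraction Hard limit on the interpolated fraction.
#' @param m Spline order.
#' @param lambda Ridge regularization.
#' @return The [epoch_set()] with bad channels replaced.
#' @export
interpolate_bad_electrodes <- function(epochs, montage, bad,
                                       max_bad_fraction = 0.2,
                                       m = 4L, lambda = 1e-5) {
  stopifnot(inherits(epochs, "epoch_set"))
  validate_montage(montage)
  ne <- dim(epochs$data)[2L]
  if (nrow(montage$pos) != ne) stop("montage size does not match the data")
  if (is.character(bad)) bad <- match(bad, montage$labels)
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0L) return(epochs)
  if (anyNA(bad) || any(bad < 1L) || any(bad > ne)) stop("unknown bad electrodes")
  if (length(bad) / ne > max_bad_fraction) {
    stop(sprintf("%d of %d electrodes are bad (%.1f%%): the limit is %.0f%% of the montage",
                 length(bad), ne, 100 * length(bad) / ne, 100 * max_bad_fraction))
  }
  good <- setdiff(seq_len(ne), bad)
  op <- spherical_spline_operator(montage$pos, good, bad, m = m, lambda = lambda)
  nt <- dim(epochs$data)[3L]
  for (tr in seq_len(dim(epochs$data)[1L])) {
    slab <- matrix(epochs$data[tr, , ], ne, nt)
    slab[bad, ] <- op %*% slab[good, , drop = FALSE]
    # interpolation perturbs the electrode mean; restore the average
    # reference so the invariant survives this stage
    epochs$data[tr, , ] <- center_cols(slab)
  }
  epochs
}

#' Average an epoch set into a single-subject ERP
#'
#' Requires a minimum number of surviving trials (default 55); subjects
#' below the minimum are excluded with an error of class
#' `erpmicro_too_few_trials` so that callers can log the reason.
#'
#' @param epochs An [epoch_set()].
#' @param min_trials Minimum trial count.
#' @return An [erp()] with `n_trials_averaged` recorded.
#' @export
average_erp <- function(epochs, min_trials = 55L) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1L]
  if (n < min_trials) {
    stop(structure(class = c("erpmicro_too_few_trials", "error", "condition"),
                   list(message = sprintf("subject %s excluded: %d surviving trials < minimum %d",
                                          epochs$subject, n, min_trials),
                        call = sys.call(-1L))))
  }
  avg <- apply(epochs$data, c(2L, 3L), mean)
  erp(avg, fs = epochs$fs, lock = epochs$lock, pre_lock_tf = epochs$pre_lock_tf,
      n_trials = n, subject = epochs$subject, group = epochs$group,
      condition = epochs$condition)
}

#' Run the canonical preprocessing chain on an epoch set
#'
#' Applies, in this fixed order: band-pass filter, average reference,
#' baseline correction (stimulus-locked epochs only), artifact/error
#' rejection, bad-electrode interpolation. Returns the processed epochs and
#' a per-stage log.
#'
#' @param epochs An [epoch_set()].
#' @param montage A [make_montage()] object.
#' @param hp,lp Filter corners (Hz).
#' @param abs_threshold Artifact amplitude criterion (microvolts).
#' @param bad Electrodes to interpolate (labels or indices).
#' @param baseline Apply pre-lock baseline correction (forced off for
#'   response-locked epochs).
#' @return List with `epochs` and `log` (stage order and rejection report).
#' @export
preprocess_epochs <- function(epochs, montage, hp = 0.2, lp = 30,
                              abs_threshold = 100, bad = integer(0),
                              baseline = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  stages <- character(0)
  epochs <- bandpass_filter(epochs, hp = hp, lp = lp)
  stages <- c(stages, sprintf("bandpass %g-%g Hz", hp, lp))
  epochs <- rereference_average(epochs)
  stages <- c(stages, "average reference")
  if (baseline && epochs$lock == "stimulus" && epochs$pre_lock_tf > 0L) {
    epochs <- baseline_correct(epochs)
    stages <- c(stages, sprintf("baseline on %d pre-stimulus TFs", epochs$pre_lock_tf))
  }
  rej <- reject_artifacts(epochs, abs_threshold = abs_threshold)
  epochs <- rej$epochs
  stages <- c(stages, sprintf("rejection (threshold %g uV): %d artifact, %d error, %d retained",
                              abs_threshold, rej$report["artifact"],
                              rej$report["error"], rej$report["retained"]))
  if (length(bad) > 0L) {
    epochs <- interpolate_bad_electrodes(epochs, montage, bad)
    stages <- c(stages, sprintf("interpolated %d electrodes", length(bad)))
  }
  list(epochs = epochs, log = stages, rejection = rej$report)
}
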