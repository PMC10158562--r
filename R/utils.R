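# Small shared helpers.

# Round half away from zero; used for every ms -> time-frame conversion so
# that epoch windows are reproducible and drift-free.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert milliseconds to time-frames
#'
#' Milliseconds are converted to sample counts with round-half-away-from-zero,
#' applied once per quantity (never cumulatively), so that epoch geometry is
#' exactly reproducible.
#'
#' @param ms Time in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Integer number of time-frames.
#' @export
ms_to_tf <- function(ms, fs) as.integer(round_half_away(ms * fs / 1000))

#' Convert time-frames to milliseconds
#' @param tf Number of time-frames.
#' @param fs Sampling rate in Hz.
#' @return Time in milliseconds.
#' @export
tf_to_ms <- function(tf, fs) tf * 1000 / fs

# Subtract the column mean from every column (average reference of a
# electrodes x TFs matrix).
center_cols <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Run-length segments of an integer/label vector: data.frame with value,
# start, length.
label_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths)
}

# Evaluate with a temporary RNG state so that seeded operations do not
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Breadth-first connected components of an adjacency matrix.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
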