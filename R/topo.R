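# Reference-free global measures of the scalp electric field.

#' Global field power
#'
#' GFP at each time-frame is the spatial standard deviation of the
#' average-referenced map, with the 1/N (population) convention:
#' `GFP(t) = sqrt(mean(u(t)^2))` for average-referenced `u`. Maps are
#' re-centered internally, so GFP is invariant to re-referencing.
#'
#' @param x An [erp()], a matrix (electrodes x TFs) or a single map vector.
#' @return Numeric vector of GFP values (one per TF), in microvolts.
#' @export
gfp <- function(x) {
  if (is.numeric(x) && is.null(dim(x)) && !inherits(x, "erp")) {
    u <- x - mean(x)
    return(sqrt(mean(u^2)))
  }
  m <- erp_matrix(x)
  u <- center_cols(m)
  sqrt(colMeans(u^2))
}

.field_eps <- 1e-9

normalize_map <- function(u, eps = .field_eps) {
  u <- u - mean(u)
  g <- sqrt(mean(u^2))
  if (g <= eps) stop("undefined field: GFP <= eps, map cannot be normalized")
  u / g
}

#' Global map dissimilarity
#'
#' Root-mean-square difference between two GFP-normalized, average-referenced
#' maps. Ranges from 0 (identical topography) to 2 (polarity inversion) and
#' satisfies `DISS^2 = 2 * (1 - r)` with `r` the spatial correlation.
#'
#' @param u,v Numeric map vectors (same length).
#' @param eps Fields with GFP below `eps` are undefined and raise an error.
#' @return Scalar dissimilarity in `[0, 2]`.
#' @export
dissimilarity <- function(u, v, eps = .field_eps) {
  stopifnot(length(u) == length(v))
  un <- normalize_map(u, eps)
  vn <- normalize_map(v, eps)
  sqrt(mean((un - vn)^2))
}

#' Spatial correlation of two maps
#'
#' Pearson correlation across electrodes of the average-referenced maps.
#'
#' @inheritParams dissimilarity
#' @return Scalar correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(u, v, eps = .field_eps) {
  stopifnot(length(u) == length(v))
  un <- normalize_map(u, eps)
  vn <- normalize_map(v, eps)
  mean(un * vn)
}

#' Global explained variance of a template labeling
#'
#' `GEV = sum_t (GFP(t) * r_t)^2 / sum_t GFP(t)^2`, where `r_t` is the
#' spatial correlation between the map at TF `t` and its assigned template;
#' unassigned TFs contribute nothing to the numerator but keep their GFP in
#' the denominator.
#'
#' @param x An [erp()] or electrodes x TFs matrix.
#' @param templates Matrix (electrodes x k) of unit-GFP template maps, or a
#'   list of map vectors.
#' @param labels Integer vector (one per TF): template index, or `0` /
#'   `NA` for unassigned.
#' @return List with `total` GEV and `per_map` GEV (both fractions).
#' @export
gev <- function(x, templates, labels) {
  m <- center_cols(erp_matrix(x))
  if (is.list(templates)) templates <- do.call(cbind, templates)
  templates <- as.matrix(templates)
  nt <- ncol(m)
  stopifnot(length(labels) == nt)
  labels[is.na(labels)] <- 0L
  g <- sqrt(colMeans(m^2))
  den <- sum(g^2)
  if (den <= .field_eps^2) stop("undefined field: all-zero data")
  per_map <- numeric(ncol(templates))
  for (k in seq_len(ncol(templates))) {
    idx <- which(labels == k & g > .field_eps)
    if (length(idx) == 0L) next
    tn <- normalize_map(templates[, k])
    r <- colSums(m[, idx, drop = FALSE] * tn) / (nrow(m) * g[idx])
    per_map[k] <- sum((g[idx] * r)^2) / den
  }
  list(total = sum(per_map), per_map = per_map)
}

#' Topographic consistency test
#'
#' Tests, at every time-frame, whether scalp topographies are consistent
#' across subjects rather than random noise. The statistic is the GFP of the
#' across-subject mean map; the null distribution is built by independently
#' shuffling the electrode assignment within each subject and re-averaging.
#'
#' @param x Array subjects x electrodes x TFs, or a list of per-subject
#'   [erp()] objects / matrices.
#' @param n_perm Number of permutations (>= 500).
#' @param alpha Significance level for the returned mask.
#' @param seed Integer seed; makes the permutation stream reproducible.
#' @return Object of class `tct_result`: `p_series`, `gfp_observed`,
#'   `n_permutations`, `significant` mask.
#' @export
tct <- function(x, n_perm = 1000L, alpha = 0.05, seed = 1L) {
  if (is.list(x)) {
    mats <- lapply(x, erp_matrix)
    x <- array(NA_real_, c(length(mats), nrow(mats[[1L]]), ncol(mats[[1L]])))
    for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  }
  stopifnot(length(dim(x)) == 3L)
  ns <- dim(x)[1L]; ne <- dim(x)[2L]; nt <- dim(x)[3L]
  if (ns < 5L) stop("topographic consistency test requires at least 5 subjects")
  if (n_perm < 500L) stop("n_perm must be at least 500")
  # average-reference each subject map
  for (i in seq_len(ns)) x[i, , ] <- center_cols(x[i, , ])
  obs_mean <- apply(x, c(2L, 3L), mean)
  obs <- sqrt(colMeans(obs_mean^2))
  count <- integer(nt)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      acc <- matrix(0, ne, nt)
      for (i in seq_len(ns)) {
        acc <- acc + x[i, sample.int(ne), ]
      }
      null_gfp <- sqrt(colMeans(center_cols(acc / ns)^2))
      count <- count + (null_gfp >= obs)
    }
  })
  p <- (1L + count) / (n_perm + 1L)
  structure(list(p_series = p, gfp_observed = obs,
                 n_permutations = as.integer(n_perm), alpha = alpha,
                 significant = p < alpha),
            class = "tct_result")
}

#' @export
print.tct_result <- function(x, ...) {
  cat(sprintf("<tct_result> %d TFs, %d permutations, %d significant at alpha=%g\n",
              length(x$p_series), x$n_permutations, sum(x$significant), x$alpha))
  invisible(x)
}

#' P1 peak latency from global field power
#'
#' Returns the latency of the maximal GFP sample inside a time window
#' (default 80-160 ms post-stimulus). Ties resolve to the earlier TF; a
#' maximum sitting on a window edge is flagged via the `boundary` attribute.
#'
#' @param x An [erp()].
#' @param window Two-element ms interval relative to the lock event.
#' @return Peak latency in ms, with attribute `boundary` (logical).
#' @export
p1_peak_latency <- function(x, window = c(80, 160)) {
  stopifnot(inherits(x, "erp"), length(window) == 2L)
  idx <- which(x$times >= window[1L] & x$times <= window[2L])
  if (length(idx) == 0L) stop("latency window lies outside the epoch")
  g <- gfp(x)[idx]
  k <- idx[which.max(g)]   # which.max takes the first maximum: earlier TF
  lat <- x$times[k]
  attr(lat, "boundary") <- k == idx[1L] || k == idx[length(idx)]
  lat
}
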