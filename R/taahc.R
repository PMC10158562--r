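# Microstate segmentation by temporal atomize-and-agglomerate hierarchical
# clustering (TAAHC), model selection, and label post-processing.
#
# ERP convention: map-to-data correlation is signed and no polarity
# inversion is applied when labeling (unlike spontaneous-EEG microstates),
# because component-locked maps differ by more than polarity.

# Correlation of centered unit-GFP columns: crossprod / n_electrodes.
unit_corr <- function(V, C) crossprod(V, C) / nrow(V)

# GFP-weighted, polarity-aligned, unit-GFP centroid of member maps.
# V: normalized maps; w: GFP weights; members: column indices.
cluster_centroid <- function(V, w, members) {
  anchor <- members[which.max(w[members])]
  s <- sign(as.numeric(crossprod(V[, members, drop = FALSE], V[, anchor])))
  s[s == 0] <- 1
  cen <- V[, members, drop = FALSE] %*% (w[members] * s)
  cen <- cen - mean(cen)
  g <- sqrt(mean(cen^2))
  if (g <= .field_eps) {
    # degenerate cancellation; fall back to the anchor map
    return(V[, anchor])
  }
  as.numeric(cen / g)
}

# Iterative absorption of short runs. labels: integer vector (0 =
# unassigned); R: TFs x k matrix of map-to-centroid correlations;
# floor_corr: score granted to the unassigned label. Runs shorter than
# min_duration are merged into the neighboring run whose label scores the
# higher mean correlation over the run; the merge repeats until every run
# reaches min_duration (or a single run remains).
absorb_short_runs <- function(labels, R, min_duration, floor_corr = -1) {
  if (min_duration <= 1L || length(labels) == 0L) return(labels)
  repeat {
    runs <- label_runs(labels)
    if (nrow(runs) <= 1L) break
    short <- which(runs$length < min_duration)
    if (length(short) == 0L) break
    i <- short[which.min(runs$length[short])]
    idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
    score <- function(lbl) {
      if (is.na(lbl)) return(-Inf)
      if (lbl == 0L) return(floor_corr)
      mean(R[idx, lbl])
    }
    left <- if (i > 1L) runs$value[i - 1L] else NA_integer_
    right <- if (i < nrow(runs)) runs$value[i + 1L] else NA_integer_
    winner <- if (score(left) >= score(right)) left else right
    labels[idx] <- winner
  }
  labels
}

#' TAAHC microstate segmentation
#'
#' Segments a set of (grand-average) ERPs into k template maps by temporal
#' atomize-and-agglomerate hierarchical clustering. Initialization treats
#' every time-frame as its own atom; agglomeration repeatedly identifies the
#' cluster contributing the least global explained variance, dissolves it,
#' and reassigns each member map to the cluster with the highest spatial
#' correlation to its centroid. Centroids are GFP-weighted, polarity-aligned
#' mean maps, renormalized to unit GFP. For every requested k the raw
#' solution is post-processed: centroids correlating at least
#' `merge_correlation` are merged, and labeled segments shorter than
#' `min_duration_tf` are absorbed by the neighboring label with the higher
#' correlation. Segmentation is run jointly on all supplied datasets, so the
#' template set is shared across groups and conditions; label runs never
#' cross dataset boundaries.
#'
#' @param erps List of [erp()] / `combined_erp` objects or matrices
#'   (electrodes x TFs), all on the same montage.
#' @param k_range Integer vector of model sizes to report.
#' @param min_duration_tf Minimal remaining duration of a topography
#'   (default 12 TFs, about 24 ms at 512 Hz).
#' @param merge_correlation Spatial correlation above which two template
#'   maps are considered the same (default 0.95).
#' @return List of `segmentation` objects, one per k (ascending), each with
#'   `templates` (electrodes x k', unit GFP), `labels` (list per dataset;
#'   0 = unassigned), `gev_total` (after post-processing), `gev_raw`
#'   (before merging/smoothing), `requested_k`, `k` (template count after
#'   merging).
#' @export
taahc_segment <- function(erps, k_range, min_duration_tf = 12L,
                          merge_correlation = 0.95) {
  mats <- lapply(erps, function(e) center_cols(erp_matrix(e)))
  ne <- unique(vapply(mats, nrow, 0L))
  if (length(ne) != 1L) stop("all ERPs must share the montage")
  ds_len <- vapply(mats, ncol, 0L)
  X <- do.call(cbind, mats)
  Tt <- ncol(X)
  g <- sqrt(colMeans(X^2))
  keep <- g > .field_eps
  Vk <- sweep(X[, keep, drop = FALSE], 2L, g[keep], "/")
  w <- g[keep]
  n_atoms <- ncol(Vk)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1L) stop("k_range must be positive")
  if (max(k_range) > n_atoms) {
    stop(sprintf("k = %d exceeds the number of atoms (%d)", max(k_range), n_atoms))
  }

  # --- agglomeration ------------------------------------------------------
  assign_v <- seq_len(n_atoms)
  members <- as.list(seq_len(n_atoms))
  cents <- Vk
  r <- rep(1, n_atoms)
  contrib <- (w * r)^2
  active <- rep(TRUE, n_atoms)
  n_active <- n_atoms
  den <- sum(g^2)
  snapshots <- list()

  update_cluster <- function(k) {
    M <- members[[k]]
    cen <- cluster_centroid(Vk, w, M)
    cents[, k] <<- cen
    rr <- as.numeric(crossprod(Vk[, M, drop = FALSE], cen)) / ne
    r[M] <<- rr
    contrib[k] <<- sum((w[M] * rr)^2)
  }

  repeat {
    if (n_active %in% k_range) {
      act <- which(active)
      snapshots[[as.character(n_active)]] <-
        list(assign = assign_v, clusters = act,
             cents = cents[, act, drop = FALSE],
             gev_raw = sum((w * r)^2) / den)
    }
    if (n_active <= min(k_range)) break
    worst <- which(active)[which.min(contrib[active])]
    m <- members[[worst]]
    active[worst] <- FALSE
    n_active <- n_active - 1L
    rem <- which(active)
    cr <- unit_corr(Vk[, m, drop = FALSE], cents[, rem, drop = FALSE])
    best <- rem[max.col(cr, ties.method = "first")]
    assign_v[m] <- best
    for (k in unique(best)) {
      members[[k]] <- c(members[[k]], m[best == k])
      update_cluster(k)
    }
    members[[worst]] <- integer(0)
  }

  # --- post-processing per requested k ------------------------------------
  ds_id <- rep(seq_along(mats), ds_len)
  Vfull <- matrix(0, ne, Tt)
  Vfull[, keep] <- Vk

  # Convergence polish of a k-cluster solution: alternate reassignment to
  # the highest-correlating centroid with centroid recomputation until the
  # labeling is stable. Returns the refined labeling and centroids.
  polish <- function(cl_of, cents_k, max_iter = 50L) {
    for (it in seq_len(max_iter)) {
      cr <- unit_corr(Vk, cents_k)
      new_cl <- max.col(cr, ties.method = "first")
      # keep every cluster alive: a cluster losing all members retains its
      # best-correlated map
      for (k in seq_len(ncol(cents_k))) {
        if (!any(new_cl == k)) new_cl[which.max(cr[, k])] <- k
      }
      if (all(new_cl == cl_of)) break
      cl_of <- new_cl
      for (k in seq_len(ncol(cents_k))) {
        cents_k[, k] <- cluster_centroid(Vk, w, which(cl_of == k))
      }
    }
    list(cl_of = cl_of, cents = cents_k)
  }

  out <- lapply(k_range, function(kk) {
    sn <- snapshots[[as.character(kk)]]
    cl_of <- match(sn$assign, sn$clusters)     # per kept TF, 1..kk
    pol <- polish(cl_of, sn$cents)
    cl_of <- pol$cl_of
    cents_k <- pol$cents
    r_pol <- vapply(seq_len(n_atoms), function(t) {
      sum(Vk[, t] * cents_k[, cl_of[t]]) / ne
    }, 0)
    gev_raw <- sum((w * r_pol)^2) / den
    memb <- split(seq_len(n_atoms), cl_of)
    # merge near-identical centroids
    repeat {
      if (ncol(cents_k) <= 1L) break
      cc <- unit_corr(cents_k, cents_k)
      diag(cc) <- -Inf
      mx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      if (cc[mx[1L], mx[2L]] < merge_correlation) break
      i <- min(mx); j <- max(mx)
      memb[[i]] <- c(memb[[i]], memb[[j]])
      memb[[j]] <- NULL
      cents_k <- cents_k[, -j, drop = FALSE]
      cents_k[, i] <- cluster_centroid(Vk, w, memb[[i]])
    }
    k_final <- ncol(cents_k)
    lab_kept <- integer(n_atoms)
    for (i in seq_len(k_final)) lab_kept[memb[[i]]] <- i
    labels_full <- integer(Tt)
    labels_full[keep] <- lab_kept
    # temporal smoothing within each dataset
    R <- unit_corr(Vfull, cents_k)
    for (d in seq_along(mats)) {
      idx <- which(ds_id == d)
      labels_full[idx] <- absorb_short_runs(labels_full[idx],
                                            R[idx, , drop = FALSE],
                                            min_duration_tf)
    }
    # order templates by first appearance and letter them
    first_seen <- vapply(seq_len(k_final), function(i) {
      h <- which(labels_full == i)
      if (length(h) == 0L) Tt + i else h[1L]
    }, 0)
    ord <- order(first_seen)
    relab <- match(labels_full, ord)
    relab[is.na(relab)] <- 0L
    labels_full <- relab
    cents_k <- cents_k[, ord, drop = FALSE]
    colnames(cents_k) <- make.unique(LETTERS[(seq_len(k_final) - 1L) %% 26L + 1L])
    # total GEV of the final labeling
    rr <- numeric(Tt)
    for (i in seq_len(k_final)) {
      idx <- which(labels_full == i & keep)
      if (length(idx) > 0L) {
        rr[idx] <- as.numeric(crossprod(Vfull[, idx, drop = FALSE], cents_k[, i])) / ne
      }
    }
    gev_total <- sum((g * rr)^2) / den
    structure(list(templates = cents_k,
                   labels = split(labels_full, ds_id),
                   gev_total = gev_total, gev_raw = gev_raw,
                   requested_k = kk, k = k_final,
                   min_duration_tf = as.integer(min_duration_tf),
                   merge_correlation = merge_correlation),
              class = "segmentation")
  })
  out
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> k = %d (requested %d), GEV = %.3f (raw %.3f), %d datasets\n",
              x$k, x$requested_k, x$gev_total, x$gev_raw, length(x$labels)))
  invisible(x)
}

#' Select the segmentation model by explained variance
#'
#' Returns the segmentation with the smallest k whose total GEV reaches
#' `gev_threshold` (default 0.95). If no k reaches the threshold, the max-k
#' segmentation is returned with a warning. The full GEV-vs-k curve is
#' attached as attribute `gev_curve`.
#'
#' @param segmentations List of [taahc_segment()] results, ascending in k.
#' @param gev_threshold Required fraction of explained variance.
#' @return A single `segmentation`.
#' @export
select_model <- function(segmentations, gev_threshold = 0.95) {
  ks <- vapply(segmentations, function(s) s$requested_k, 0L)
  stopifnot(!is.unsorted(ks))
  gevs <- vapply(segmentations, function(s) s$gev_total, 0)
  curve <- data.frame(k = ks, gev = gevs)
  hit <- which(gevs >= gev_threshold)
  if (length(hit) == 0L) {
    warning(sprintf("no model reaches GEV >= %g (max %.3f at k = %d); returning the largest model",
                    gev_threshold, max(gevs), ks[length(ks)]))
    sel <- segmentations[[length(segmentations)]]
  } else {
    sel <- segmentations[[hit[1L]]]
  }
  attr(sel, "gev_curve") <- curve
  sel
}

#' Back-fit template maps to an individual ERP
#'
#' Labels every time-frame of a window with the candidate template of
#' highest (signed) spatial correlation, provided the correlation reaches
#' `min_correlation`; TFs below the floor, or with an undefined field,
#' remain unassigned. Ties resolve to the previous TF's label (temporal
#' continuity), else to the lowest template index. Runs shorter than
#' `min_duration_tf` are absorbed as in segmentation. A map is "present"
#' when its total assigned duration reaches `min_presence_tf`. Per-map GEV
#' is computed within the window.
#'
#' @param x An [erp()], `combined_erp` or matrix.
#' @param templates Electrodes x k matrix of unit-GFP template maps with
#'   column names.
#' @param window Integer TF interval `c(first, last)` (1-based within `x`),
#'   or `NULL` for the whole signal.
#' @param candidates Template column names competing in this window
#'   (default: all).
#' @param min_presence_tf Presence criterion (default 12 TFs).
#' @param min_duration_tf Smoothing criterion (default 12 TFs).
#' @param min_correlation Assignment floor on the map-to-template
#'   correlation.
#' @param fs Sampling rate, taken from `x` when available.
#' @return Object of class `fitting_result`: a data frame with one row per
#'   candidate map (`map`, `presence`, `gev`, `duration_tf`, `duration_ms`,
#'   `onset_tf`, `onset_ms` relative to the window start) and the per-TF
#'   `labels` as an attribute.
#' @export
fit_templates <- function(x, templates, window = NULL, candidates = NULL,
                          min_presence_tf = 12L, min_duration_tf = 12L,
                          min_correlation = 0.5, fs = NULL) {
  m <- erp_matrix(x)
  if (is.null(fs)) fs <- if (is.list(x) && !is.null(x$fs)) x$fs else 512
  templates <- as.matrix(templates)
  if (is.null(colnames(templates))) {
    colnames(templates) <- LETTERS[seq_len(ncol(templates))]
  }
  if (is.null(candidates)) candidates <- colnames(templates)
  if (length(candidates) == 0L) stop("empty candidate template list")
  if (!all(candidates %in% colnames(templates))) stop("unknown candidate maps")
  if (is.null(window)) window <- c(1L, ncol(m))
  if (window[1L] < 1L || window[2L] > ncol(m) || window[2L] < window[1L]) {
    stop("fitting window lies outside the ERP")
  }
  cand <- templates[, candidates, drop = FALSE]
  cand <- apply(cand, 2L, normalize_map)
  idx <- window[1L]:window[2L]
  mm <- center_cols(m[, idx, drop = FALSE])
  g <- sqrt(colMeans(mm^2))
  ok <- g > .field_eps
  Vn <- mm
  Vn[, ok] <- sweep(mm[, ok, drop = FALSE], 2L, g[ok], "/")
  Vn[, !ok] <- 0
  R <- unit_corr(Vn, cand)                 # TFs x k
  nw <- length(idx)
  labels <- integer(nw)
  prev <- 0L
  for (t in seq_len(nw)) {
    if (!ok[t]) { prev <- 0L; next }
    rt <- R[t, ]
    top <- max(rt)
    if (top < min_correlation) { prev <- 0L; next }
    ties <- which(rt >= top - 1e-12)
    labels[t] <- if (prev %in% ties) prev else ties[1L]
    prev <- labels[t]
  }
  labels <- absorb_short_runs(labels, R, min_duration_tf,
                              floor_corr = min_correlation)
  den <- sum(g^2)
  res <- lapply(seq_along(candidates), function(k) {
    at <- which(labels == k)
    dur <- length(at)
    gev_k <- if (dur > 0L && den > 0) sum((g[at] * R[at, k])^2) / den else 0
    data.frame(map = candidates[k],
               presence = dur >= min_presence_tf,
               gev = gev_k,
               duration_tf = dur,
               duration_ms = dur * 1000 / fs,
               onset_tf = if (dur > 0L) at[1L] else NA_integer_,
               onset_ms = if (dur > 0L) (at[1L] - 1L) * 1000 / fs else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "labels") <- labels
  attr(out, "window") <- window
  class(out) <- c("fitting_result", class(out))
  out
}

#' Group and condition statistics on back-fitting results
#'
#' For every fitted window and map, runs the split-plot ANOVA (group
#' between-subject, condition within-subject) on GEV and on duration,
#' tabulates presence per group and condition, and optionally correlates
#' per-subject GEV with a covariate such as age.
#'
#' @param fits Data frame binding [fit_templates()] rows across subjects,
#'   with added columns `subject`, `group`, `condition`, `window`.
#' @param covariate Optional named numeric vector (by subject) correlated
#'   with per-subject mean GEV of every map.
#' @return List with `stats` (F/p per window x map x measure x effect),
#'   `presence` (counts per window x map x group x condition) and
#'   `covariate` (correlation per window x map, or `NULL`).
#' @export
compare_fitting <- function(fits, covariate = NULL) {
  need <- c("subject", "group", "condition", "window", "map", "gev",
            "duration_ms", "presence")
  stopifnot(all(need %in% names(fits)))
  subjects <- unique(fits$subject)
  conds <- sort(unique(fits$condition))
  S <- length(subjects); C <- length(conds)
  stats_rows <- list()
  pres_rows <- list()
  cov_rows <- list()
  for (wk in unique(fits$window)) {
    fw <- fits[fits$window == wk, , drop = FALSE]
    for (mp in unique(fw$map)) {
      fm <- fw[fw$map == mp, , drop = FALSE]
      y_gev <- array(NA_real_, c(S, C, 1L))
      y_dur <- array(NA_real_, c(S, C, 1L))
      grp <- character(S)
      for (i in seq_len(S)) for (j in seq_len(C)) {
        r <- which(fm$subject == subjects[i] & fm$condition == conds[j])
        if (length(r) != 1L) {
          stop(sprintf("degenerate cell: subject %s, condition %s, map %s (window %s) has %d rows",
                       subjects[i], conds[j], mp, wk, length(r)))
        }
        y_gev[i, j, 1L] <- fm$gev[r]
        y_dur[i, j, 1L] <- fm$duration_ms[r]
        grp[i] <- fm$group[r]
      }
      for (meas in c("gev", "duration")) {
        y <- if (meas == "gev") y_gev else y_dur
        an <- splitplot_anova(y, grp)
        for (eff in names(an)) {
          stats_rows[[length(stats_rows) + 1L]] <-
            data.frame(window = wk, map = mp, measure = meas, effect = eff,
                       F = an[[eff]]$F, p = an[[eff]]$p,
                       df1 = an[[eff]]$df[1L], df2 = an[[eff]]$df[2L],
                       stringsAsFactors = FALSE)
        }
      }
      pr <- stats::aggregate(presence ~ group + condition, data = fm, FUN = sum)
      pr$window <- wk; pr$map <- mp
      pres_rows[[length(pres_rows) + 1L]] <- pr
      if (!is.null(covariate)) {
        mg <- stats::aggregate(gev ~ subject, data = fm, FUN = mean)
        cv <- covariate[as.character(mg$subject)]
        ct <- stats::cor.test(mg$gev, cv)
        cov_rows[[length(cov_rows) + 1L]] <-
          data.frame(window = wk, map = mp, r = unname(ct$estimate),
                     p = ct$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  list(stats = do.call(rbind, stats_rows),
       presence = do.call(rbind, pres_rows),
       covariate = if (length(cov_rows)) do.call(rbind, cov_rows) else NULL)
}
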