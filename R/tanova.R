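# Topographic analysis of variance: per-TF nonparametric randomization test
# of map differences (group, condition, interaction) on GFP-normalized maps.

# Normalize every (subject, condition) map per TF: average reference then
# division by GFP. Returns list(norm = S x C x E x T array, bad = S x C x T
# logical of undefined fields).
normalize_subject_maps <- function(x, eps = .field_eps) {
  S <- dim(x)[1L]; C <- dim(x)[2L]; E <- dim(x)[3L]; Tn <- dim(x)[4L]
  bad <- array(FALSE, c(S, C, Tn))
  for (s in seq_len(S)) for (c in seq_len(C)) {
    m <- center_cols(matrix(x[s, c, , ], E, Tn))
    g <- sqrt(colMeans(m^2))
    b <- g <= eps
    g[b] <- 1
    x[s, c, , ] <- sweep(m, 2L, g, "/")
    bad[s, c, ] <- b
  }
  list(norm = x, bad = bad)
}

# Generalized dissimilarity of level-mean maps to the grand mean, per TF.
# lv: list of level-mean matrices (E x T); gn: normalized grand mean.
gen_dissimilarity <- function(lv, gn, eps = .field_eps) {
  d <- 0
  for (U in lv) {
    g <- sqrt(colMeans(U^2))
    g[g <= eps] <- NA_real_
    Un <- sweep(U, 2L, g, "/")
    d <- d + sqrt(colMeans((Un - gn)^2))
  }
  d / length(lv)
}

#' Topographic ANOVA by randomization
#'
#' At every time-frame, subject maps are GFP-normalized and the effect size
#' is the generalized dissimilarity: the mean, across factor levels, of the
#' global dissimilarity between the level-mean map and the grand-mean map.
#' Significance is assessed by randomization: subject-to-group reassignment
#' for the group effect, within-subject condition swaps for the condition
#' effect, and within-subject condition swaps evaluated on double-centered
#' cell means (both main effects removed) for the interaction. The observed
#' data count as one permutation, so p >= 1/(n_perm + 1).
#'
#' @param x Array subjects x conditions x electrodes x TFs, or a
#'   [stack_erps()] result.
#' @param group Factor per subject (ignored for a [stack_erps()] input).
#' @param n_perm Number of random permutations (>= 1000; default 5000).
#' @param alpha Significance level used for the consecutive-TF mask.
#' @param min_consec_tf Consecutive-significance criterion (default 12 TFs).
#' @param seed Integer seed; the stored seed reproduces p-values exactly.
#' @param effects Which effects to test.
#' @return Object of class `tanova_result`: per effect, `p_series`,
#'   `effect_size`, `mask` (after the consecutive criterion) and
#'   `untestable` (TFs with undefined fields, excluded from masks).
#' @export
tanova <- function(x, group = NULL, n_perm = 5000L, alpha = 0.01,
                   min_consec_tf = 12L, seed = 1L,
                   effects = c("group", "condition", "interaction")) {
  if (is.list(x) && !is.null(x$x)) {
    group <- x$group
    x <- x$x
  }
  stopifnot(length(dim(x)) == 4L, !is.null(group))
  if (n_perm < 1000L) stop("n_perm must be at least 1000")
  S <- dim(x)[1L]; C <- dim(x)[2L]; E <- dim(x)[3L]; Tn <- dim(x)[4L]
  group <- factor(group)
  if (any(table(group) < 2L)) stop("every group level needs at least 2 subjects")
  effects <- match.arg(effects, several.ok = TRUE)
  if (C < 2L) effects <- setdiff(effects, c("condition", "interaction"))
  gi <- as.integer(group)
  a <- nlevels(group)

  nm <- normalize_subject_maps(x)
  Xn <- nm$norm
  out <- list()

  with_seed(seed, {
    if ("group" %in% effects) {
      # condition-averaged, renormalized subject maps
      Xs <- array(0, c(S, E, Tn))
      for (c in seq_len(C)) Xs <- Xs + Xn[, c, , ]
      Xs <- Xs / C
      M <- matrix(Xs, S, E * Tn)
      grand <- matrix(colMeans(M), E, Tn)
      ggfp <- sqrt(colMeans(grand^2))
      untestable <- ggfp <= .field_eps | apply(nm$bad, 3L, any)
      ggfp[untestable] <- 1
      gn <- sweep(grand, 2L, ggfp, "/")
      level_means <- function(idx_gi) {
        lapply(seq_len(a), function(l) {
          matrix(colMeans(M[idx_gi == l, , drop = FALSE]), E, Tn)
        })
      }
      obs_lv <- level_means(gi)
      lv_gfp_bad <- Reduce(`|`, lapply(obs_lv, function(U) {
        sqrt(colMeans(U^2)) <= .field_eps
      }))
      untestable <- untestable | lv_gfp_bad
      obs <- gen_dissimilarity(obs_lv, gn)
      count <- integer(Tn)
      for (b in seq_len(n_perm)) {
        d <- gen_dissimilarity(level_means(gi[sample.int(S)]), gn)
        count <- count + (!is.na(d) & !is.na(obs) & d >= obs - 1e-12)
      }
      p <- (1L + count) / (n_perm + 1L)
      p[untestable] <- NA_real_
      out$group <- list(p_series = p, effect_size = obs,
                        untestable = untestable)
    }

    if ("condition" %in% effects) {
      Mc <- lapply(seq_len(C), function(c) matrix(Xn[, c, , ], S, E * Tn))
      grand <- matrix(Reduce(`+`, lapply(Mc, colMeans)) / C, E, Tn)
      ggfp <- sqrt(colMeans(grand^2))
      untestable <- ggfp <= .field_eps | apply(nm$bad, 3L, any)
      ggfp[untestable] <- 1
      gn <- sweep(grand, 2L, ggfp, "/")
      cond_stat <- function(assign_mat) {
        # assign_mat: S x C matrix; row s holds the permuted condition of
        # subject s's c-th map
        lv <- lapply(seq_len(C), function(c) {
          acc <- numeric(E * Tn)
          for (cc in seq_len(C)) {
            rows <- which(assign_mat[, cc] == c)
            if (length(rows) > 0L) acc <- acc + colSums(Mc[[cc]][rows, , drop = FALSE])
          }
          matrix(acc / S, E, Tn)
        })
        gen_dissimilarity(lv, gn)
      }
      id <- matrix(rep(seq_len(C), each = S), S, C)
      obs <- cond_stat(id)
      untestable <- untestable | is.na(obs)
      count <- integer(Tn)
      for (b in seq_len(n_perm)) {
        perm <- t(apply(matrix(seq_len(C), C, S), 2L, sample))
        d <- cond_stat(perm)
        count <- count + (!is.na(d) & !is.na(obs) & d >= obs - 1e-12)
      }
      p <- (1L + count) / (n_perm + 1L)
      p[untestable] <- NA_real_
      out$condition <- list(p_series = p, effect_size = obs,
                            untestable = untestable)
    }

    if ("interaction" %in% effects) {
      Mc <- lapply(seq_len(C), function(c) matrix(Xn[, c, , ], S, E * Tn))
      inter_stat <- function(assign_mat) {
        # cell means under the permuted condition assignment
        cell <- array(0, c(a, C, E * Tn))
        for (cc in seq_len(C)) {
          for (c in seq_len(C)) {
            rows <- which(assign_mat[, cc] == c)
            if (length(rows) == 0L) next
            sums <- rowsum(Mc[[cc]][rows, , drop = FALSE], gi[rows])
            lv <- sort(unique(gi[rows]))
            cell[lv, c, ] <- cell[lv, c, ] + sums
          }
        }
        ngc <- as.vector(table(gi))       # subjects per group (per condition)
        for (g in seq_len(a)) cell[g, , ] <- cell[g, , ] / ngc[g]
        mg <- matrix(0, a, E * Tn)                    # a x ET
        for (c in seq_len(C)) mg <- mg + matrix(cell[, c, ], a, E * Tn)
        mg <- mg / C
        mc <- matrix(0, C, E * Tn)                    # C x ET (unweighted)
        for (g in seq_len(a)) mc <- mc + matrix(cell[g, , ], C, E * Tn)
        mc <- mc / a
        mu <- colMeans(mg)
        d <- 0
        for (g in seq_len(a)) for (c in seq_len(C)) {
          resid <- matrix(cell[g, c, ] - mg[g, ] - mc[c, ] + mu, E, Tn)
          d <- d + sqrt(colMeans(resid^2))
        }
        d / (a * C)
      }
      id <- matrix(rep(seq_len(C), each = S), S, C)
      obs <- inter_stat(id)
      untestable <- apply(nm$bad, 3L, any)
      count <- integer(Tn)
      for (b in seq_len(n_perm)) {
        perm <- t(apply(matrix(seq_len(C), C, S), 2L, sample))
        d <- inter_stat(perm)
        count <- count + (d >= obs - 1e-12)
      }
      p <- (1L + count) / (n_perm + 1L)
      p[untestable] <- NA_real_
      out$interaction <- list(p_series = p, effect_size = obs,
                              untestable = untestable)
    }
  })

  for (eff in names(out)) {
    out[[eff]]$mask <- consecutive_criterion(out[[eff]]$p_series,
                                             alpha = alpha,
                                             min_consec_tf = min_consec_tf)
  }
  structure(list(effects = out, n_permutations = as.integer(n_perm),
                 alpha = alpha, min_consec_tf = as.integer(min_consec_tf),
                 seed = as.integer(seed)),
            class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("<tanova_result> %d permutations, alpha %g, %d-TF criterion\n",
              x$n_permutations, x$alpha, x$min_consec_tf))
  for (eff in names(x$effects)) {
    cat(sprintf("  %s: %d/%d TFs significant after criterion\n", eff,
                sum(x$effects[[eff]]$mask),
                length(x$effects[[eff]]$p_series)))
  }
  invisible(x)
}

#' Consecutive-significance criterion
#'
#' Retains time-frames lying inside a run of at least `min_consec_tf`
#' consecutive TFs with `p < alpha` (defaults: 12 TFs, about 24 ms at
#' 512 Hz, at alpha 0.01). `NA` p-values (untestable TFs) break runs and are
#' never retained.
#'
#' @param p_series Per-TF p-values.
#' @param alpha Significance level.
#' @param min_consec_tf Minimal run length.
#' @return Logical mask, one value per TF.
#' @export
consecutive_criterion <- function(p_series, alpha = 0.01, min_consec_tf = 12L) {
  sig <- !is.na(p_series) & p_series < alpha
  runs <- label_runs(sig)
  mask <- logical(length(p_series))
  for (k in which(runs$value & runs$length >= min_consec_tf)) {
    mask[runs$start[k] + seq_len(runs$length[k]) - 1L] <- TRUE
  }
  mask
}
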