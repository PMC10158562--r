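# Sampling-point-wise factorial ANOVA on ERP amplitudes with temporal and
# spatial extent significance criteria.

# Closed-form split-plot (mixed) ANOVA, vectorized over measurement points.
# y: subjects x conditions x points array; group: factor per subject.
# Group is a between-subject factor (error: subjects within groups);
# condition is within-subject (error: condition x subject within groups).
splitplot_anova <- function(y, group) {
  stopifnot(length(dim(y)) == 3L)
  S <- dim(y)[1L]; C <- dim(y)[2L]; P <- dim(y)[3L]
  group <- factor(group)
  a <- nlevels(group)
  if (a < 2L) stop("at least two groups are required")
  ng <- as.vector(table(group))
  if (any(ng < 2L)) stop("every group needs at least 2 subjects")
  gi <- as.integer(group)

  # F with explicit conventions for degenerate data: zero effect and zero
  # error give F = 0 (p = 1); positive effect over zero error gives Inf.
  safe_F <- function(ssn, dfn, ssd, dfd) {
    ifelse(ssd <= 0, ifelse(ssn <= 1e-24, 0, Inf), (ssn / dfn) / (ssd / dfd))
  }

  Ms <- matrix(0, S, P)                      # subject means over conditions
  for (c in seq_len(C)) Ms <- Ms + matrix(y[, c, ], S, P)
  Ms <- Ms / C
  Mg <- rowsum(Ms, gi) / ng                  # a x P
  Mu <- colMeans(Ms)                         # grand mean per point
  SSg <- colSums(C * ng * (sweep(Mg, 2L, Mu))^2)
  SSsw <- C * colSums((Ms - Mg[gi, , drop = FALSE])^2)
  df_g <- a - 1L
  df_sw <- S - a
  F_g <- safe_F(SSg, df_g, SSsw, df_sw)
  out <- list(group = list(F = F_g,
                           p = stats::pf(F_g, df_g, df_sw, lower.tail = FALSE),
                           df = c(df_g, df_sw)))
  if (C >= 2L) {
    Mc <- matrix(0, C, P)
    for (c in seq_len(C)) Mc[c, ] <- colMeans(matrix(y[, c, ], S, P))
    SSc <- colSums(S * (sweep(Mc, 2L, Mu))^2)
    SSi <- numeric(P)
    SSe <- numeric(P)
    for (c in seq_len(C)) {
      yc <- matrix(y[, c, ], S, P)
      Mgc <- rowsum(yc, gi) / ng                         # a x P
      cellint <- Mgc - Mg - matrix(Mc[c, ], a, P, byrow = TRUE) +
        matrix(Mu, a, P, byrow = TRUE)
      SSi <- SSi + colSums(ng * cellint^2)
      resid <- yc - Ms - (Mgc - Mg)[gi, , drop = FALSE]
      SSe <- SSe + colSums(resid^2)
    }
    df_c <- C - 1L
    df_i <- (a - 1L) * (C - 1L)
    df_e <- (S - a) * (C - 1L)
    F_c <- safe_F(SSc, df_c, SSe, df_e)
    F_i <- safe_F(SSi, df_i, SSe, df_e)
    out$condition <- list(F = F_c,
                          p = stats::pf(F_c, df_c, df_e, lower.tail = FALSE),
                          df = c(df_c, df_e))
    out$interaction <- list(F = F_i,
                            p = stats::pf(F_i, df_i, df_e, lower.tail = FALSE),
                            df = c(df_i, df_e))
  }
  out
}

#' Point-wise factorial ANOVA on ERP amplitudes
#'
#' Runs, at every electrode and time-frame, a two-way mixed ANOVA with
#' group as between-subject factor and condition as within-subject
#' (repeated-measures) factor, returning F and p maps for the group effect,
#' the condition effect and their interaction.
#'
#' @param x Array subjects x conditions x electrodes x TFs (e.g. from
#'   [stack_erps()]), or the list returned by [stack_erps()].
#' @param group Factor of group membership per subject (ignored when `x`
#'   is a [stack_erps()] result).
#' @return Object of class `pointwise_stat_map`: per effect, `F` and `p`
#'   matrices (electrodes x TFs) and the degrees of freedom.
#' @export
pointwise_anova <- function(x, group = NULL) {
  if (is.list(x) && !is.null(x$x)) {
    group <- x$group
    x <- x$x
  }
  stopifnot(length(dim(x)) == 4L, !is.null(group))
  S <- dim(x)[1L]; C <- dim(x)[2L]; E <- dim(x)[3L]; Tn <- dim(x)[4L]
  if (anyNA(x)) stop("missing cells in the subject x condition design")
  y <- array(x, c(S, C, E * Tn))
  res <- splitplot_anova(y, group)
  for (eff in names(res)) {
    res[[eff]]$F <- matrix(res[[eff]]$F, E, Tn)
    res[[eff]]$p <- matrix(res[[eff]]$p, E, Tn)
  }
  structure(list(effects = res, n_electrodes = E, n_tf = Tn),
            class = "pointwise_stat_map")
}

#' @export
print.pointwise_stat_map <- function(x, ...) {
  cat(sprintf("<pointwise_stat_map> %d electrodes x %d TFs; effects: %s\n",
              x$n_electrodes, x$n_tf, paste(names(x$effects), collapse = ", ")))
  invisible(x)
}

# Core extent-criterion mask on one p matrix (electrodes x TFs): a point
# survives iff it lies in a run of >= min_consec_tf consecutive TFs that are
# supra-threshold at its electrode AND belong, at each TF of the run, to a
# connected set (montage adjacency) of >= min_adjacent supra-threshold
# electrodes.
extent_mask_matrix <- function(p, adjacency, min_consec_tf = 10L,
                               min_adjacent = 5L, alpha = 0.01) {
  stopifnot(nrow(p) == nrow(adjacency))
  supra <- p < alpha
  spatial_ok <- matrix(FALSE, nrow(p), ncol(p))
  for (t in seq_len(ncol(p))) {
    el <- which(supra[, t])
    if (length(el) == 0L) next
    if (length(el) < min_adjacent) next
    comp <- graph_components(adjacency[el, el, drop = FALSE])
    sizes <- tabulate(comp)
    spatial_ok[el[sizes[comp] >= min_adjacent], t] <- TRUE
  }
  combined <- supra & spatial_ok
  mask <- matrix(FALSE, nrow(p), ncol(p))
  for (e in seq_len(nrow(p))) {
    runs <- label_runs(combined[e, ])
    keep <- runs$value & runs$length >= min_consec_tf
    for (k in which(keep)) {
      mask[e, runs$start[k] + seq_len(runs$length[k]) - 1L] <- TRUE
    }
  }
  mask
}

#' Apply temporal and spatial extent criteria to point-wise p maps
#'
#' Keeps only effects lasting at least `min_consec_tf` consecutive TFs on a
#' connected set of at least `min_adjacent` electrodes at `p < alpha`
#' (defaults 10 TFs, 5 electrodes, alpha 0.01). No further multiple-testing
#' correction is applied.
#'
#' @param stat A [pointwise_anova()] result.
#' @param montage The [make_montage()] whose adjacency defines
#'   "adjacent electrodes".
#' @param min_consec_tf Temporal criterion (consecutive TFs).
#' @param min_adjacent Spatial criterion (connected supra-threshold
#'   electrodes).
#' @param alpha Significance level.
#' @return The `pointwise_stat_map` with a `mask` added to every effect and
#'   the criteria recorded.
#' @export
extent_threshold <- function(stat, montage, min_consec_tf = 10L,
                             min_adjacent = 5L, alpha = 0.01) {
  stopifnot(inherits(stat, "pointwise_stat_map"))
  validate_montage(montage)
  if (nrow(montage$adjacency) != stat$n_electrodes) {
    stop("montage adjacency does not cover the electrodes present in the data")
  }
  for (eff in names(stat$effects)) {
    stat$effects[[eff]]$mask <- extent_mask_matrix(stat$effects[[eff]]$p,
                                                   montage$adjacency,
                                                   min_consec_tf, min_adjacent,
                                                   alpha)
  }
  stat$criteria <- c(min_consec_tf = min_consec_tf,
                     min_adjacent = min_adjacent, alpha = alpha)
  stat
}
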