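# End-to-end orchestration: synthetic data -> preprocessing -> alignment ->
# topographic consistency -> waveform ANOVA -> tANOVA -> segmentation ->
# back-fitting -> statistics, with on-disk artifacts and a manifest.

#' Build a pipeline configuration
#'
#' Centralizes every analysis parameter with the canonical defaults:
#' 0.2-30 Hz filtering, 100 microvolt artifact criterion, minimum 55 trials
#' per average, 500-2000 ms RT bounds, waveform-ANOVA extent criteria of 10
#' consecutive TFs on 5 adjacent electrodes at alpha 0.01, a 12-TF
#' consecutive criterion for the tANOVA at alpha 0.01, and segmentation with
#' a 12-TF minimum duration at 95% merge correlation selecting the smallest
#' model with 95% explained variance.
#'
#' @param design A [synthetic_design()] describing the data source; its seed
#'   is overridden by `seed`.
#' @param seed Integer seed for the whole run.
#' @param hp,lp Band-pass corners (Hz).
#' @param abs_threshold Artifact amplitude criterion (microvolts).
#' @param min_trials Minimum surviving trials per subject average.
#' @param bad_electrodes Electrode labels interpolated for every subject.
#' @param rt_lo,rt_hi RT outlier bounds (ms).
#' @param anova_alpha,anova_min_consec_tf,anova_min_adjacent Waveform-ANOVA
#'   significance and extent criteria.
#' @param tanova_alpha,tanova_min_consec_tf,tanova_n_perm Topographic ANOVA
#'   parameters.
#' @param tct_n_perm,tct_alpha Topographic consistency test parameters.
#' @param k_range,min_duration_tf,merge_correlation,gev_threshold
#'   Segmentation and model-selection parameters.
#' @param fit_min_presence_tf,fit_min_correlation Back-fitting parameters.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = synthetic_design(),
                            seed = 1L,
                            hp = 0.2, lp = 30,
                            abs_threshold = 100,
                            min_trials = 55L,
                            bad_electrodes = character(0),
                            rt_lo = 500, rt_hi = 2000,
                            anova_alpha = 0.01,
                            anova_min_consec_tf = 10L,
                            anova_min_adjacent = 5L,
                            tanova_alpha = 0.01,
                            tanova_min_consec_tf = 12L,
                            tanova_n_perm = 5000L,
                            tct_n_perm = 1000L,
                            tct_alpha = 0.05,
                            k_range = 2:12,
                            min_duration_tf = 12L,
                            merge_correlation = 0.95,
                            gev_threshold = 0.95,
                            fit_min_presence_tf = 12L,
                            fit_min_correlation = 0.5) {
  design$seed <- as.integer(seed)
  structure(list(design = design, seed = as.integer(seed), hp = hp, lp = lp,
                 abs_threshold = abs_threshold,
                 min_trials = as.integer(min_trials),
                 bad_electrodes = bad_electrodes,
                 rt_lo = rt_lo, rt_hi = rt_hi,
                 anova_alpha = anova_alpha,
                 anova_min_consec_tf = as.integer(anova_min_consec_tf),
                 anova_min_adjacent = as.integer(anova_min_adjacent),
                 tanova_alpha = tanova_alpha,
                 tanova_min_consec_tf = as.integer(tanova_min_consec_tf),
                 tanova_n_perm = as.integer(tanova_n_perm),
                 tct_n_perm = as.integer(tct_n_perm), tct_alpha = tct_alpha,
                 k_range = as.integer(k_range),
                 min_duration_tf = as.integer(min_duration_tf),
                 merge_correlation = merge_correlation,
                 gev_threshold = gev_threshold,
                 fit_min_presence_tf = as.integer(fit_min_presence_tf),
                 fit_min_correlation = fit_min_correlation),
            class = "pipeline_config")
}

#' Demonstration configuration
#'
#' A scaled-down configuration (4 groups x 5 subjects x 2 conditions, 32
#' electrodes, 512 Hz, 30 trials per condition) that exercises every stage
#' of the pipeline in a few minutes on one CPU.
#'
#' @param seed Integer seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    design = synthetic_design(n_subjects_per_group = 5L,
                              n_trials_per_condition = 30L,
                              n_electrodes = 32L),
    seed = seed,
    min_trials = 20L,
    tanova_n_perm = 1000L,
    tct_n_perm = 500L,
    k_range = 2:10
  )
}

#' Write / read a pipeline configuration (lossless JSON round trip)
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns the path; `read_config` the config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- unclass(config)
  cfg$design <- unclass(cfg$design)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dsn <- raw$design
  dsn$state_seq <- as.data.frame(dsn$state_seq, stringsAsFactors = FALSE)
  if (!is.null(dsn$template_maps)) dsn$template_maps <- as.matrix(dsn$template_maps)
  design <- do.call(synthetic_design, dsn[setdiff(names(dsn), "groups")])
  args <- raw[setdiff(names(raw), "design")]
  args$bad_electrodes <- as.character(args$bad_electrodes %||% character(0))
  do.call(pipeline_config, c(list(design = design), args))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> seed %d; %d groups x %d subjects, %d electrodes; filters %g-%g Hz; tANOVA %d perms\n",
              x$seed, x$design$n_groups, x$design$n_subjects_per_group,
              x$design$n_electrodes, x$hp, x$lp, x$tanova_n_perm))
  invisible(x)
}

write_json_num <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order: simulate, preprocess (filter,
#' average reference, baseline, artifact/RT/error rejection, interpolation,
#' averaging), response-locked epoching, topographic consistency tests,
#' point-wise waveform ANOVA with extent criteria, tANOVA, overlap removal
#' and concatenation, TAAHC segmentation with model selection, back-fitting
#' and fitting statistics. Every stage writes its outputs under `out_dir`;
#' the manifest records the seed, the configuration and the MD5 hash of
#' every artifact, and re-running with the same configuration reproduces
#' all outputs bit-exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing run directory.
#' @return Invisibly, a list with the main in-memory results (`synth`,
#'   `erps`, `tct`, `anova`, `tanova`, `segmentation`, `fits`,
#'   `fit_stats`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite) {
    stop("out_dir already holds a completed run; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name,
                                      conditionMessage(e))),
                 file.path(out_dir, "log.txt"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  design <- config$design
  fs <- design$fs
  conds <- c("early", "late")

  write_config(config, file.path(out_dir, "config.json"))

  note("stage simulate: %d groups x %d subjects, %d electrodes, seed %d",
       design$n_groups, design$n_subjects_per_group, design$n_electrodes,
       config$seed)
  synth <- stage("simulate", simulate_epochs(design))
  montage <- synth$montage
  utils::write.csv(synth$behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)

  # --- per-subject preprocessing and averaging ----------------------------
  stim_erps <- list(); resp_erps <- list()
  erp_index <- list()
  rt_table <- list()
  excluded <- character(0)
  stage("preprocess", {
    for (subj in names(synth$subjects)) {
      su <- synth$subjects[[subj]]
      stim <- synth$stim_epochs[[subj]]
      resp <- epoch_response_locked(su$continuous, su$meta$rt_ms, fs = fs,
                                    pre_onset_tf = design$pre_lock_tf,
                                    length_tf = design$resp_epoch_tf,
                                    end_offset_tf = design$resp_end_offset_tf,
                                    meta = su$meta)
      resp$subject <- subj; resp$group <- su$group
      synth$subjects[[subj]]$continuous <- NULL   # free memory as we go
      pp_s <- preprocess_epochs(stim, montage, hp = config$hp, lp = config$lp,
                                abs_threshold = config$abs_threshold,
                                bad = config$bad_electrodes, baseline = TRUE)
      pp_r <- preprocess_epochs(resp, montage, hp = config$hp, lp = config$lp,
                                abs_threshold = config$abs_threshold,
                                bad = config$bad_electrodes, baseline = FALSE)
      for (l in pp_s$log) note("subject %s stimulus: %s", subj, l)
      for (l in pp_r$log) note("subject %s response: %s", subj, l)
      note("subject %s: %d response-locked trials dropped (window precedes onset)",
           subj, attr(resp, "dropped"))
      # retain trials that are correct, inside the RT bounds, and artifact
      # free in BOTH alignments
      keep_s <- rt_filter(pp_s$epochs$meta, config$rt_lo, config$rt_hi)
      keep_r <- rt_filter(pp_r$epochs$meta, config$rt_lo, config$rt_hi)
      common <- intersect(keep_s$trials$trial, keep_r$trials$trial)
      note("subject %s: %d trials retained in both alignments", subj,
           length(common))
      ok <- TRUE
      for (cond in conds) {
        ids_s <- which(pp_s$epochs$meta$trial %in% common &
                         pp_s$epochs$meta$condition == cond)
        ids_r <- which(pp_r$epochs$meta$trial %in% common &
                         pp_r$epochs$meta$condition == cond)
        sub_s <- pp_s$epochs; sub_s$data <- sub_s$data[ids_s, , , drop = FALSE]
        sub_s$meta <- sub_s$meta[ids_s, , drop = FALSE]; sub_s$condition <- cond
        sub_r <- pp_r$epochs; sub_r$data <- sub_r$data[ids_r, , , drop = FALSE]
        sub_r$meta <- sub_r$meta[ids_r, , drop = FALSE]; sub_r$condition <- cond
        e_s <- tryCatch(average_erp(sub_s, min_trials = config$min_trials),
                        erpmicro_too_few_trials = function(e) e)
        e_r <- tryCatch(average_erp(sub_r, min_trials = config$min_trials),
                        erpmicro_too_few_trials = function(e) e)
        if (inherits(e_s, "condition") || inherits(e_r, "condition")) {
          note("subject %s condition %s excluded: too few trials", subj, cond)
          ok <- FALSE
          next
        }
        key <- paste(subj, cond, sep = ".")
        stim_erps[[key]] <- e_s
        resp_erps[[key]] <- e_r
        erp_index[[key]] <- data.frame(subject = subj, group = su$group,
                                       condition = cond,
                                       stringsAsFactors = FALSE)
        rt_table[[key]] <- data.frame(subject = subj, group = su$group,
                                      condition = cond,
                                      mean_rt = mean(sub_s$meta$rt_ms),
                                      n_trials = dim(sub_s$data)[1L],
                                      stringsAsFactors = FALSE)
      }
      if (!ok) excluded <- c(excluded, subj)
    }
  })
  if (length(excluded) > 0L) {
    keep <- !(vapply(erp_index, function(d) d$subject, "") %in% excluded)
    stim_erps <- stim_erps[keep]; resp_erps <- resp_erps[keep]
    erp_index <- erp_index[keep]; rt_table <- rt_table[keep]
    note("excluded subjects: %s", paste(unique(excluded), collapse = ", "))
  }
  idx <- do.call(rbind, c(erp_index, make.row.names = FALSE))
  rts <- do.call(rbind, c(rt_table, make.row.names = FALSE))
  utils::write.csv(rts, file.path(out_dir, "subject_rt.csv"), row.names = FALSE)

  panel_s <- stack_erps(stim_erps, idx$subject, idx$group, idx$condition)
  panel_r <- stack_erps(resp_erps, idx$subject, idx$group, idx$condition)

  # --- topographic consistency --------------------------------------------
  tct_res <- stage("tct", {
    out <- list()
    for (lk in c("stimulus", "response")) {
      pn <- if (lk == "stimulus") panel_s else panel_r
      for (gr in levels(pn$group)) {
        rows <- which(pn$group == gr)
        if (length(rows) < 5L) {
          note("tct: group %s skipped for %s lock (%d subjects < 5)",
               gr, lk, length(rows))
          next
        }
        xs <- (pn$x[rows, 1L, , ] + pn$x[rows, 2L, , ]) / 2
        out[[paste(lk, gr, sep = ".")]] <-
          tct(xs, n_perm = config$tct_n_perm, alpha = config$tct_alpha,
              seed = config$seed + 11L)
      }
    }
    out
  })
  tct_df <- do.call(rbind, lapply(names(tct_res), function(nm) {
    data.frame(set = nm, tf = seq_along(tct_res[[nm]]$p_series),
               p = tct_res[[nm]]$p_series, stringsAsFactors = FALSE)
  }))
  if (!is.null(tct_df)) {
    utils::write.csv(tct_df, file.path(out_dir, "tct.csv"), row.names = FALSE)
  }

  # --- point-wise waveform ANOVA with extent criteria ---------------------
  anova_res <- stage("waveform_anova", {
    lapply(list(stimulus = panel_s, response = panel_r), function(pn) {
      extent_threshold(pointwise_anova(pn), montage,
                       min_consec_tf = config$anova_min_consec_tf,
                       min_adjacent = config$anova_min_adjacent,
                       alpha = config$anova_alpha)
    })
  })
  for (lk in names(anova_res)) {
    for (eff in names(anova_res[[lk]]$effects)) {
      utils::write.csv(anova_res[[lk]]$effects[[eff]]$mask,
                       file.path(out_dir, sprintf("anova_mask_%s_%s.csv", lk, eff)),
                       row.names = FALSE)
    }
  }

  # --- tANOVA -------------------------------------------------------------
  tanova_res <- stage("tanova", {
    list(stimulus = tanova(panel_s, n_perm = config$tanova_n_perm,
                           alpha = config$tanova_alpha,
                           min_consec_tf = config$tanova_min_consec_tf,
                           seed = config$seed + 23L),
         response = tanova(panel_r, n_perm = config$tanova_n_perm,
                           alpha = config$tanova_alpha,
                           min_consec_tf = config$tanova_min_consec_tf,
                           seed = config$seed + 29L))
  })
  tanova_df <- do.call(rbind, lapply(names(tanova_res), function(lk) {
    do.call(rbind, lapply(names(tanova_res[[lk]]$effects), function(eff) {
      ef <- tanova_res[[lk]]$effects[[eff]]
      data.frame(lock = lk, effect = eff, tf = seq_along(ef$p_series),
                 p = ef$p_series, effect_size = ef$effect_size,
                 mask = ef$mask, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(tanova_df, file.path(out_dir, "tanova.csv"), row.names = FALSE)

  # --- overlap removal and concatenation ----------------------------------
  combined <- stage("concatenate", {
    grand <- list(); indiv <- list()
    # the stimulus-locked epoch supports the overlap cut only up to a
    # maximal RT; longer mean RTs are clipped to it (and logged)
    rt_cap <- (design$epoch_tf - design$pre_lock_tf + design$resp_epoch_tf +
                 design$resp_end_offset_tf) * 1000 / fs
    cap_rt <- function(rt, what) {
      if (rt > rt_cap) {
        note("concatenate: %s mean RT %.1f ms exceeds epoch coverage; clipped to %.1f ms",
             what, rt, rt_cap)
        rt_cap
      } else rt
    }
    for (gr in levels(panel_s$group)) {
      for (cond in conds) {
        sel <- which(idx$group == gr & idx$condition == cond)
        stim_avg <- Reduce(`+`, lapply(stim_erps[sel], function(e) e$data)) /
          length(sel)
        resp_avg <- Reduce(`+`, lapply(resp_erps[sel], function(e) e$data)) /
          length(sel)
        g_rt <- cap_rt(mean(rts$mean_rt[rts$group == gr & rts$condition == cond]),
                       paste(gr, cond))
        gs <- erp(stim_avg, fs = fs, lock = "stimulus",
                  pre_lock_tf = design$pre_lock_tf, group = gr, condition = cond)
        gr_ <- erp(resp_avg, fs = fs, lock = "response",
                   pre_lock_tf = design$resp_epoch_tf + design$resp_end_offset_tf,
                   group = gr, condition = cond)
        grand[[paste(gr, cond, sep = ".")]] <-
          remove_overlap_concatenate(gs, gr_, g_rt)
      }
    }
    for (i in seq_len(nrow(idx))) {
      key <- paste(idx$subject[i], idx$condition[i], sep = ".")
      indiv[[key]] <- remove_overlap_concatenate(
        stim_erps[[i]], resp_erps[[i]],
        cap_rt(rts$mean_rt[rts$subject == idx$subject[i] &
                             rts$condition == idx$condition[i]], key))
    }
    list(grand = grand, indiv = indiv)
  })
  for (nm in names(combined$grand)) {
    utils::write.csv(round(combined$grand[[nm]]$data, 6),
                     file.path(out_dir, sprintf("grand_combined_%s.csv", nm)),
                     row.names = FALSE)
  }

  # --- TAAHC segmentation and model selection -----------------------------
  seg_sel <- stage("segmentation", {
    segs <- taahc_segment(combined$grand, k_range = config$k_range,
                          min_duration_tf = config$min_duration_tf,
                          merge_correlation = config$merge_correlation)
    select_model(segs, gev_threshold = config$gev_threshold)
  })
  note("segmentation: selected k = %d (requested %d), GEV = %.4f",
       seg_sel$k, seg_sel$requested_k, seg_sel$gev_total)
  utils::write.csv(attr(seg_sel, "gev_curve"),
                   file.path(out_dir, "gev_curve.csv"), row.names = FALSE)
  utils::write.csv(round(seg_sel$templates, 8),
                   file.path(out_dir, "templates.csv"), row.names = FALSE)
  seg_labels <- do.call(rbind, lapply(seq_along(seg_sel$labels), function(d) {
    data.frame(dataset = names(combined$grand)[d],
               tf = seq_along(seg_sel$labels[[d]]),
               label = seg_sel$labels[[d]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(seg_labels, file.path(out_dir, "segmentation_labels.csv"),
                   row.names = FALSE)

  # --- back-fitting -------------------------------------------------------
  fits_all <- stage("fitting", {
    wins <- fitting_windows(seg_sel, combined$grand, fs,
                            design$pre_lock_tf, design$epoch_tf)
    rows <- list()
    for (i in seq_len(nrow(idx))) {
      key <- paste(idx$subject[i], idx$condition[i], sep = ".")
      ce <- combined$indiv[[key]]
      n_tf <- ncol(ce$data)
      for (wname in names(wins)) {
        w <- wins[[wname]]
        tf_win <- switch(wname,
          p1 = c(max(1L, w$tf[1L]), min(w$tf[2L], ce$boundary_tf)),
          lexical = c(max(1L, w$tf[1L]), ce$boundary_tf),
          response = c(ce$boundary_tf + 1L, n_tf))
        if (tf_win[2L] <= tf_win[1L]) next
        f <- fit_templates(ce, seg_sel$templates, window = tf_win,
                           candidates = w$candidates,
                           min_presence_tf = config$fit_min_presence_tf,
                           min_duration_tf = config$min_duration_tf,
                           min_correlation = config$fit_min_correlation,
                           fs = fs)
        f <- as.data.frame(f)
        f$subject <- idx$subject[i]; f$group <- idx$group[i]
        f$condition <- idx$condition[i]; f$window <- wname
        rows[[length(rows) + 1L]] <- f
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(fits_all, file.path(out_dir, "fitting.csv"),
                   row.names = FALSE)

  fit_stats <- stage("fitting_statistics", compare_fitting(fits_all))
  utils::write.csv(fit_stats$stats, file.path(out_dir, "fitting_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_stats$presence, file.path(out_dir, "fitting_presence.csv"),
                   row.names = FALSE)

  # --- summary ------------------------------------------------------------
  p1 <- stage("p1_latency", {
    sapply(levels(panel_s$group), function(gr) {
      rows <- which(panel_s$group == gr)
      avg <- apply(panel_s$x[rows, , , , drop = FALSE], c(3L, 4L), mean)
      as.numeric(p1_peak_latency(erp(avg, fs = fs, lock = "stimulus",
                                     pre_lock_tf = design$pre_lock_tf)))
    })
  })
  summary <- list(
    seed = config$seed,
    n_subjects_analyzed = length(unique(idx$subject)),
    excluded_subjects = unique(excluded),
    selected_k = seg_sel$k,
    total_gev = seg_sel$gev_total,
    tanova_group_sig_fraction_stimulus =
      mean(tanova_res$stimulus$effects$group$mask),
    anova_group_sig_fraction_stimulus =
      mean(anova_res$stimulus$effects$group$mask),
    p1_latency_ms = as.list(p1),
    group_mean_rt_ms = as.list(tapply(rts$mean_rt, rts$group, mean))
  )
  write_json_num(summary, file.path(out_dir, "summary.json"))

  writeLines(log_lines, file.path(out_dir, "log.txt"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("erpmicro")),
                   files = as.list(tools::md5sum(file.path(out_dir, sort(files)))))
  names(manifest$files) <- sort(files)
  write_json_num(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(synth = synth, montage = montage,
                 stim_erps = stim_erps, resp_erps = resp_erps,
                 rts = rts, tct = tct_res, anova = anova_res,
                 tanova = tanova_res, combined = combined,
                 segmentation = seg_sel, fits = fits_all,
                 fit_stats = fit_stats, summary = summary,
                 out_dir = out_dir))
}

# Derive the three canonical fitting periods from the selected segmentation:
# an early window around the first visual component (68-202 ms), the
# remaining stimulus-locked portion (from ~200 ms to the overlap cut), and
# the response-locked portion. Candidates are the maps the grand-average
# labeling uses inside each period.
fitting_windows <- function(seg, grand, fs, pre_lock_tf, epoch_tf) {
  p1_tf <- c(ms_to_tf(68, fs) + 1L, ms_to_tf(202, fs))
  lex_start <- ms_to_tf(200, fs) + 1L
  maps_in <- function(region_of) {
    used <- integer(0)
    for (d in seq_along(grand)) {
      lab <- seg$labels[[d]]
      reg <- region_of(grand[[d]], length(lab))
      if (length(reg) > 0L) used <- union(used, setdiff(lab[reg], 0L))
    }
    if (length(used) == 0L) used <- seq_len(ncol(seg$templates))
    colnames(seg$templates)[sort(used)]
  }
  list(
    p1 = list(tf = p1_tf,
              candidates = maps_in(function(ce, n) {
                p1_tf[1L]:min(p1_tf[2L], ce$boundary_tf)
              })),
    lexical = list(tf = c(lex_start, NA),
                   candidates = maps_in(function(ce, n) {
                     if (ce$boundary_tf >= lex_start) lex_start:ce$boundary_tf
                     else integer(0)
                   })),
    response = list(tf = c(NA, NA),
                    candidates = maps_in(function(ce, n) {
                      if (ce$boundary_tf < n) (ce$boundary_tf + 1L):n
                      else integer(0)
                    }))
  )
}

#' Render a human-readable report of a pipeline run
#'
#' Reads the artifacts of a completed [run_pipeline()] directory and renders
#' GFP curves of the grand combined ERPs, significance rasters
#' (electrodes x TFs) for the waveform ANOVA, the tANOVA significance
#' series, template map topographies, segmentation timelines, and a textual
#' summary of the fitting tables.
#'
#' @param run_dir A completed run directory.
#' @return Invisibly, the paths of the written report files.
#' @export
report <- function(run_dir) {
  manifest <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest)) stop("not a completed run directory: ", run_dir)
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  paths <- character(0)

  grand_files <- list.files(run_dir, pattern = "^grand_combined_.*\\.csv$")
  if (length(grand_files) > 0L) {
    p <- file.path(rep_dir, "gfp_curves.png")
    grDevices::png(p, width = 900, height = 600)
    graphics::par(mar = c(4, 4, 2, 1))
    first <- TRUE
    cols <- grDevices::rainbow(length(grand_files))
    for (i in seq_along(grand_files)) {
      m <- as.matrix(utils::read.csv(file.path(run_dir, grand_files[i])))
      gv <- gfp(m)
      if (first) {
        graphics::plot(seq_along(gv), gv, type = "l", col = cols[i],
                       xlab = "TF (from picture onset)", ylab = "GFP (uV)",
                       main = "Grand combined ERPs: global field power")
        first <- FALSE
      } else graphics::lines(seq_along(gv), gv, col = cols[i])
    }
    graphics::legend("topright", legend = sub("^grand_combined_(.*)\\.csv$", "\\1",
                                              grand_files),
                     col = cols, lty = 1, cex = 0.7)
    grDevices::dev.off()
    paths <- c(paths, p)
  }

  mask_files <- list.files(run_dir, pattern = "^anova_mask_.*\\.csv$")
  for (mf in mask_files) {
    m <- as.matrix(utils::read.csv(file.path(run_dir, mf)))
    p <- file.path(rep_dir, sub("\\.csv$", ".png", mf))
    grDevices::png(p, width = 900, height = 500)
    graphics::image(t(m * 1), xlab = "TF", ylab = "electrode",
                    main = sub("\\.csv$", "", mf),
                    col = c("grey95", "turquoise3"), zlim = c(0, 1))
    grDevices::dev.off()
    paths <- c(paths, p)
  }

  tanova_file <- file.path(run_dir, "tanova.csv")
  if (file.exists(tanova_file)) {
    tv <- utils::read.csv(tanova_file)
    p <- file.path(rep_dir, "tanova.png")
    grDevices::png(p, width = 900, height = 600)
    sets <- unique(tv[, c("lock", "effect")])
    graphics::par(mfrow = c(nrow(sets), 1), mar = c(3, 4, 2, 1))
    for (i in seq_len(nrow(sets))) {
      sel <- tv$lock == sets$lock[i] & tv$effect == sets$effect[i]
      graphics::plot(tv$tf[sel], -log10(tv$p[sel]), type = "h",
                     col = ifelse(tv$mask[sel], "turquoise3", "grey70"),
                     xlab = "TF", ylab = "-log10 p",
                     main = sprintf("tANOVA %s / %s", sets$lock[i], sets$effect[i]))
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }

  tmpl_file <- file.path(run_dir, "templates.csv")
  cfg <- read_config(file.path(run_dir, "config.json"))
  if (file.exists(tmpl_file)) {
    tm <- as.matrix(utils::read.csv(tmpl_file))
    mont <- make_montage(nrow(tm))
    # azimuthal projection of the cap
    px <- mont$pos[, 1] / (1 + mont$pos[, 3])
    py <- mont$pos[, 2] / (1 + mont$pos[, 3])
    p <- file.path(rep_dir, "templates.png")
    grDevices::png(p, width = 250 * ncol(tm), height = 300)
    graphics::par(mfrow = c(1, ncol(tm)), mar = c(1, 1, 2, 1))
    for (k in seq_len(ncol(tm))) {
      v <- tm[, k]
      cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
      ci <- 1 + round(50 * (1 + v / max(abs(v))))
      graphics::plot(px, py, pch = 21, bg = cols[ci], cex = 2.2, axes = FALSE,
                     xlab = "", ylab = "", main = colnames(tm)[k], asp = 1)
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }

  lab_file <- file.path(run_dir, "segmentation_labels.csv")
  if (file.exists(lab_file)) {
    lab <- utils::read.csv(lab_file)
    sets <- unique(lab$dataset)
    p <- file.path(rep_dir, "segmentation_timeline.png")
    grDevices::png(p, width = 900, height = 60 * length(sets) + 120)
    graphics::par(mar = c(4, 10, 2, 1))
    kmax <- max(lab$label)
    cols <- c("grey90", grDevices::rainbow(max(1L, kmax)))
    graphics::plot(NULL, xlim = c(0, max(lab$tf)), ylim = c(0, length(sets)),
                   xlab = "TF", ylab = "", yaxt = "n",
                   main = "Microstate timeline per dataset")
    graphics::axis(2, at = seq_along(sets) - 0.5, labels = sets, las = 1,
                   cex.axis = 0.7)
    for (i in seq_along(sets)) {
      li <- lab[lab$dataset == sets[i], ]
      graphics::rect(li$tf - 1, i - 0.9, li$tf, i - 0.1,
                     col = cols[li$label + 1L], border = NA)
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }

  fit_file <- file.path(run_dir, "fitting.csv")
  if (file.exists(fit_file)) {
    ft <- utils::read.csv(fit_file)
    txt <- file.path(rep_dir, "fitting_summary.txt")
    con <- file(txt, "w")
    agg <- stats::aggregate(cbind(gev, duration_ms, presence) ~ window + map + group,
                            data = ft, FUN = mean)
    writeLines("Back-fitting: mean GEV / duration (ms) / presence rate per window, map, group",
               con)
    utils::write.table(format(agg, digits = 3), con, row.names = FALSE,
                       quote = FALSE)
    close(con)
    paths <- c(paths, txt)
  }
  invisible(paths)
}
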