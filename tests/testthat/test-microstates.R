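montage32 <- make_montage(32)

test_that("TAAHC recovers planted structure exactly on noise-free data", {
  tm <- make_template_maps(4, montage32, min_separation = 0.4, seed = 11)
  X <- tm[, rep(1:4, each = 40)] * 3
  segs <- taahc_segment(list(X), k_range = 1:6)
  s4 <- segs[[4]]
  expect_identical(s4$k, 4L)
  # recovered centroids match the planted maps up to label permutation
  cr <- abs(crossprod(s4$templates, tm) / 32)
  expect_true(all(apply(cr, 2, max) >= 0.999))
  expect_identical(rle(s4$labels[[1]])$lengths, rep(40L, 4))
  expect_equal(s4$gev_total, 1, tolerance = 1e-9)
})

test_that("TAAHC reaches the exhaustively enumerated contiguous optimum on tiny instances", {
  for (seed in c(1, 2, 3, 4, 5, 6, 7, 8)) {
    set.seed(seed)
    tm <- separated_pair_4el()
    X <- tm[, rep(1:2, each = 4)] * rep(c(2, 3), each = 4) +
      matrix(rnorm(32, sd = 0.4), 4, 8)
    got <- taahc_segment(list(X), k_range = 2, min_duration_tf = 1,
                         merge_correlation = 0.999)[[1]]$gev_total
    expect_gte(got, oracle_contiguous_best(X) - 1e-9)
  }
})

test_that("raw GEV is non-decreasing in k and labels are scale invariant", {
  set.seed(12)
  tm <- make_template_maps(4, montage32, min_separation = 0.4, seed = 13)
  X <- tm[, rep(1:4, each = 40)] * 3 + matrix(rnorm(32 * 160, sd = 0.8), 32)
  segs <- taahc_segment(list(X), k_range = 1:6)
  gr <- vapply(segs, function(s) s$gev_raw, 0)
  expect_true(all(diff(gr) >= -1e-12))
  # rescaling one input ERP leaves the labeling unchanged
  segs2 <- taahc_segment(list(X * 7.3), k_range = 1:6)
  expect_identical(segs[[4]]$labels, segs2[[4]]$labels)
})

test_that("smoothing leaves no labeled run shorter than the minimum duration", {
  set.seed(14)
  tm <- make_template_maps(3, montage32, min_separation = 0.5, seed = 15)
  X <- tm[, sample(1:3, 120, replace = TRUE)] * 3 +
    matrix(rnorm(32 * 120, sd = 1.5), 32)
  segs <- taahc_segment(list(X[, 1:60], X[, 61:120]), k_range = 3,
                        min_duration_tf = 12)
  for (lab in segs[[1]]$labels) {
    runs <- rle(lab)
    expect_true(all(runs$lengths[runs$values != 0] >= 12 |
                      length(runs$lengths) == 1))
  }
})

test_that("model selection follows the smallest-k-above-threshold rule", {
  fake <- function(k, g) structure(list(requested_k = k, gev_total = g),
                                   class = "segmentation")
  segs <- list(fake(1L, 0.80), fake(2L, 0.93), fake(3L, 0.96), fake(4L, 0.97))
  expect_identical(select_model(segs, 0.95)$requested_k, 3L)
  expect_warning(sel <- select_model(segs, 0.99), "largest model")
  expect_identical(sel$requested_k, 4L)
  expect_equal(attr(sel, "gev_curve")$gev, c(0.80, 0.93, 0.96, 0.97))
})

test_that("back-fitting labels a noise-free two-state ERP exactly", {
  tm <- make_template_maps(2, montage32, min_separation = 0.4, seed = 16)
  X <- cbind(tm[, 1] %o% rep(2, 50), tm[, 2] %o% rep(3, 50))
  f <- fit_templates(X, tm, fs = 512)
  expect_identical(f$presence, c(TRUE, TRUE))
  expect_identical(f$duration_tf, c(50L, 50L))
  expect_identical(f$onset_tf, c(1L, 51L))
  expect_equal(f$duration_ms, c(50, 50) * 1000 / 512)
  # a single candidate explains everything, and its GEV agrees with gev()
  f1 <- fit_templates(X[, 1:50], tm[, 1, drop = FALSE], candidates = "A",
                      fs = 512)
  expect_equal(f1$gev, gev(X[, 1:50], tm[, 1, drop = FALSE],
                           rep(1L, 50))$total, tolerance = 1e-12)
  expect_error(fit_templates(X, tm, candidates = character(0)), "empty candidate")
  expect_error(fit_templates(X, tm, window = c(90, 120)), "outside the ERP")
})

test_that("pure-noise individuals yield no spurious map presence", {
  tm <- make_template_maps(2, montage32, min_separation = 0.4, seed = 17)
  set.seed(18)
  n_present <- 0L
  for (i in 1:100) {
    X <- matrix(rnorm(32 * 68), 32)
    f <- fit_templates(X, tm, min_presence_tf = 12, fs = 512)
    if (any(f$presence)) n_present <- n_present + 1L
  }
  expect_lte(n_present, 10L)
})

test_that("back-fitting the segmentation's own inputs reproduces its labels", {
  tm <- make_template_maps(4, montage32, min_separation = 0.4, seed = 19)
  set.seed(20)
  X <- tm[, rep(1:4, each = 40)] * 3 + matrix(rnorm(32 * 160, sd = 0.3), 32)
  seg <- taahc_segment(list(X), k_range = 4)[[1]]
  f <- fit_templates(X, seg$templates, fs = 512)
  expect_gt(mean(attr(f, "labels") == seg$labels[[1]]), 0.95)
})

test_that("fitting statistics flag planted group differences and covariate trends", {
  tm <- make_template_maps(2, montage32, min_separation = 0.4, seed = 21)
  set.seed(22)
  rows <- list()
  ages <- c()
  for (g in 1:2) for (s in 1:8) {
    subj <- sprintf("g%ds%d", g, s)
    age <- if (g == 1) runif(1, 10, 13) else runif(1, 20, 30)
    ages[subj] <- age
    for (cond in c("c1", "c2")) {
      dur <- if (g == 1) 120L else 140L
      X <- cbind(tm[, 1] %o% rep(3, dur), tm[, 2] %o% rep(3, 260 - dur)) +
        matrix(rnorm(32 * 260, sd = 0.3), 32)
      f <- as.data.frame(fit_templates(X, tm, fs = 512))
      # make GEV decrease with age to plant a covariate trend
      f$gev <- f$gev - 0.01 * age + rnorm(2, sd = 0.005)
      f$subject <- subj; f$group <- paste0("g", g); f$condition <- cond
      f$window <- "w"
      rows[[length(rows) + 1L]] <- f
    }
  }
  fits <- do.call(rbind, rows)
  cf <- compare_fitting(fits, covariate = ages)
  pg <- cf$stats$p[cf$stats$map == "A" & cf$stats$measure == "duration" &
                     cf$stats$effect == "group"]
  expect_lt(pg, 0.01)
  rA <- cf$covariate$r[cf$covariate$map == "A"]
  expect_lt(rA, 0)
  expect_lt(cf$covariate$p[cf$covariate$map == "A"], 0.05)
  # identical values everywhere give F = 0, p = 1
  fits0 <- fits
  fits0$gev <- 0.5; fits0$duration_ms <- 100
  cf0 <- compare_fitting(fits0)
  expect_true(all(cf0$stats$F == 0))
  expect_true(all(cf0$stats$p == 1))
})
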