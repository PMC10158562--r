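montage32 <- make_montage(32)

test_that("two-group one-condition F equals the squared two-sample t", {
  set.seed(1)
  for (i in 1:20) {
    y <- array(rnorm(12), c(12, 1, 1))
    grp <- rep(c("a", "b"), each = 6)
    F_mine <- erpmicro:::splitplot_anova(y, grp)$group$F
    tt <- t.test(y[1:6, 1, 1], y[7:12, 1, 1], var.equal = TRUE)
    expect_lt(abs(F_mine - tt$statistic^2), 1e-9)
  }
})

test_that("the split-plot engine matches stats::aov with an Error stratum", {
  set.seed(2)
  S <- 12; grp <- rep(c("g1", "g2", "g3"), each = 4)
  y <- array(rnorm(S * 2), c(S, 2, 1))
  mine <- erpmicro:::splitplot_anova(y, grp)
  df <- data.frame(y = c(y[, 1, 1], y[, 2, 1]),
                   cond = factor(rep(c("c1", "c2"), each = S)),
                   subj = factor(rep(seq_len(S), 2)),
                   grp = factor(rep(grp, 2)))
  av <- summary(stats::aov(y ~ grp * cond + Error(subj / cond), data = df))
  between <- av[["Error: subj"]][[1]]
  within <- av[["Error: subj:cond"]][[1]]
  expect_equal(mine$group$F, between["grp", "F value"], tolerance = 1e-9)
  expect_equal(mine$condition$F, within["cond", "F value"], tolerance = 1e-9)
  expect_equal(mine$interaction$F, within["grp:cond", "F value"],
               tolerance = 1e-9)
  expect_equal(mine$group$p, between["grp", "Pr(>F)"], tolerance = 1e-9)
})

test_that("point-wise ANOVA is calibrated under the null and localizes a planted effect", {
  set.seed(3)
  S <- 16; E <- 16; Tn <- 40
  x <- array(rnorm(S * 2 * E * Tn), c(S, 2, E, Tn))
  grp <- rep(c("a", "b"), each = 8)
  res <- pointwise_anova(x, grp)
  frac <- mean(res$effects$group$p < 0.01)
  expect_lt(abs(frac - 0.01), 1.96 * sqrt(0.01 * 0.99 / (E * Tn)) + 0.005)
  # planted group effect: +5 uV on electrodes 3:8, TFs 11:25, low noise
  x2 <- array(rnorm(S * 2 * E * Tn, sd = 0.5), c(S, 2, E, Tn))
  x2[1:8, , 3:8, 11:25] <- x2[1:8, , 3:8, 11:25] + 5
  res2 <- pointwise_anova(x2, grp)
  inside <- res2$effects$group$F[3:8, 11:25]
  outside <- res2$effects$group$F
  outside[3:8, 11:25] <- NA
  expect_gt(min(inside), max(outside, na.rm = TRUE))
})

test_that("identical generators across conditions yield the degenerate F convention", {
  y <- array(2.5, c(8, 2, 1))
  res <- erpmicro:::splitplot_anova(y, rep(c("a", "b"), each = 4))
  expect_equal(res$group$F, 0)
  expect_equal(res$group$p, 1)
})

test_that("extent thresholding applies the 10-TF / 5-adjacent-electrode rule", {
  ring <- ring_montage(8)
  Tn <- 30
  mk_p <- function() matrix(1, 8, Tn)
  # run of 9 TFs on 6 adjacent electrodes: fails the temporal criterion
  p <- mk_p(); p[1:6, 5:13] <- 0.001
  s <- structure(list(effects = list(group = list(p = p)),
                      n_electrodes = 8L, n_tf = Tn),
                 class = "pointwise_stat_map")
  expect_false(any(extent_threshold(s, ring)$effects$group$mask))
  # run of 12 TFs on 5 adjacent electrodes: retained
  p <- mk_p(); p[1:5, 5:16] <- 0.001
  s$effects$group$p <- p
  m <- extent_threshold(s, ring)$effects$group$mask
  expect_true(all(m[1:5, 5:16]))
  expect_false(any(m[6:8, ]))
  # 12 TFs on 4 mutually adjacent + 1 distant electrode: removed
  p <- mk_p(); p[c(1:4, 6), 5:16] <- 0.001
  s$effects$group$p <- p
  expect_false(any(extent_threshold(s, ring)$effects$group$mask))
})

test_that("extent thresholding matches a connected-component oracle on random masks", {
  set.seed(4)
  for (i in 1:10) {
    p <- matrix(runif(32 * 60), 32, 60)^0.25   # denser supra-threshold areas
    mine <- erpmicro:::extent_mask_matrix(p, montage32$adjacency,
                                          min_consec_tf = 4L,
                                          min_adjacent = 3L, alpha = 0.3)
    orc <- oracle_extent_mask(p, montage32$adjacency, 4L, 3L, 0.3)
    expect_identical(mine, orc)
  }
})

test_that("the surviving set shrinks as the extent criteria tighten", {
  set.seed(5)
  p <- matrix(runif(32 * 60), 32, 60)^0.3
  base <- erpmicro:::extent_mask_matrix(p, montage32$adjacency, 4L, 3L, 0.3)
  expect_true(all(erpmicro:::extent_mask_matrix(p, montage32$adjacency, 8L, 3L, 0.3) <= base))
  expect_true(all(erpmicro:::extent_mask_matrix(p, montage32$adjacency, 4L, 5L, 0.3) <= base))
  expect_true(all(erpmicro:::extent_mask_matrix(p, montage32$adjacency, 4L, 3L, 0.1) <= base))
})
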