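three_groups <- function(n = c(10, 10, 9))
  rep(c("Ctr", "CtrStress", "FVTStress"), times = n)

test_that("outlier exclusion implements the 2.5-SD single-pass rule", {
  # nine values of 1 and one of 50: z of the 50 is ~2.85 and it is removed
  v <- c(rep(1, 9), 50)
  out <- exclude_outliers(v)
  expect_equal(out$excluded$value, 50)
  expect_gt(out$excluded$z, 2.5)
  expect_equal(length(out$values), 9L)
  # homogeneous values: nothing removed
  expect_equal(nrow(exclude_outliers(rep(3, 6))$excluded), 0L)
  # n = 3: the z-score bound (n-1)/sqrt(n) ~ 1.15 makes removal impossible
  expect_equal(nrow(exclude_outliers(c(1, 2, 100))$excluded), 0L)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("outlier exclusion caps removals at 2 per test", {
  v <- c(rep(0, 40), 80, 90, 100)
  out <- exclude_outliers(v)
  expect_equal(nrow(out$excluded), 2L)
  expect_setequal(out$excluded$value, c(90, 100))   # largest deviations first
})

test_that("variance pre-filter applies the absolute 0.5 cut-off", {
  set.seed(21)
  base <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:40)))
  x <- base / sqrt(apply(base, 1, var))    # unit variance rows
  x[1, ] <- x[1, ] * sqrt(0.49)
  x[2, ] <- x[2, ] * sqrt(0.51)
  x[3, ] <- 7                              # constant
  kept <- rownames(variance_prefilter(x, 0.5))
  expect_false("g1" %in% kept)
  expect_true("g2" %in% kept)
  expect_false("g3" %in% kept)
  expect_equal(nrow(variance_prefilter(x, 0)), 5L)
})

test_that("restoration contrast reproduces closed-form t on hand-made data", {
  g <- three_groups(c(3, 3, 3))
  # all group means equal -> L = 0, p = 1
  r0 <- restoration_contrast(rep(c(1, 2, 3), times = 3), g)
  expect_equal(r0$contrast_estimate, 0)
  expect_equal(r0$p_restoration, 1)
  # Ctr = FVT = 1, CtrStress = 0 with tiny noise -> L = 1, p ~ 0
  set.seed(1)
  v <- c(1, 1, 1, 0, 0, 0, 1, 1, 1) + rnorm(9, sd = 1e-6)
  r1 <- restoration_contrast(v, g)
  expect_equal(r1$contrast_estimate, 1, tolerance = 1e-4)
  expect_lt(r1$p_restoration, 1e-10)
  expect_equal(r1$direction, -1)           # stress below the Ctr/FVT average
  expect_equal(r1$df, 6)                   # N - 3
  expect_error(restoration_contrast(v[1:6], g[1:6]), "missing group")
})

test_that("contrast inference is invariant to rescaling the weights", {
  set.seed(13)
  g <- three_groups()
  v <- rnorm(29) + (g == "CtrStress") * 1.2
  r1 <- restoration_contrast(v, g, weights = c(0.5, -1, 0.5))
  r2 <- restoration_contrast(v, g, weights = c(1, -2, 1))
  expect_equal(r1$t_statistic, r2$t_statistic, tolerance = 1e-12)
  expect_equal(r1$p_restoration, r2$p_restoration, tolerance = 1e-12)
  expect_equal(r2$contrast_estimate, 2 * r1$contrast_estimate)
})

test_that("restoration contrast matches an lm-based orthogonal contrast", {
  set.seed(14)
  g <- three_groups()
  v <- rnorm(29) + (g == "CtrStress") * -0.8
  mine <- restoration_contrast(v, g)
  fit <- lm(v ~ 0 + factor(g, levels = c("Ctr", "CtrStress", "FVTStress")))
  w <- c(0.5, -1, 0.5)
  L <- sum(w * coef(fit))
  se <- sqrt(drop(t(w) %*% vcov(fit) %*% w))
  expect_equal(mine$contrast_estimate, L, tolerance = 1e-12)
  expect_equal(mine$t_statistic, L / se, tolerance = 1e-10)
})

test_that("Tukey pairwise p-values are family-wise protective and sane", {
  g <- three_groups(c(5, 5, 5))
  # identical groups -> adjusted p = 1
  tk0 <- tukey_pairwise(rep(c(1, 2, 3, 4, 5), 3), g)
  expect_equal(tk0$p_adjusted, c(1, 1), tolerance = 1e-12)
  set.seed(15)
  for (i in 1:20) {
    v <- rnorm(15)
    tk <- tukey_pairwise(v, g)
    # dominance over the matched unadjusted t test (same pooled s, same df)
    n <- tapply(v, g, length); m <- tapply(v, g, mean)
    s2 <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / 12
    for (k in 1:2) {
      pr <- list(c("Ctr", "CtrStress"), c("CtrStress", "FVTStress"))[[k]]
      tstat <- (m[pr[1]] - m[pr[2]]) /
        sqrt(s2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
      p_t <- 2 * pt(-abs(tstat), 12)
      expect_gte(tk$p_adjusted[k], p_t - 1e-12)
    }
    expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))
  }
})

test_that("Tukey family-wise error under the global null is near nominal", {
  set.seed(16)
  g <- three_groups(c(10, 10, 10))
  hits <- 0L
  n_sim <- 2000L
  for (i in seq_len(n_sim)) {
    v <- rnorm(30)
    tk <- tukey_pairwise(v, g,
                         pairs = list(c("Ctr", "CtrStress"),
                                      c("CtrStress", "FVTStress"),
                                      c("Ctr", "FVTStress")))
    if (any(tk$p_adjusted < 0.05)) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.03)
  expect_lt(hits / n_sim, 0.07)
})

test_that("BH adjustment equals the step-up oracle and hand example", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:500, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
})

test_that("matrix-level restoration test flags planted features", {
  s <- simulate_clr_study(n_features = 100, n_restored = 10,
                          n_stress_only = 10, effect_size = 2.5, seed = 18)
  res <- restoration_test(s$x, s$design)
  expect_equal(res$feature_id, s$truth$feature_id)
  restored <- s$truth$class == "restored"
  stress_only <- s$truth$class == "stress_only"
  expect_gt(mean(res$restored_call[restored]), 0.8)
  # restored features separate stress from FVT in the Tukey post hoc;
  # stress-only features (FVT stays shifted) do not
  expect_gt(mean(res$p_stress_vs_fvt[restored] < 0.05), 0.7)
  expect_lt(mean(res$p_stress_vs_fvt[stress_only] < 0.05), 0.3)
  expect_gt(mean(res$p_ctr_vs_stress[stress_only] < 0.05), 0.7)
  expect_true(all(res$q_value <= 1))
})

test_that("longitudinal model reduces exactly to the cross-sectional contrast", {
  cs <- simulate_clr_study(n_features = 6, n_restored = 2, n_stress_only = 1,
                           seed = 19)
  x <- cs$x; des1 <- cs$design
  Tn <- 3
  design_long <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    d <- des1
    d$timepoint <- t
    d$sample_id <- paste0(d$subject_id, "_t", t)
    d
  }))
  # timepoint copies plus a pure time shift: zero within-subject residual
  x_long <- sweep(x[, rep(seq_len(ncol(x)), Tn)], 2,
                  rep(seq_len(Tn) * 2, each = ncol(x)), "+")
  colnames(x_long) <- design_long$sample_id
  for (i in seq_len(nrow(x))) {
    r_cs <- restoration_contrast(x[i, ], des1$group)
    r_lg <- longitudinal_restoration(x_long[i, ], design_long)
    expect_lt(abs(r_cs$t_statistic - r_lg$t_statistic), 1e-6)
    expect_equal(r_lg$df, r_cs$df, tolerance = 1e-9)
    expect_equal(r_lg$contrast_estimate, r_cs$contrast_estimate,
                 tolerance = 1e-12)
  }
})

test_that("per-subject offsets load on the subject variance component", {
  s <- simulate_clr_study(n_features = 1, n_restored = 1, effect_size = 1.5,
                          subject_sd = 0.5, timepoints = 3, seed = 20)
  r1 <- longitudinal_restoration(s$x[1, ], s$design)
  # a grand offset changes nothing
  r_const <- longitudinal_restoration(s$x[1, ] + 11, s$design)
  expect_equal(r1$contrast_estimate, r_const$contrast_estimate,
               tolerance = 1e-12)
  expect_equal(r1$t_statistic, r_const$t_statistic, tolerance = 1e-12)
  # per-subject offsets inflate the subject component, not the residual
  set.seed(21)
  offs <- setNames(rnorm(length(unique(s$design$subject_id)), sd = 3),
                   unique(s$design$subject_id))
  r2 <- longitudinal_restoration(s$x[1, ] + offs[s$design$subject_id],
                                 s$design)
  expect_gt(r2$sigma_subject, r1$sigma_subject)
  expect_equal(r2$sigma_residual, r1$sigma_residual, tolerance = 1e-9)
})

test_that("longitudinal model agrees with lmer/emmeans on a balanced instance", {
  skip_if_not_installed("lmerTest")
  skip_if_not_installed("emmeans")
  set.seed(9)
  g <- rep(c("Ctr", "CtrStress", "FVTStress"), each = 6)
  sub <- sprintf("s%02d", 1:18)
  dd <- do.call(rbind, lapply(1:3, function(t) data.frame(
    sample_id = paste0(sub, "_t", t), group = g, subject_id = sub,
    timepoint = t, stringsAsFactors = FALSE)))
  y <- rnorm(54, sd = 0.6) + rep(rnorm(18, sd = 1), 3) +
    ifelse(dd$group == "CtrStress" & dd$timepoint >= 2, -1.2, 0)
  mine <- longitudinal_restoration(y, dd)
  dd$timepoint <- factor(dd$timepoint)
  fit <- lmerTest::lmer(y ~ group * timepoint + (1 | subject_id), data = dd)
  em <- emmeans::emmeans(fit, ~ group | timepoint)
  ct <- summary(emmeans::contrast(em, list(rest = c(0.5, -1, 0.5)))[3])
  expect_equal(mine$contrast_estimate, ct$estimate, tolerance = 1e-6)
  expect_equal(mine$t_statistic, ct$t.ratio, tolerance = 1e-3)
  expect_equal(mine$df, ct$df, tolerance = 0.1)
})

test_that("a subject cannot sit in two groups and designs must be complete", {
  d <- data.frame(group = c("Ctr", "CtrStress"), subject_id = c("m1", "m1"),
                  timepoint = c(1, 1))
  expect_error(longitudinal_restoration(c(1, 2), d), "more than one group")
  d2 <- data.frame(group = rep(c("Ctr", "CtrStress", "FVTStress"), each = 2),
                   subject_id = sprintf("m%d", 1:6),
                   timepoint = c(1, 1, 1, 1, 1, 2))
  expect_error(longitudinal_restoration(rnorm(6), d2), "complete")
})

test_that("hypergeometric enrichment matches enumeration", {
  u <- sprintf("g%03d", 1:10)
  r <- hypergeometric_enrichment(u[1:5], u[1:5], u)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-15)
  expect_equal(r$overlap, 5L)
  # term = universe -> p = 1
  expect_equal(hypergeometric_enrichment(u[1:3], u, u)$p_value, 1)
  # overlap 0 with a small term: p equals the pmf-summation complement
  r0 <- hypergeometric_enrichment(u[1:4], u[5:6], u)
  expect_equal(r0$p_value, oracle_hyper_tail(0, 2, 4, 10), tolerance = 1e-15)
  expect_equal(r0$p_value, 1)
  expect_error(hypergeometric_enrichment(c(u[1:2], "zz"), u[1:2], u),
               "outside the universe")
})
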