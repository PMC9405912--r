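test_that("pooled t from summaries behaves like a Student t", {
  r <- pooled_t_from_summary(10, 1, 12, 10, 1, 12)
  expect_equal(r$t, 0)
  expect_equal(r$df, 22)
  # antisymmetric under group swap
  a <- pooled_t_from_summary(12, 1.1, 10, 9, 0.9, 14)
  b <- pooled_t_from_summary(9, 0.9, 14, 12, 1.1, 10)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # agrees with t.test on raw data when summaries come from the same data
  set.seed(71)
  x <- rnorm(9, 1)
  y <- rnorm(13, 0.2)
  tt <- t.test(x, y, var.equal = TRUE)
  r2 <- pooled_t_from_summary(mean(x), sd(x) / sqrt(9), 9,
                              mean(y), sd(y) / sqrt(13), 13)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  expect_error(pooled_t_from_summary(1, 0, 5, 2, 1, 5), "positive")
})

test_that("effect sizes follow their closed forms", {
  expect_equal(partial_eta_sq(0, 1, 30), 0)
  # monotone increasing in F at fixed dfs
  fs <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(partial_eta_sq(fs, 1, 30)) > 0))
  expect_error(partial_eta_sq(1, 0, 30), "positive")
  expect_equal(cohens_d(1, 1, 10, 0, 1, 10), 1)
  expect_equal(cohens_d(0, 2, 8, 1, 2, 12), -0.5)
})

test_that("the mixed model matches a naive split-plot oracle", {
  set.seed(72)
  n <- 24
  g <- rep(c("a", "b"), each = n / 2)
  Y <- matrix(rnorm(n * 5), n, 5) + ifelse(g == "a", 0.8, 0)
  dat <- data.frame(g = g, Y)
  res <- mixed_anova(dat, paste0("X", 1:5), between = "g")
  expect_setequal(res$effect, c("group", "roi", "group:roi"))
  grp <- res[res$effect == "group", ]
  expect_equal(grp$F, oracle_split_plot_F(Y, g), tolerance = 1e-9)
  expect_equal(grp$df1, 1)
  expect_equal(grp$df2, n - 2)
  # the eta identity holds on every reported row
  expect_equal(res$partial_eta_sq,
               res$F * res$df1 / (res$F * res$df1 + res$df2))
})

test_that("Greenhouse-Geisser epsilon is near 1 under compound symmetry", {
  set.seed(73)
  n <- 200
  subj <- rnorm(n, sd = 2)
  Y <- matrix(rnorm(n * 5), n, 5) + subj
  dat <- data.frame(g = rep(c("a", "b"), each = n / 2), Y)
  res <- mixed_anova(dat, paste0("X", 1:5), between = "g")
  roi <- res[res$effect == "roi", ]
  expect_gt(roi$gg_epsilon, 0.9)
  # corrected dfs shrink by epsilon
  expect_equal(roi$df1, 4 * roi$gg_epsilon)
})

test_that("mixed-model preconditions are enforced", {
  dat <- data.frame(g = rep("a", 6), matrix(rnorm(30), 6, 5))
  expect_error(mixed_anova(dat, paste0("X", 1:5), between = "g"),
               "at least 2 levels")
  dat2 <- data.frame(g = c("a", rep("b", 5)), matrix(rnorm(30), 6, 5))
  expect_error(mixed_anova(dat2, paste0("X", 1:5), between = "g"),
               "at least 2 subjects")
  dat3 <- data.frame(g = rep(c("a", "b"), 3), matrix(rnorm(30), 6, 5))
  dat3$X1[2] <- NA
  expect_error(mixed_anova(dat3, paste0("X", 1:5), between = "g"),
               "missing ROI cells")
})

test_that("ANCOVA adjusts the group effect for the covariate", {
  set.seed(74)
  n <- 40
  g <- rep(c("a", "b"), each = n / 2)
  cov_ <- rnorm(n) + ifelse(g == "a", 1, 0)
  y <- 2 * cov_ + rnorm(n) # group difference entirely through the covariate
  dat <- data.frame(g = g, cov_ = cov_, y = y)
  plain <- mixed_anova(dat, "y", between = "g")
  adj <- mixed_anova(dat, "y", between = "g", covariate = "cov_")
  expect_gt(plain$F, adj$F) # adjustment removes the spurious effect
  expect_gt(adj$p, 0.05)
  # and matches car's Type III ANCOVA directly
  fit <- lm(y ~ cov_ + g, data = dat,
            contrasts = list(g = "contr.sum"))
  av <- car::Anova(fit, type = 3)
  expect_equal(adj$F, av["g", "F value"], tolerance = 1e-9)
})

test_that("bootstrap t-test is calibrated at its endpoints", {
  set.seed(75)
  a <- rnorm(12)
  r_same <- bootstrap_ttest(a, a, n_boot = 500, seed = 2)
  expect_gt(r_same$p_boot, 0.9)

  b <- rnorm(12) + 10 # ten pooled SDs away
  r_sep <- bootstrap_ttest(a, b, n_boot = 1000, seed = 2)
  expect_lte(r_sep$p_boot, 2 / 1000)
  expect_lt(r_sep$ci_upper, 0) # CI for mean(a) - mean(b) well below zero

  # deterministic given the seed
  expect_identical(bootstrap_ttest(a, b, seed = 9),
                   bootstrap_ttest(a, b, seed = 9))
  expect_error(bootstrap_ttest(a, b, n_boot = 50), "at least 100")
})

test_that("group-shift power: a 1.5 SD shift is detected in most cohorts", {
  set.seed(76)
  hits <- vapply(1:50, function(r) {
    g <- rep(c("TBI", "nonTBI"), c(15, 18))
    Y <- matrix(rnorm(33 * 5, sd = 1), 33, 5) +
      ifelse(g == "TBI", 0, 1.5) # 1.5 SD shift on every ROI
    dat <- data.frame(g = g, Y)
    res <- mixed_anova(dat, paste0("X", 1:5), between = "g")
    res$p[res$effect == "group"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Shapiro-Wilk wrapper and its guards", {
  set.seed(77)
  ws <- vapply(1:40, function(s) normality_test(rnorm(50))$W, numeric(1))
  expect_gte(mean(ws > 0.9), 0.95)
  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_error(normality_test(rep(1, 10)), "identical")
})

test_that("Mann-Whitney agrees with exhaustive enumeration", {
  a <- c(1.2, 3.4, 0.5, 2.2)
  b <- c(5.1, 4.4, 2.9)
  got <- mann_whitney(a, b)
  expect_equal(got$p, oracle_mann_whitney_p(a, b), tolerance = 1e-12)
  # another ranking, group sizes swapped
  got2 <- mann_whitney(b, a)
  expect_equal(got2$p, got$p, tolerance = 1e-12)
  # two identical groups (structure only, no cross ties): p = 1
  x <- 1:4
  y <- c(1.5, 2.5, 3.5, 0.5)
  expect_equal(mann_whitney(x, y)$p, oracle_mann_whitney_p(x, y))
})

test_that("screening selects and reports coherently", {
  set.seed(78)
  n <- 30
  cohort <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    etiology = rep(c("TBI", "nonTBI"), each = n / 2),
    age_years = rnorm(n, 45, 10),
    gcs_baseline = 5, gos_t0 = 2, gos_t1 = rep(c(2, 3), n / 2)
  )
  features <- tibble::tibble(
    subject_id = cohort$subject_id,
    dominant_freq_hz = rnorm(n, 6) + ifelse(cohort$etiology == "TBI", -2, 0),
    peen_mean = runif(n)
  )
  for (r in doceeg:::roi_names()) {
    features[[paste0("wpli_", r)]] <- rnorm(n, 0.3, 0.05) +
      ifelse(cohort$etiology == "TBI", -0.12, 0)
    features[[paste0("mi_", r)]] <- rnorm(n, 0.2, 0.05)
    features[[paste0("pcoh_", r)]] <- rnorm(n, 0.4, 0.05)
  }
  scr <- screen_biomarkers(features, cohort, factor = "etiology")
  expect_s3_class(scr, "doc_screen")
  grp <- scr[scr$effect == "group", ]
  expect_true(grp$selected[grp$measure == "dominant_freq_hz"])
  expect_true(grp$selected[grp$measure == "wpli"])
  expect_false(grp$selected[grp$measure == "mi"])
  td <- tidy(scr)
  expect_s3_class(td, "tbl_df")
  gl <- glance(scr)
  expect_equal(gl$n_measures, nrow(grp))
  expect_equal(gl$factor, "etiology")
  # outcome factor derives labels from the GOS change
  scr2 <- screen_biomarkers(features, cohort, factor = "outcome")
  expect_s3_class(scr2, "doc_screen")
})
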