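# Group-level biomarker screening: summary-statistics t-tests, mixed
# ANOVA/ANCOVA with Greenhouse-Geisser correction, bootstrap t-tests,
# effect sizes, normality and rank tests.

#' Pooled two-sample t from printed summary statistics
#'
#' Reconstructs the Student t-test from group means, standard errors and
#' sizes: SDs are recovered as `se * sqrt(n)`, variances pooled with
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param m1,se1,n1 Mean, standard error and size of group 1.
#' @param m2,se2,n2 Mean, standard error and size of group 2.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(m1, se1, n1, m2, se2, n2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2", call. = FALSE)
  sd1 <- se1 * sqrt(n1)
  sd2 <- se2 * sqrt(n2)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Partial eta squared from an F statistic
#'
#' @param F_value F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return `F * df1 / (F * df1 + df2)`.
#' @export
partial_eta_sq <- function(F_value, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0)) stop("dfs must be positive", call. = FALSE)
  F_value * df1 / (F_value * df1 + df2)
}

#' Cohen's d from summary statistics (pooled SD)
#'
#' @param m1,sd1,n1,m2,sd2,n2 Group means, SDs and sizes.
#' @return Standardised mean difference `(m1 - m2) / pooled SD`.
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Mixed ANOVA / ANCOVA with a repeated ROI factor
#'
#' One between-subject factor (two or more groups), an optional
#' between-subject covariate, and a within-subject ROI factor given as one
#' column per level. Fitted as a multivariate linear model with Type III
#' sums of squares; within-subject effects carry Greenhouse-Geisser
#' corrected degrees of freedom and p-values. With a single response
#' column the model reduces to a one-way (An)cova. Partial eta squared is
#' computed as `F*df1 / (F*df1 + df2)` from each reported effect.
#'
#' @param data Data frame, one row per subject.
#' @param dv_cols Response column names (the 5 ROI levels, or one column).
#' @param between Name of the grouping column (factor, >= 2 levels, each
#'   with >= 2 subjects).
#' @param covariate Optional covariate column name.
#' @return Tibble: `effect`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`,
#'   `gg_epsilon` (NA for between-subject effects).
#' @export
mixed_anova <- function(data, dv_cols, between, covariate = NULL) {
  g <- factor(data[[between]])
  if (nlevels(g) < 2) stop("between factor needs at least 2 levels", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs at least 2 subjects", call. = FALSE)
  Y <- as.matrix(data[, dv_cols, drop = FALSE])
  if (anyNA(Y)) stop("missing ROI cells", call. = FALSE)
  k <- ncol(Y)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))

  if (k == 1) {
    df_fit <- data.frame(y = Y[, 1], g = g)
    form <- if (is.null(covariate)) y ~ g else {
      df_fit$cov_ <- data[[covariate]]
      y ~ cov_ + g
    }
    fit <- stats::lm(form, data = df_fit)
    av <- car::Anova(fit, type = 3)
    row <- av["g", ]
    df2 <- av["Residuals", "Df"]
    Fv <- row[["F value"]]
    return(tibble::tibble(
      effect = "group", F = Fv, df1 = row[["Df"]], df2 = df2,
      p = row[["Pr(>F)"]],
      partial_eta_sq = partial_eta_sq(Fv, row[["Df"]], df2),
      gg_epsilon = NA_real_
    ))
  }

  df_fit <- data.frame(g = g)
  rhs <- "g"
  if (!is.null(covariate)) {
    df_fit$cov_ <- data[[covariate]]
    rhs <- "cov_ + g"
  }
  fit <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = df_fit)
  idata <- data.frame(roi = factor(seq_len(k)))
  av <- car::Anova(fit, idata = idata, idesign = ~roi, type = 3)
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      # Huynh-Feldt epsilon (not used here) can exceed 1; harmless
      if (grepl("HF eps", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ut <- s$univariate.tests
  adj <- s$pval.adjustments

  pull_effect <- function(term, label) {
    if (!term %in% rownames(ut)) return(NULL)
    Fv <- ut[term, "F value"]
    df1 <- ut[term, "num Df"]
    df2 <- ut[term, "den Df"]
    p <- ut[term, "Pr(>F)"]
    eps <- NA_real_
    if (!is.null(adj) && term %in% rownames(adj)) {
      eps <- adj[term, "GG eps"]
      p <- adj[term, "Pr(>F[GG])"]
      df1 <- df1 * eps
      df2 <- df2 * eps
    }
    tibble::tibble(effect = label, F = Fv, df1 = df1, df2 = df2, p = p,
                   partial_eta_sq = partial_eta_sq(Fv, df1, df2),
                   gg_epsilon = eps)
  }
  dplyr::bind_rows(
    pull_effect("g", "group"),
    pull_effect("roi", "roi"),
    pull_effect("g:roi", "group:roi")
  )
}

#' Bootstrap two-sample t-test
#'
#' Two-sided p-value for the pooled-variance t statistic from `n_boot`
#' within-group resamples drawn under the null (both groups recentred to
#' the grand mean), plus a percentile bootstrap CI for the raw mean
#' difference. Deterministic given `seed`.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble: `t`, `df`, `p_boot`, `p_param`, `ci_lower`,
#'   `ci_upper` (95% CI of `mean(a) - mean(b)`).
#' @export
bootstrap_ttest <- function(a, b, n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  local_seed(seed)
  na <- length(a)
  nb <- length(b)
  t_stat <- function(x, y) {
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  t_obs <- t_stat(a, b)
  gm <- mean(c(a, b))
  a0 <- a - mean(a) + gm
  b0 <- b - mean(b) + gm
  ra <- matrix(sample(a0, na * n_boot, replace = TRUE), nrow = na)
  rb <- matrix(sample(b0, nb * n_boot, replace = TRUE), nrow = nb)
  ma <- colMeans(ra)
  mb <- colMeans(rb)
  va <- (colMeans(ra^2) - ma^2) * na / (na - 1)
  vb <- (colMeans(rb^2) - mb^2) * nb / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t_null <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p_boot <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_boot + 1)
  # percentile CI under resampling of the observed groups
  da <- matrix(sample(a, na * n_boot, replace = TRUE), nrow = na)
  db <- matrix(sample(b, nb * n_boot, replace = TRUE), nrow = nb)
  diffs <- colMeans(da) - colMeans(db)
  df <- na + nb - 2
  tibble::tibble(
    t = t_obs, df = df,
    p_boot = p_boot,
    p_param = 2 * stats::pt(-abs(t_obs), df),
    ci_lower = stats::quantile(diffs, 0.025, names = FALSE),
    ci_upper = stats::quantile(diffs, 0.975, names = FALSE)
  )
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric vector (>= 3 values, not all identical).
#' @return One-row tibble: `W`, `p`.
#' @export
normality_test <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs at least 3 values", call. = FALSE)
  if (stats::sd(x) < 1e-12) {
    stop("Shapiro-Wilk undefined for identical values", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  tibble::tibble(W = unname(sw$statistic), p = sw$p.value)
}

#' Mann-Whitney U test
#'
#' Exact distribution for combined n <= 25 without ties, normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric vectors.
#' @return One-row tibble: `U`, `p`.
#' @export
mann_whitney <- function(a, b) {
  exact <- (length(a) + length(b)) <= 25 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)
  )
  tibble::tibble(U = unname(wt$statistic), p = wt$p.value)
}

#' Step-1 biomarker screening
#'
#' Runs the group-level screen over all candidate EEG measures for one
#' between-subject factor: scalar qEEG measures through a one-way
#' (An)cova, connectivity estimators through the mixed model with the ROI
#' within-subject factor. A measure is selected as a biomarker when its
#' group effect is significant at `alpha` (no multiple-testing correction
#' across the family, mirroring common screening practice).
#'
#' @param features Feature table, one row per subject (see
#'   [extract_subject_features()]): scalar qEEG columns plus
#'   `<estimator>_<roi>` connectivity columns.
#' @param cohort Cohort tibble with `subject_id`, `etiology`, `age_years`,
#'   `gcs_baseline`, `gos_t0`, `gos_t1` and/or `outcome`.
#' @param factor `"etiology"` or `"outcome"`.
#' @param covariate Covariate column; by default age for the etiology
#'   factor (the groups differ in age) and none for outcome.
#' @param alpha Selection level.
#' @return A `doc_screen` object: tibble `measure`, `effect`, `F`, `df1`,
#'   `df2`, `p`, `partial_eta_sq`, `gg_epsilon`, `selected`.
#' @export
screen_biomarkers <- function(features, cohort,
                              factor = c("etiology", "outcome"),
                              covariate = if (factor[1] == "etiology")
                                "age_years" else NULL,
                              alpha = 0.05) {
  factor <- match.arg(factor)
  dat <- dplyr::inner_join(features, cohort, by = "subject_id",
                           suffix = c("", ".cohort"))
  if (factor == "outcome" && !"outcome" %in% names(dat)) {
    dat$outcome <- outcome_from_gos(dat$gos_t0, dat$gos_t1)
  }
  qeeg_cols <- intersect(
    c("dominant_freq_hz", "zpsd_delta", "zpsd_theta", "zpsd_alpha",
      "zpsd_beta", "peen_mean", "amp_mean_uv"),
    names(dat)
  )
  conn <- c("wpli", "pcoh", "mi")
  rows <- purrr::map(qeeg_cols, function(col) {
    res <- mixed_anova(dat, col, between = factor, covariate = covariate)
    dplyr::mutate(res, measure = col, .before = 1)
  })
  for (est in conn) {
    cols <- paste0(est, "_", roi_names())
    if (!all(cols %in% names(dat))) next
    res <- mixed_anova(dat, cols, between = factor, covariate = covariate)
    rows <- c(rows, list(dplyr::mutate(res, measure = est, .before = 1)))
  }
  out <- dplyr::bind_rows(rows)
  out$selected <- out$effect == "group" & out$p < alpha
  class(out) <- c("doc_screen", class(out))
  attr(out, "factor") <- factor
  attr(out, "covariate") <- covariate
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.doc_screen <- function(x, ...) {
  cat(sprintf("<doc_screen> factor = %s, covariate = %s, alpha = %g\n",
              attr(x, "factor"),
              attr(x, "covariate") %||% "none", attr(x, "alpha")))
  sel <- x$measure[x$selected]
  cat("selected biomarkers:",
      if (length(sel)) paste(sel, collapse = ", ") else "none", "\n\n")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
tidy.doc_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @importFrom generics glance
#' @export
glance.doc_screen <- function(x, ...) {
  grp <- x[x$effect == "group", ]
  tibble::tibble(
    factor = attr(x, "factor"),
    n_measures = nrow(grp),
    n_selected = sum(grp$selected),
    alpha = attr(x, "alpha")
  )
}
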