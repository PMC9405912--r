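# Outcome classification: leave-one-subject-out diagonal-covariance LDA
# with exhaustive feature-subset search, metric reporting and a logistic
# regression control.

# Diagonal-covariance LDA: classes share one diagonal covariance (feature
# correlations fully discounted); priors are training-fold class
# frequencies.
diag_lda_fit <- function(X, y, positive) {
  classes <- levels(y)
  n <- nrow(X)
  means <- matrix(0, nrow = length(classes), ncol = ncol(X),
                  dimnames = list(classes, colnames(X)))
  for (cl in classes) means[cl, ] <- colMeans(X[y == cl, , drop = FALSE])
  pooled_var <- vapply(seq_len(ncol(X)), function(j) {
    ss <- sum(vapply(classes, function(cl) {
      xs <- X[y == cl, j]
      sum((xs - mean(xs))^2)
    }, numeric(1)))
    ss / (n - length(classes))
  }, numeric(1))
  pooled_var <- pmax(pooled_var, 1e-12)
  priors <- as.numeric(table(y)[classes]) / n
  list(classes = classes, means = means, var = pooled_var,
       log_prior = log(priors), positive = positive)
}

diag_lda_score <- function(fit, X) {
  delta <- vapply(seq_along(fit$classes), function(k) {
    -0.5 * colSums((t(X) - fit$means[k, ])^2 / fit$var) + fit$log_prior[k]
  }, numeric(nrow(X)))
  delta <- matrix(delta, nrow = nrow(X))
  pos <- match(fit$positive, fit$classes)
  neg <- setdiff(seq_along(fit$classes), pos)
  list(
    predicted = fit$classes[max.col(delta, ties.method = "first")],
    score = delta[, pos] - delta[, neg] # positive-class discriminant score
  )
}

check_two_classes <- function(y) {
  if (nlevels(droplevels(y)) < 2) {
    stop("classification requires both outcome classes to be present",
         call. = FALSE)
  }
}

loo_protocol <- function(X, y, positive, fit_fun, predict_fun) {
  n <- nrow(X)
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    tr_y <- droplevels(y[-i])
    if (any(table(tr_y) < 2)) {
      stop("a class has fewer than 2 members in a training fold",
           call. = FALSE)
    }
    Xtr <- X[-i, , drop = FALSE]
    # fold-wise standardisation: fit on training statistics only
    mu <- colMeans(Xtr)
    sdv <- pmax(apply(Xtr, 2, stats::sd), 1e-12)
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- fit_fun(Xtr, tr_y, positive)
    out <- predict_fun(fit, Xte)
    pred[i] <- out$predicted
    score[i] <- out$score
  }
  list(predicted = pred, score = score)
}

classifier_report <- function(features, truth, predicted, score, positive,
                              subject_id, method) {
  neg_lab <- setdiff(levels(truth), positive)
  TP <- sum(predicted == positive & truth == positive)
  FN <- sum(predicted != positive & truth == positive)
  TN <- sum(predicted != positive & truth != positive)
  FP <- sum(predicted == positive & truth != positive)
  n <- length(truth)
  stopifnot(TP + FN + TN + FP == n)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  metrics <- tibble::tibble(
    accuracy = (TP + TN) / n,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    precision = if (TP + FP > 0) TP / (TP + FP) else NaN
  )
  # ROC by sweeping the pooled discriminant-score threshold
  ord <- order(score, decreasing = TRUE)
  tp_c <- cumsum(truth[ord] == positive)
  fp_c <- cumsum(truth[ord] != positive)
  roc <- tibble::tibble(
    fpr = c(0, fp_c / max(FP + TN, 1)),
    tpr = c(0, tp_c / max(TP + FN, 1))
  )
  confusion <- matrix(c(TP, FP, FN, TN), nrow = 2,
                      dimnames = list(predicted = c(positive, neg_lab),
                                      truth = c(positive, neg_lab)))
  structure(
    list(
      method = method,
      feature_subset = features,
      positive = positive,
      confusion = confusion,
      metrics = metrics,
      roc_points = roc,
      per_fold = tibble::tibble(subject_id = subject_id,
                                truth = as.character(truth),
                                predicted = predicted, score = score)
    ),
    class = "doc_classifier"
  )
}

#' Leave-one-subject-out diagonal LDA
#'
#' For each held-out subject, a diagonal-covariance linear discriminant
#' (shared diagonal covariance across classes; priors = training-fold
#' class frequencies) is fitted on the remaining subjects, with
#' feature standardisation recomputed inside each fold, and the held-out
#' label predicted. Metrics come from the pooled LOO confusion matrix, the
#' ROC from the pooled discriminant scores. The positive class is the
#' nonimproved outcome.
#'
#' @param data Data frame with one row per subject: the feature columns,
#'   an outcome column and optionally `subject_id`.
#' @param features Character vector of feature column names.
#' @param outcome_col Name of the class column.
#' @param positive Positive class label.
#' @return A `doc_classifier` report: confusion matrix, metrics
#'   (accuracy, sensitivity, specificity, balanced accuracy, precision),
#'   ROC points and per-fold predictions.
#' @export
lda_loo <- function(data, features, outcome_col = "outcome",
                    positive = "nonimproved") {
  if (length(features) == 0) stop("feature subset must be non-empty", call. = FALSE)
  X <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(X)) stop("missing feature values", call. = FALSE)
  y <- factor(data[[outcome_col]])
  check_two_classes(y)
  res <- loo_protocol(X, y, positive, diag_lda_fit, diag_lda_score)
  classifier_report(features, y, res$predicted, res$score, positive,
                    if ("subject_id" %in% names(data)) data$subject_id
                    else sprintf("s%02d", seq_len(nrow(X))),
                    method = "diag-LDA")
}

#' Exhaustive stepwise feature-subset search
#'
#' Evaluates every non-empty subset of up to 10 candidate features by LOO
#' accuracy (use `method = "greedy"` forward selection for larger pools).
#' Ties break by higher balanced accuracy, then fewer features, then
#' lexicographic order.
#'
#' @param data,outcome_col,positive As [lda_loo()].
#' @param candidates Candidate feature names (1-10 for exhaustive search).
#' @param method `"exhaustive"` or `"greedy"`.
#' @return A `doc_search`: list with `best` (the winning `doc_classifier`)
#'   and `ranking` (tibble of all evaluated subsets).
#' @export
stepwise_search <- function(data, candidates, outcome_col = "outcome",
                            positive = "nonimproved",
                            method = c("exhaustive", "greedy")) {
  method <- match.arg(method)
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  if (method == "exhaustive" && length(candidates) > 10) {
    stop("more than 10 candidates: use method = \"greedy\"", call. = FALSE)
  }
  subsets <- if (method == "exhaustive") {
    unlist(lapply(seq_along(candidates), function(k) {
      utils::combn(candidates, k, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    greedy_path(data, candidates, outcome_col, positive)
  }
  reports <- lapply(subsets, function(s) {
    lda_loo(data, s, outcome_col = outcome_col, positive = positive)
  })
  ranking <- dplyr::bind_rows(lapply(reports, function(r) {
    dplyr::bind_cols(
      tibble::tibble(
        features = paste(sort(r$feature_subset), collapse = "+"),
        n_features = length(r$feature_subset)
      ),
      r$metrics
    )
  }))
  ord <- order(-ranking$accuracy, -ranking$balanced_accuracy,
               ranking$n_features, ranking$features)
  ranking <- ranking[ord, ]
  structure(list(best = reports[[ord[1]]], ranking = ranking),
            class = "doc_search")
}

greedy_path <- function(data, candidates, outcome_col, positive) {
  chosen <- character(0)
  path <- list()
  pool <- candidates
  while (length(pool) > 0) {
    accs <- vapply(pool, function(f) {
      lda_loo(data, c(chosen, f), outcome_col, positive)$metrics$accuracy
    }, numeric(1))
    chosen <- c(chosen, pool[which.max(accs)])
    pool <- setdiff(pool, chosen)
    path <- c(path, list(chosen))
  }
  path
}

#' @export
print.doc_search <- function(x, ...) {
  cat("<doc_search> best subset:",
      paste(x$best$feature_subset, collapse = " + "), "\n")
  print(x$best)
  invisible(x)
}

#' Classification metrics from printed rates
#'
#' Reconstructs the report-level metrics from published sensitivity and
#' specificity: `TP = round(sens * n_pos)`, `TN = round(spec * n_neg)`,
#' accuracy `(TP + TN) / (n_pos + n_neg)`, balanced accuracy
#' `(sens + spec) / 2`, precision `TP / (TP + (n_neg - TN))`.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_pos,n_neg Positive/negative class sizes.
#' @return One-row tibble: `accuracy`, `balanced_accuracy`, `precision`.
#' @export
metrics_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be positive", call. = FALSE)
  TP <- round(sensitivity * n_pos)
  TN <- round(specificity * n_neg)
  if (TP + (n_neg - TN) == 0) stop("zero predicted positives", call. = FALSE)
  tibble::tibble(
    accuracy = (TP + TN) / (n_pos + n_neg),
    balanced_accuracy = (sensitivity + specificity) / 2,
    precision = TP / (TP + (n_neg - TN))
  )
}

# Ridge-penalised logistic fit by Newton iterations; fallback under
# perfect separation.
ridge_logistic <- function(X, y01, lambda = 1e-4, maxit = 50) {
  Xd <- cbind(1, X)
  beta <- numeric(ncol(Xd))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p) + 1e-10
    H <- crossprod(Xd, Xd * W) + pen
    gr <- crossprod(Xd, y01 - p) - pen %*% beta
    step <- solve(H, gr)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' Leave-one-subject-out logistic regression control
#'
#' The same LOO protocol as [lda_loo()] with a maximum-likelihood
#' multivariate logistic model; a training fold with perfect separation
#' falls back to a ridge-penalised fit (penalty 1e-4) with a warning. The
#' report is formatted identically to the LDA report for side-by-side
#' comparison.
#'
#' @inheritParams lda_loo
#' @return A `doc_classifier` report.
#' @export
logistic_loo <- function(data, features, outcome_col = "outcome",
                         positive = "nonimproved") {
  if (length(features) == 0) stop("feature subset must be non-empty", call. = FALSE)
  X <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(X)) stop("missing feature values", call. = FALSE)
  y <- factor(data[[outcome_col]])
  check_two_classes(y)
  fit_fun <- function(Xtr, ytr, pos) {
    y01 <- as.integer(ytr == pos)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, Xtr), y01, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    beta <- if (sep || !fit$converged) {
      warning("perfect separation in a training fold: ridge-penalised fit used",
              call. = FALSE)
      ridge_logistic(Xtr, y01)
    } else {
      fit$coefficients
    }
    list(beta = beta, classes = levels(ytr), positive = pos)
  }
  predict_fun <- function(fit, Xte) {
    eta <- drop(cbind(1, Xte) %*% fit$beta)
    neg <- setdiff(fit$classes, fit$positive)
    list(predicted = ifelse(eta > 0, fit$positive, neg), score = eta)
  }
  res <- loo_protocol(X, y, positive, fit_fun, predict_fun)
  classifier_report(features, y, res$predicted, res$score, positive,
                    if ("subject_id" %in% names(data)) data$subject_id
                    else sprintf("s%02d", seq_len(nrow(X))),
                    method = "logistic")
}

#' @export
print.doc_classifier <- function(x, ...) {
  cat(sprintf("<doc_classifier> %s on {%s}, positive = %s\n", x$method,
              paste(x$feature_subset, collapse = ", "), x$positive))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf(
    "accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%% | balanced %.1f%% | precision %.1f%%\n",
    100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity,
    100 * m$balanced_accuracy, 100 * m$precision
  ))
  invisible(x)
}

#' @export
tidy.doc_classifier <- function(x, ...) {
  x$per_fold
}

#' @export
glance.doc_classifier <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method,
                   features = paste(sort(x$feature_subset), collapse = "+"),
                   n = nrow(x$per_fold)),
    x$metrics
  )
}

#' @export
autoplot.doc_classifier <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("LOO ROC: %s (%s)",
                      paste(object$feature_subset, collapse = " + "),
                      object$method)
    ) +
    ggplot2::theme_minimal()
}
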