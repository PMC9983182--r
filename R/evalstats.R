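#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval obtained by inverting the binomial tail probabilities,
#' computed through the beta-quantile closed form. The lower bound is 0 when
#' there are no successes and the upper bound 1 when every trial succeeded.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1`.
#' @param conf.level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(successes, trials, conf.level = 0.95) {
  check_field(
    is.numeric(trials) && length(trials) == 1 && trials >= 1,
    "trials", "must be a count >= 1"
  )
  check_field(
    is.numeric(successes) && length(successes) == 1 &&
      successes >= 0 && successes <= trials,
    "successes", "must be a count in 0..trials"
  )
  check_field(conf.level > 0 && conf.level < 1, "conf.level", "must be in (0, 1)")
  alpha <- 1 - conf.level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

as_confusion_tbl <- function(folds) {
  if (inherits(folds, "data.frame")) {
    tbl <- tibble::as_tibble(folds)
  } else {
    tbl <- purrr::map_dfr(folds, function(f) tibble::as_tibble(as.list(f)))
  }
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(tbl)))
  tbl
}

#' Pooled (micro-averaged) accuracy, sensitivity and specificity
#'
#' Cross-validation metrics computed from the *summed* per-fold confusion
#' counts, equivalent to concatenating all folds' predictions into one
#' confusion matrix:
#' accuracy = sum(TP + TN) / sum(TP + TN + FP + FN),
#' sensitivity = sum(TP) / sum(TP + FN),
#' specificity = sum(TN) / sum(TN + FP).
#' Exact binomial confidence intervals treat each formula's denominator as
#' the trial count and its numerator as the success count.
#'
#' @param folds Per-fold confusion counts: a data frame with columns `TP`,
#'   `TN`, `FP`, `FN`, or a list of named vectors with those entries.
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble with one row per metric: `metric`, `successes`,
#'   `trials`, `estimate`, `lower`, `upper`. A metric whose pooled
#'   denominator is zero raises a condition of class
#'   `augsplit_undefined_metric`.
#' @export
pooled_proportion_metrics <- function(folds, conf.level = 0.95) {
  tbl <- as_confusion_tbl(folds)
  TP <- sum(tbl$TP)
  TN <- sum(tbl$TN)
  FP <- sum(tbl$FP)
  FN <- sum(tbl$FN)
  defs <- list(
    accuracy = c(TP + TN, TP + TN + FP + FN),
    sensitivity = c(TP, TP + FN),
    specificity = c(TN, TN + FP)
  )
  purrr::map_dfr(names(defs), function(metric) {
    s <- defs[[metric]][1]
    n <- defs[[metric]][2]
    if (n == 0) {
      abort(sprintf("metric '%s' is undefined: its pooled denominator is zero", metric),
        class = "augsplit_undefined_metric"
      )
    }
    ci <- exact_binomial_ci(s, n, conf.level)
    tibble::tibble(
      metric = metric, successes = s, trials = n,
      estimate = s / n, lower = ci[["lower"]], upper = ci[["upper"]]
    )
  })
}

#' Pooled ROC AUC over the cross-validation folds
#'
#' The prediction probabilities of all folds' test images are pooled before
#' the ROC analysis, so the AUC equals the probability that a randomly
#' chosen positive outranks a randomly chosen negative (ties counting
#' one-half) *across folds* — a model whose probability scales are
#' inconsistent between folds is penalized, unlike when per-fold AUCs are
#' averaged. The default confidence interval uses the DeLong
#' placement-variance estimate; `ci_method = "exact"` instead treats the
#' AUC as a proportion of concordant pairs and applies the exact binomial
#' interval.
#'
#' @param prob_positive Pooled positive-class probabilities (or any
#'   monotone scores).
#' @param labels Parallel vector of `"positive"` / `"negative"` labels (or
#'   a logical/0-1 vector marking positives).
#' @param conf.level Confidence level (default 0.95).
#' @param ci_method `"delong"` (default) or `"exact"`.
#' @return A list: `auc`, `lower`, `upper`, `n_pos`, `n_neg`, `ci_method`.
#' @export
pooled_roc_auc <- function(prob_positive, labels, conf.level = 0.95,
                           ci_method = c("delong", "exact")) {
  ci_method <- match.arg(ci_method)
  if (is.character(labels)) labels <- labels == "positive"
  y <- as.logical(labels)
  stopifnot(length(prob_positive) == length(y))
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined: the pooled labels contain a single class",
      class = "augsplit_undefined_metric"
    )
  }
  r <- rank(prob_positive) # midranks handle ties as one-half
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (ci_method == "delong") {
    pos <- prob_positive[y]
    neg <- prob_positive[!y]
    # placement values: for each positive, fraction of negatives it beats
    v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
    v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
    se <- sqrt(var_or_zero(v10) / n_pos + var_or_zero(v01) / n_neg)
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    pairs <- n_pos * n_neg
    ci <- unname(exact_binomial_ci(round(auc * pairs), pairs, conf.level))
  }
  list(
    auc = auc, lower = ci[[1]], upper = ci[[2]],
    n_pos = n_pos, n_neg = n_neg, ci_method = ci_method
  )
}

var_or_zero <- function(x) if (length(x) > 1) stats::var(x) else 0

#' Mean of per-fold measurements with a Student-t confidence interval
#'
#' For k per-fold values (k = 5 under five-fold cross-validation, so 4
#' degrees of freedom), the interval is
#' `mean +/- t(1 - alpha/2, k - 1) * sd / sqrt(k)`.
#'
#' @param values Numeric vector of per-fold measurements, length >= 2.
#' @param conf.level Confidence level (default 0.95).
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
mean_t_ci <- function(values, conf.level = 0.95) {
  k <- length(values)
  if (k < 2) {
    abort("a t-based confidence interval needs at least 2 values",
      class = "augsplit_undefined_metric"
    )
  }
  m <- mean(values)
  half <- qt(1 - (1 - conf.level) / 2, df = k - 1) * sd(values) / sqrt(k)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Restrict testing groups to those entering the time-cost analysis
#'
#' Drops the augment-first groups (way F, whose metrics are optimistic by
#' construction) and the non-augmented-test-set metrics, the exclusions
#' applied before correlating performance with training time. With 4
#' classifiers and all ways present, 20 groups remain.
#'
#' @param groups A tibble with at least columns `way` and `test_condition`.
#' @return The filtered tibble.
#' @export
filter_time_cost_groups <- function(groups) {
  dplyr::filter(groups, .data$way != "F", .data$test_condition == "augmented")
}

#' Correlation of performance metrics with log mean training time
#'
#' Within each classifier stratum, Pearson's correlation between a
#' performance metric and the natural logarithm of the mean training time
#' (the log transform reflects that the metrics are bounded above while
#' time is not), with the two-sided p-value from the t-test on r with
#' n - 2 degrees of freedom and the fitted least-squares line. The caller
#' supplies groups already filtered with [filter_time_cost_groups()].
#'
#' @param groups A tibble with columns `classifier`, `mean_time` (strictly
#'   positive) and the metric column.
#' @param metric Name of the metric column (e.g. `"accuracy"`).
#' @return A tibble: `classifier`, `metric`, `n`, `pearson_r`, `p_value`,
#'   `slope`, `intercept`.
#' @export
time_cost_correlation <- function(groups, metric) {
  stopifnot(metric %in% names(groups), all(groups$mean_time > 0))
  purrr::map_dfr(split(groups, groups$classifier), function(g) {
    if (nrow(g) < 3) {
      abort("each classifier stratum needs at least 3 groups",
        class = "augsplit_parameter_error"
      )
    }
    x <- log(g$mean_time)
    y <- g[[metric]]
    if (sd(x) == 0 || sd(y) == 0) {
      abort("correlation undefined: zero variance in metric or log-time",
        class = "augsplit_undefined_metric"
      )
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    fit <- stats::lm(y ~ x)
    tibble::tibble(
      classifier = g$classifier[1], metric = metric, n = nrow(g),
      pearson_r = unname(ct$estimate), p_value = ct$p.value,
      slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1])
    )
  })
}

#' Exact one-sided paired sign-flip test
#'
#' Resampling check for directional paired comparisons across replicate
#' seeds: under the null of no direction, each paired difference is equally
#' likely to carry either sign. All `2^n` sign assignments are enumerated
#' (up to `n = 20`), and the p-value is the fraction of assignments whose
#' mean difference is at least the observed one.
#'
#' @param x,y Paired numeric vectors; the alternative is `mean(x - y) > 0`.
#' @return The exact one-sided p-value.
#' @export
paired_sign_flip_test <- function(x, y) {
  d <- x - y
  n <- length(d)
  stopifnot(n >= 2, n <= 20, length(y) == n)
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- drop(signs %*% d) / n
  mean(perm >= obs - 1e-12)
}

#' Pool the fold results of one testing group into its summary metrics
#'
#' Convenience wrapper combining the pooled proportion metrics, the pooled
#' ROC AUC, the validation accuracy pooled over folds, and the t-based
#' summaries of epoch counts and training times for one `way_result` under
#' one test-set condition.
#'
#' @param way_result A result of [run_experiment()].
#' @param test_condition `"original"` or `"augmented"`.
#' @param conf.level Confidence level (default 0.95).
#' @param ci_method AUC confidence-interval method, see [pooled_roc_auc()].
#' @return A one-row tibble of group summaries.
#' @export
pool_fold_results <- function(way_result, test_condition = "augmented",
                              conf.level = 0.95, ci_method = "delong") {
  folds <- way_result$folds
  tests <- lapply(folds, function(f) f$tests[[test_condition]])
  if (any(vapply(tests, is.null, logical(1)))) {
    abort(sprintf(
      "way %s has no '%s' test evaluations", way_result$way, test_condition
    ), class = "augsplit_parameter_error")
  }
  conf <- purrr::map_dfr(tests, function(tt) tibble::as_tibble(as.list(tt$confusion)))
  props <- pooled_proportion_metrics(conf, conf.level)
  probs <- dplyr::bind_rows(lapply(tests, function(tt) tt$probabilities))
  auc_res <- pooled_roc_auc(probs$prob_positive, probs$true_label, conf.level, ci_method)
  val_succ <- sum(vapply(folds, function(f) f$validation_successes, numeric(1)))
  val_tri <- sum(vapply(folds, function(f) f$validation_trials, numeric(1)))
  val_ci <- exact_binomial_ci(val_succ, val_tri, conf.level)
  epochs <- vapply(folds, function(f) f$epoch_count, numeric(1))
  times <- vapply(folds, function(f) f$training_time, numeric(1))
  ep <- mean_t_ci(epochs, conf.level)
  tm <- mean_t_ci(times, conf.level)
  leak <- function(field) sum(vapply(folds, function(f) f$leakage[[field]], numeric(1)))
  row <- function(metric) props[props$metric == metric, ]
  tibble::tibble(
    classifier = way_result$classifier %||% NA_character_,
    way = way_result$way,
    test_condition = test_condition,
    n_folds = length(folds),
    accuracy = row("accuracy")$estimate,
    accuracy_lower = row("accuracy")$lower,
    accuracy_upper = row("accuracy")$upper,
    sensitivity = row("sensitivity")$estimate,
    sensitivity_lower = row("sensitivity")$lower,
    sensitivity_upper = row("sensitivity")$upper,
    specificity = row("specificity")$estimate,
    specificity_lower = row("specificity")$lower,
    specificity_upper = row("specificity")$upper,
    auc = auc_res$auc, auc_lower = auc_res$lower, auc_upper = auc_res$upper,
    validation_accuracy = val_succ / val_tri,
    validation_lower = val_ci[["lower"]],
    validation_upper = val_ci[["upper"]],
    mean_epochs = ep[["mean"]],
    epochs_lower = ep[["lower"]], epochs_upper = ep[["upper"]],
    mean_time = tm[["mean"]],
    time_lower = tm[["lower"]], time_upper = tm[["upper"]],
    leak_train_val = leak("parents_train_val"),
    leak_train_test = leak("parents_train_test"),
    leak_val_test = leak("parents_val_test")
  )
}
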