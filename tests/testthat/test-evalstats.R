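test_that("pooled proportion metrics follow the summed-count formulas", {
  perfect <- data.frame(TP = rep(10, 5), TN = rep(10, 5), FP = 0, FN = 0)
  m <- pooled_proportion_metrics(perfect)
  expect_equal(m$estimate, c(1, 1, 1))

  five <- data.frame(TP = rep(3, 5), TN = rep(2, 5), FP = rep(1, 5), FN = rep(2, 5))
  m2 <- pooled_proportion_metrics(five)
  expect_equal(m2$estimate[m2$metric == "accuracy"], 25 / 40)
  expect_equal(m2$estimate[m2$metric == "sensitivity"], 15 / 25)
  expect_equal(m2$estimate[m2$metric == "specificity"], 10 / 15)

  # no positives anywhere: sensitivity is undefined
  negs <- data.frame(TP = 0, TN = 5, FP = 2, FN = 0)
  expect_error(pooled_proportion_metrics(negs), "sensitivity",
    class = "augsplit_undefined_metric"
  )
})

test_that("pooled metrics equal the micro-averaged concatenation oracle", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    conf <- data.frame(
      TP = rpois(k, 5) + 1, TN = rpois(k, 5) + 1,
      FP = rpois(k, 2), FN = rpois(k, 2)
    )
    m <- pooled_proportion_metrics(conf)
    oracle <- micro_average_oracle(conf)
    expect_equal(m$estimate, unname(oracle[m$metric]))
  }
})

test_that("Clopper-Pearson bounds match the tail-sum bisection oracle to 1e-6", {
  cases <- rbind(
    expand.grid(s = c(0, 1, 5, 10, 19, 20), n = 20),
    data.frame(s = c(0, 3, 57, 200), n = 200)
  )
  set.seed(7)
  extra_n <- sample(5:500, 20)
  cases <- rbind(cases, data.frame(s = vapply(extra_n, function(n) sample(0:n, 1), numeric(1)), n = extra_n))
  for (i in seq_len(nrow(cases))) {
    s <- cases$s[i]
    n <- cases$n[i]
    got <- exact_binomial_ci(s, n)
    want <- cp_bisection_oracle(s, n)
    expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-6)
    expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-6)
  }
  expect_equal(exact_binomial_ci(0, 20)[["lower"]], 0)
  expect_equal(exact_binomial_ci(20, 20)[["upper"]], 1)
  expect_error(exact_binomial_ci(5, 4), "successes", class = "augsplit_parameter_error")
})

test_that("the exact interval is conservative: simulated coverage at least 95%", {
  set.seed(2024)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(20, 200)) {
      draws <- rbinom(2000, n, p)
      lower <- ifelse(draws == 0, 0, qbeta(0.025, draws, n - draws + 1))
      upper <- ifelse(draws == n, 1, qbeta(0.975, draws + 1, n - draws))
      expect_gte(mean(lower <= p & p <= upper), 0.95)
    }
  }
})

test_that("pooled AUC equals exhaustive pair counting, including ties", {
  perfect <- pooled_roc_auc(c(0.9, 0.8, 0.2, 0.1), c("positive", "positive", "negative", "negative"))
  expect_equal(perfect$auc, 1)
  ties <- pooled_roc_auc(rep(0.5, 10), rep(c("positive", "negative"), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(pooled_roc_auc(runif(5), rep("positive", 5)),
    class = "augsplit_undefined_metric"
  )

  set.seed(11)
  for (rep in 1:30) {
    n <- sample(4:50, 1)
    labels <- c("positive", "negative", sample(c("positive", "negative"), n - 2, replace = TRUE))
    probs <- round(runif(n), sample(c(1, 2), 1)) # coarse rounding forces ties
    got <- pooled_roc_auc(probs, labels)
    expect_equal(got$auc, auc_pair_oracle(probs, labels))
    expect_gte(got$auc, got$lower)
    expect_lte(got$auc, got$upper)
  }
})

test_that("the DeLong interval agrees with the independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- sample(c("positive", "negative"), 60, replace = TRUE, prob = c(0.5, 0.5))
  probs <- runif(60) + 0.4 * (labels == "positive")
  got <- pooled_roc_auc(probs, labels)
  ref <- pROC::ci.auc(
    pROC::roc(labels, probs, levels = c("negative", "positive"), direction = "<", quiet = TRUE),
    method = "delong"
  )
  expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(got$lower, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(got$upper, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("pooling penalizes fold-wise miscalibration that per-fold AUC hides", {
  # two folds, each perfectly separated within itself, on disjoint ranges
  fold1 <- list(probs = c(0.40, 0.45, 0.30, 0.35), labels = c("positive", "positive", "negative", "negative"))
  fold2 <- list(probs = c(0.80, 0.85, 0.60, 0.70), labels = c("positive", "positive", "negative", "negative"))
  per_fold <- vapply(
    list(fold1, fold2),
    function(f) pooled_roc_auc(f$probs, f$labels)$auc, numeric(1)
  )
  expect_equal(mean(per_fold), 1)
  pooled <- pooled_roc_auc(c(fold1$probs, fold2$probs), c(fold1$labels, fold2$labels))
  expect_lt(pooled$auc, 1)
})

test_that("eight-fold test augmentation shrinks the exact interval width beyond half", {
  for (s in c(15, 60, 150)) {
    n <- 200
    w1 <- diff(exact_binomial_ci(s, n))
    w8 <- diff(exact_binomial_ci(8 * s, 8 * n))
    expect_lt(w8 / w1, 0.5) # approaches 1/sqrt(8) ~ 0.354
  }
})

test_that("t-based fold summaries match an independent quantile route", {
  expect_equal(unname(mean_t_ci(rep(3.3, 5))), c(3.3, 3.3, 3.3))
  v <- c(1, 2, 3, 4, 5)
  got <- mean_t_ci(v)
  # independent t quantile via the F distribution: T^2 ~ F(1, 4)
  t975 <- sqrt(qf(0.95, 1, 4))
  half <- t975 * sd(v) / sqrt(5)
  expect_equal(got[["mean"]], 3)
  expect_equal(got[["upper"]] - got[["mean"]], half, tolerance = 1e-10)
  # width shrinks to zero as the level drops to nothing
  expect_lt(
    diff(mean_t_ci(v, conf.level = 0.01)[c("lower", "upper")]),
    diff(mean_t_ci(v, conf.level = 0.95)[c("lower", "upper")])
  )
  expect_error(mean_t_ci(3), class = "augsplit_undefined_metric")
})

test_that("time-cost correlation matches the covariance formula and filters to 20 groups", {
  # exact linear relation: r = 1 with a vanishing p-value
  g <- tibble::tibble(
    classifier = "one", way = c("A", "B", "C", "D", "E"),
    test_condition = "augmented",
    mean_time = c(10, 20, 40, 80, 160),
    accuracy = 0.5 + 0.05 * log(c(10, 20, 40, 80, 160))
  )
  res <- time_cost_correlation(g, "accuracy")
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)
  expect_equal(res$slope, 0.05, tolerance = 1e-12)

  set.seed(3)
  g2 <- dplyr::mutate(g, accuracy = runif(5, 0.6, 0.9))
  res2 <- time_cost_correlation(g2, "accuracy")
  x <- log(g2$mean_time)
  y <- g2$accuracy
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$pearson_r, r_direct, tolerance = 1e-12)

  # the exclusion helper: 4 classifiers x 11 protocols -> 20 groups
  all_groups <- tidyr::expand_grid(
    classifier = paste0("cnn", 1:4),
    enumerate_protocols()[, c("way", "test_augmented")]
  )
  all_groups$test_condition <- ifelse(all_groups$test_augmented, "augmented", "original")
  expect_equal(nrow(filter_time_cost_groups(all_groups)), 20)

  flat <- dplyr::mutate(g, accuracy = 0.7)
  expect_error(time_cost_correlation(flat, "accuracy"), class = "augsplit_undefined_metric")
})

test_that("the sign-flip test is exact for consistent paired differences", {
  x <- c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  y <- x - 1
  expect_equal(paired_sign_flip_test(x, y), 1 / 2^10)
  # no direction: p is large
  set.seed(1)
  a <- rnorm(10)
  expect_gt(paired_sign_flip_test(a, a + rnorm(10, 0, 1e-3) * sample(c(-1, 1), 10, TRUE)), 0.05)
})
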