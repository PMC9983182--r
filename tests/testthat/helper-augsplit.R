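# Shared fixtures: all built in code at test time.

make_ds <- function(n_per_class = 20, seed = 1, image_size = 16, ...) {
  generate_synthetic_dataset(synth_params(
    n_per_class = n_per_class, image_size = image_size, seed = seed, ...
  ))
}

# Stub classifier whose validation accuracy follows a fixed schedule,
# regardless of the data: epoch t scores acc_schedule[min(t, length))].
# featurize() leaks the labels so predict_proba can hit any target accuracy.
schedule_classifier <- function(acc_schedule) {
  new_classifier(
    name = "schedule_stub",
    featurize = function(records) {
      matrix(as.numeric(records$class_label == "positive"), ncol = 1)
    },
    init = function(n_features, seed) list(epoch = 0L),
    train_epoch = function(model, X, y, cfg) {
      model$epoch <- model$epoch + 1L
      model
    },
    predict_proba = function(model, X) {
      a <- acc_schedule[min(max(model$epoch, 1L), length(acc_schedule))]
      y <- X[, 1]
      n <- length(y)
      n_right <- round(a * n)
      right <- seq_len(n) <= n_right
      ifelse(right, ifelse(y == 1, 0.9, 0.1), ifelse(y == 1, 0.1, 0.9))
    }
  )
}

# Classifier that returns fixed probabilities by record position.
fixed_prob_classifier <- function(probs) {
  new_classifier(
    name = "fixed_prob",
    featurize = function(records) matrix(0, nrow(records), 1),
    init = function(n_features, seed) list(),
    train_epoch = function(model, X, y, cfg) model,
    predict_proba = function(model, X) probs[seq_len(nrow(X))]
  )
}

# Classifier violating the probability contract.
broken_classifier <- function() {
  new_classifier(
    name = "broken",
    featurize = function(records) matrix(0, nrow(records), 1),
    init = function(n_features, seed) list(),
    train_epoch = function(model, X, y, cfg) model,
    predict_proba = function(model, X) rep(2, nrow(X))
  )
}

# Micro-averaging oracle: concatenate explicit per-record outcomes across
# folds and compute the three proportion metrics directly.
micro_average_oracle <- function(conf_tbl) {
  y <- integer(0)
  pred <- integer(0)
  for (i in seq_len(nrow(conf_tbl))) {
    r <- conf_tbl[i, ]
    y <- c(y, rep(1, r$TP), rep(0, r$TN), rep(0, r$FP), rep(1, r$FN))
    pred <- c(pred, rep(1, r$TP), rep(0, r$TN), rep(1, r$FP), rep(0, r$FN))
  }
  c(
    accuracy = mean(pred == y),
    sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
    specificity = sum(pred == 0 & y == 0) / sum(y == 0)
  )
}

# Clopper-Pearson oracle: invert the binomial tail sums by bisection.
cp_bisection_oracle <- function(s, n, conf.level = 0.95) {
  alpha <- 1 - conf.level
  lower <- if (s == 0) 0 else {
    uniroot(function(p) 1 - pbinom(s - 1, n, p) - alpha / 2,
      c(1e-12, 1 - 1e-12), tol = 1e-10
    )$root
  }
  upper <- if (s == n) 1 else {
    uniroot(function(p) pbinom(s, n, p) - alpha / 2,
      c(1e-12, 1 - 1e-12), tol = 1e-10
    )$root
  }
  c(lower = lower, upper = upper)
}

# AUC oracle: exhaustive pair counting with ties worth one half.
auc_pair_oracle <- function(probs, labels) {
  pos <- probs[labels == "positive" | labels == TRUE | labels == 1]
  neg <- probs[!(labels == "positive" | labels == TRUE | labels == 1)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
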