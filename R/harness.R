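#' Training schedule configuration
#'
#' Defaults follow the benchmark schedule: stochastic gradient descent with
#' momentum 0.9 and learning rate 1e-4 on mini-batches of 10 images, L2
#' regularization factor 1e-4, the training set reshuffled at the start of
#' every epoch, validation accuracy computed after each epoch, and training
#' stopped once 5 consecutive epochs fail to improve the best validation
#' accuracy or 50 epochs are reached.
#'
#' @param minibatch_size Images per mini-batch (default 10).
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param l2_factor L2 regularization factor (default 1e-4).
#' @param max_epochs Epoch budget (default 50).
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping (default 5); must be below `max_epochs`.
#' @param classification_threshold Probability threshold for calling the
#'   positive class; a probability exactly at the threshold counts as
#'   positive. Default 0.5.
#' @param seed Integer seed for epoch shuffling and model initialization.
#' @return An object of class `training_config`.
#' @export
training_config <- function(minibatch_size = 10L, learning_rate = 1e-4,
                            momentum = 0.9, l2_factor = 1e-4,
                            max_epochs = 50L, patience = 5L,
                            classification_threshold = 0.5, seed = 1L) {
  check_field(minibatch_size >= 1, "minibatch_size", "must be >= 1")
  check_field(learning_rate > 0, "learning_rate", "must be > 0")
  check_field(momentum >= 0 && momentum < 1, "momentum", "must be in [0, 1)")
  check_field(l2_factor >= 0, "l2_factor", "must be >= 0")
  check_field(max_epochs >= 1, "max_epochs", "must be >= 1")
  check_field(
    patience >= 1 && patience < max_epochs, "patience",
    "must be >= 1 and below max_epochs"
  )
  check_field(
    classification_threshold > 0 && classification_threshold < 1,
    "classification_threshold", "must be strictly between 0 and 1"
  )
  structure(list(
    minibatch_size = as.integer(minibatch_size), learning_rate = learning_rate,
    momentum = momentum, l2_factor = l2_factor,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    classification_threshold = classification_threshold, seed = as.integer(seed)
  ), class = "training_config")
}

label01 <- function(records) as.numeric(records$class_label == "positive")

check_probabilities <- function(p, n) {
  if (!is.numeric(p) || length(p) != n || anyNA(p) || any(p < 0 | p > 1)) {
    abort("classifier contract violated: predict_proba must return one probability in [0,1] per record",
      class = "augsplit_contract_error"
    )
  }
  invisible(p)
}

#' Train a classifier with validation-gated early stopping
#'
#' Runs mini-batch epochs over the (per-epoch reshuffled) training set.
#' After each epoch the validation accuracy at the classification threshold
#' is computed; an epoch "improves the model" when it strictly exceeds the
#' best validation accuracy seen so far. Training stops when `patience`
#' consecutive epochs fail to improve, or at `max_epochs`. The returned
#' model is the best-validation-accuracy checkpoint.
#'
#' @param classifier An `augsplit_classifier`.
#' @param train,validation Non-empty `labeled_dataset`s; the validation set
#'   must contain both classes.
#' @param cfg A [training_config()].
#' @return A list: `model` (best checkpoint), `epoch_count`,
#'   `training_time` (wall-clock seconds), `validation_trace` (per-epoch
#'   accuracies), `validation_accuracy`, `validation_successes`,
#'   `validation_trials`.
#' @export
train_with_early_stopping <- function(classifier, train, validation, cfg) {
  if (n_records(train) == 0 || n_records(validation) == 0) {
    abort("train and validation must be non-empty", class = "augsplit_parameter_error")
  }
  if (length(unique(validation$records$class_label)) < 2) {
    abort("validation set must contain both classes", class = "augsplit_parameter_error")
  }
  t0 <- proc.time()[["elapsed"]]
  Xtr <- classifier$featurize(train$records)
  ytr <- label01(train$records)
  Xva <- classifier$featurize(validation$records)
  yva <- label01(validation$records)
  n_tr <- nrow(Xtr)
  n_va <- nrow(Xva)

  model <- classifier$init(ncol(Xtr), derive_seed(cfg$seed, "init"))
  best_acc <- -Inf
  best_model <- model
  best_correct <- 0L
  since_improve <- 0L
  trace <- numeric(0)
  epoch <- 0L

  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    ord <- withr::with_seed(
      derive_seed(cfg$seed, "epoch", epoch),
      sample.int(n_tr)
    )
    model <- classifier$train_epoch(model, Xtr[ord, , drop = FALSE], ytr[ord], cfg)
    p <- check_probabilities(classifier$predict_proba(model, Xva), n_va)
    correct <- sum((p >= cfg$classification_threshold) == (yva == 1))
    acc <- correct / n_va
    trace <- c(trace, acc)
    if (acc > best_acc) {
      best_acc <- acc
      best_model <- model
      best_correct <- correct
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    if (since_improve >= cfg$patience) break
  }

  list(
    model = best_model,
    epoch_count = epoch,
    training_time = proc.time()[["elapsed"]] - t0,
    validation_trace = trace,
    validation_accuracy = best_acc,
    validation_successes = best_correct,
    validation_trials = n_va
  )
}

#' Evaluate a trained model on a test set
#'
#' Retains the per-record positive-class probabilities and computes the
#' confusion counts, with predicted-positive defined as probability greater
#' than or equal to the threshold.
#'
#' @param classifier The `augsplit_classifier` the model came from.
#' @param model A trained model state.
#' @param test A non-empty `labeled_dataset`.
#' @param threshold Classification probability threshold (default 0.5).
#' @return A list: `confusion` (named vector `TP`, `TN`, `FP`, `FN`) and
#'   `probabilities`, a tibble `image_id`, `true_label`, `prob_positive`.
#' @export
evaluate_on_test <- function(classifier, model, test, threshold = 0.5) {
  if (n_records(test) == 0) {
    abort("test set must be non-empty", class = "augsplit_parameter_error")
  }
  X <- classifier$featurize(test$records)
  y <- label01(test$records)
  p <- check_probabilities(classifier$predict_proba(model, X), length(y))
  pred <- as.numeric(p >= threshold)
  list(
    confusion = c(
      TP = sum(pred == 1 & y == 1), TN = sum(pred == 0 & y == 0),
      FP = sum(pred == 1 & y == 0), FN = sum(pred == 0 & y == 1)
    ),
    probabilities = tibble::tibble(
      image_id = test$records$image_id,
      true_label = test$records$class_label,
      prob_positive = p
    )
  )
}

#' Run one model-building way across all folds
#'
#' For each fold: builds the train/validation/test datasets for the way,
#' trains one model with early stopping, and evaluates that same model under
#' every permitted test-set condition — `"original"` and `"augmented"` for
#' ways A-E, `"augmented"` only for way F (whose test set is inherently
#' augmented). The per-fold leakage audit of the allocation-time assignment
#' is included.
#'
#' @param ds A `labeled_dataset` of originals.
#' @param way One of [augmentation_ways()].
#' @param classifier An `augsplit_classifier`.
#' @param tcfg A [training_config()]; per-fold training seeds are derived
#'   from `seed`, not from `tcfg$seed`.
#' @param k Fold count (default 5).
#' @param seed Master seed for splitting and training.
#' @return A list of class `way_result`: `way`, `k`, `folds` (list of
#'   per-fold results with `epoch_count`, `training_time`,
#'   `validation_*`, `tests` (per condition: confusion + probabilities) and
#'   `leakage`).
#' @export
run_experiment <- function(ds, way, classifier, tcfg = training_config(),
                           k = 5L, seed = 1L) {
  way <- match.arg(way, augmentation_ways())
  cfg <- protocol_config(way, test_augmented = (way == "F"), k = k, seed = seed)
  conditions <- if (way == "F") "augmented" else c("original", "augmented")
  folds <- lapply(seq_len(k), function(fold) {
    built <- build_fold_datasets(ds, cfg, fold)
    fold_tcfg <- tcfg
    fold_tcfg$seed <- derive_seed(seed, "train", way, fold)
    fit <- train_with_early_stopping(classifier, built$train, built$validation, fold_tcfg)
    tests <- list()
    if ("original" %in% conditions) {
      tests$original <- evaluate_on_test(
        classifier, fit$model, built$test,
        tcfg$classification_threshold
      )
    }
    aug_test <- if (way == "F") built$test else augment_dataset(built$test)
    tests$augmented <- evaluate_on_test(
      classifier, fit$model, aug_test,
      tcfg$classification_threshold
    )
    list(
      fold = fold,
      epoch_count = fit$epoch_count,
      training_time = fit$training_time,
      validation_accuracy = fit$validation_accuracy,
      validation_successes = fit$validation_successes,
      validation_trials = fit$validation_trials,
      validation_trace = fit$validation_trace,
      tests = tests,
      leakage = leakage_audit(built$assignment)
    )
  })
  structure(
    list(way = way, k = k, seed = seed, classifier = classifier$name, folds = folds),
    class = "way_result"
  )
}
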