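#' Define a probabilistic image classifier
#'
#' The pluggable contract used by the training harness. A classifier owns
#' its feature extraction and its per-epoch update; the harness owns epoch
#' shuffling, validation scoring and early stopping.
#'
#' @param name Short identifier used in result tables.
#' @param featurize `function(records)` returning an `n x d` numeric feature
#'   matrix for the `records` tibble of a `labeled_dataset`.
#' @param init `function(n_features, seed)` returning a fresh model state.
#' @param train_epoch `function(model, X, y, cfg)` performing one pass over
#'   the already-shuffled rows of `X` (labels `y` in 0/1 coding, positive
#'   class = 1) in mini-batches of `cfg$minibatch_size`, returning the
#'   updated model.
#' @param predict_proba `function(model, X)` returning the probability of
#'   the positive class per row, each in `[0, 1]`; must be side-effect-free.
#' @return An object of class `augsplit_classifier`.
#' @export
new_classifier <- function(name, featurize, init, train_epoch, predict_proba) {
  structure(
    list(
      name = name, featurize = featurize, init = init,
      train_epoch = train_epoch, predict_proba = predict_proba
    ),
    class = "augsplit_classifier"
  )
}

#' Reference classifier: regularized logistic regression on pixels
#'
#' The bundled reference model: logistic regression on centered, rescaled
#' raw pixel intensities, trained by mini-batch stochastic gradient descent
#' with momentum and an L2 penalty, exactly as the training configuration
#' prescribes. Being linear on raw pixels it is orientation-sensitive (it
#' adapts to the orientation statistics of its training images) yet able to
#' memorize the dihedral-invariant component of per-image fingerprints —
#' the two properties that make augmentation-placement effects visible.
#' It trains a fold of the default synthetic benchmark in seconds on one
#' CPU core.
#'
#' @param pixel_scale Multiplier applied to centered pixel intensities so
#'   that gradient magnitudes suit the default learning rate of the
#'   training configuration. Default 1.
#' @param init_sd Standard deviation of the random weight initialization
#'   (0 gives deterministic zero initialization).
#' @return An `augsplit_classifier`.
#' @export
logistic_pixel_classifier <- function(pixel_scale = 1, init_sd = 0) {
  new_classifier(
    name = "logistic_pixel",
    featurize = function(records) {
      d <- length(records$pixels[[1]])
      X <- t(vapply(records$pixels, as.numeric, numeric(d)))
      (X - 0.5) * pixel_scale
    },
    init = function(n_features, seed) {
      w <- if (init_sd > 0) {
        withr::with_seed(seed, rnorm(n_features, sd = init_sd))
      } else {
        numeric(n_features)
      }
      list(w = w, b = 0, vw = numeric(n_features), vb = 0)
    },
    train_epoch = function(model, X, y, cfg) {
      n <- nrow(X)
      m <- cfg$minibatch_size
      starts <- seq(1, n, by = m)
      for (s in starts) {
        idx <- s:min(s + m - 1, n)
        Xb <- X[idx, , drop = FALSE]
        p <- plogis(drop(Xb %*% model$w) + model$b)
        err <- p - y[idx]
        gw <- drop(crossprod(Xb, err)) / length(idx) + cfg$l2_factor * model$w
        gb <- mean(err)
        model$vw <- cfg$momentum * model$vw - cfg$learning_rate * gw
        model$vb <- cfg$momentum * model$vb - cfg$learning_rate * gb
        model$w <- model$w + model$vw
        model$b <- model$b + model$vb
      }
      model
    },
    predict_proba = function(model, X) {
      plogis(drop(X %*% model$w) + model$b)
    }
  )
}
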