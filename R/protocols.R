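#' The six model-building ways of placing augmentation
#'
#' * `A` — make the three sets, then augment the validation set only.
#' * `B` — make the three sets; no augmentation.
#' * `C` — make the three sets, then augment the training set only.
#' * `D` — make the three sets, then augment training and validation,
#'   each independently after their separation.
#' * `E` — separate the test set, augment the remainder eight-fold, then
#'   split the augmented pool into training and validation sets.
#' * `F` — augment the whole dataset eight-fold before any splitting.
#'
#' @return Character vector `c("A", ..., "F")`.
#' @export
augmentation_ways <- function() LETTERS[1:6]

#' A single augmentation-placement protocol configuration
#'
#' @param way One of [augmentation_ways()].
#' @param test_augmented Should the test set be augmented after its
#'   allocation? Way `F` forces `TRUE`: its test set is inherently augmented
#'   because augmentation precedes test-set allocation.
#' @param k Fold count for cross-validation (default 5).
#' @param seed Master integer seed for all splitting randomness.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(way, test_augmented = FALSE, k = 5L, seed = 1L) {
  way <- match.arg(way, augmentation_ways())
  check_field(is.logical(test_augmented) && length(test_augmented) == 1,
    "test_augmented", "must be TRUE or FALSE"
  )
  check_field(is.numeric(k) && length(k) == 1 && k >= 2, "k", "must be >= 2")
  if (way == "F" && !test_augmented) {
    abort("way F augments before test-set allocation, so its test set is inherently augmented; test_augmented must be TRUE",
      class = "augsplit_parameter_error"
    )
  }
  structure(list(
    way = way, test_augmented = test_augmented,
    k = as.integer(k), train_val_ratio = c(3L, 1L), seed = as.integer(seed)
  ), class = "protocol_config")
}

#' Enumerate the 11 evaluation protocols
#'
#' The 6 model-building ways crossed with the test-set condition: ways A-E
#' can each be evaluated on both the non-augmented and the augmented test
#' set (11 = 5 x 2 + 1), while way F admits only the augmented condition.
#'
#' @param k Fold count stored in every configuration.
#' @param seed Seed stored in every configuration.
#' @return A tibble with one row per protocol (`way`, `test_augmented`) and
#'   a `config` list-column of `protocol_config` objects.
#' @export
enumerate_protocols <- function(k = 5L, seed = 1L) {
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(way = setdiff(augmentation_ways(), "F"), test_augmented = c(FALSE, TRUE)),
    tibble::tibble(way = "F", test_augmented = TRUE)
  )
  grid <- dplyr::arrange(grid, .data$way, .data$test_augmented)
  grid$config <- purrr::map2(
    grid$way, grid$test_augmented,
    function(w, ta) protocol_config(w, ta, k = k, seed = seed)
  )
  grid
}

#' Stratified k-fold partition
#'
#' Partitions the records into k disjoint parts covering the dataset, with
#' per-class part sizes differing by at most one record (class proportions
#' are preserved as closely as integer arithmetic allows). Which parts
#' receive the remainder records is decided by the seed.
#'
#' @param ds A `labeled_dataset`.
#' @param k Number of folds; every class must have at least k records.
#' @param seed Integer seed driving the shuffle.
#' @return A tibble `image_id`, `fold` (1..k) covering every record.
#' @export
stratified_kfold <- function(ds, k, seed) {
  check_field(is.numeric(k) && length(k) == 1 && k >= 2, "k", "must be >= 2")
  cc <- class_counts(ds)
  if (any(cc < k)) {
    abort(sprintf(
      "stratification impossible: class '%s' has %d records but k = %d",
      names(cc)[which.min(cc)], min(cc), k
    ), class = "augsplit_stratification_error")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(c("negative", "positive"), function(cl) {
      ids <- ds$records$image_id[ds$records$class_label == cl]
      ids <- sample(ids)
      n <- length(ids)
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) {
        lucky <- sample(k, extra)
        sizes[lucky] <- sizes[lucky] + 1
      }
      tibble::tibble(image_id = ids, fold = rep(seq_len(k), sizes))
    })
  })
}

# Largest-remainder 3:1 split of a single class's ids (already shuffled).
# Fractional parts of 3n/4 and n/4 are {0,.25,.5,.75}; they tie only at .5,
# where a seeded coin decides.
split_counts_3to1 <- function(n) {
  n_tr <- floor(3 * n / 4)
  n_va <- floor(n / 4)
  leftover <- n - n_tr - n_va
  if (leftover > 0) {
    rem_tr <- 3 * n / 4 - n_tr
    rem_va <- n / 4 - n_va
    if (rem_tr > rem_va) {
      n_tr <- n_tr + leftover
    } else if (rem_va > rem_tr) {
      n_va <- n_va + leftover
    } else if (runif(1) < 0.5) { # tie: n %% 4 == 2
      n_tr <- n_tr + 1
      n_va <- n_va + leftover - 1
    } else {
      n_va <- n_va + 1
      n_tr <- n_tr + leftover - 1
    }
  }
  c(train = n_tr, validation = n_va)
}

#' Stratified 3:1 train/validation split
#'
#' Shuffles each class independently (driven by the seed) and divides it
#' into training and validation parts in a 3:1 ratio, applying a
#' largest-remainder rule per class when the class size is not divisible
#' by 4.
#'
#' @param ds A `labeled_dataset` with both classes present.
#' @param seed Integer seed.
#' @return A list with `labeled_dataset` elements `train` and `validation`.
#' @export
split_train_val <- function(ds, seed) {
  cc <- class_counts(ds)
  if (any(cc == 0)) {
    abort("both classes must be present for a stratified split",
      class = "augsplit_stratification_error"
    )
  }
  withr::with_seed(seed, {
    parts <- purrr::map(c("negative", "positive"), function(cl) {
      ids <- sample(ds$records$image_id[ds$records$class_label == cl])
      counts <- split_counts_3to1(length(ids))
      list(
        train = ids[seq_len(counts["train"])],
        validation = ids[counts["train"] + seq_len(counts["validation"])]
      )
    })
    list(
      train = subset_dataset(ds, c(parts[[1]]$train, parts[[2]]$train)),
      validation = subset_dataset(ds, c(parts[[1]]$validation, parts[[2]]$validation))
    )
  })
}

#' Build the train/validation/test datasets for one fold of a protocol
#'
#' Implements the placement of augmentation exactly as the protocol
#' prescribes. Ways A-D allocate the test part and split train/validation on
#' the originals, then augment the named subsets in place. Way E allocates
#' the original test part, augments the remaining originals eight-fold, and
#' splits the augmented pool 3:1 at the individual-image level (orbit
#' members may land on both sides, which is what leaks information between
#' training and validation). Way F augments everything first and performs
#' both the k-fold test allocation and the 3:1 split at the individual-image
#' level (orbit members may land in all three subsets). If
#' `cfg$test_augmented`, the allocated test part (ways A-E) is augmented
#' after allocation.
#'
#' The k-fold allocation and the train/validation shuffle derive their seeds
#' from `cfg$seed` and the fold index only (not the way), so ways sharing a
#' split structure (A-D) see identical original-image splits — paired
#' comparisons between ways isolate the effect of augmentation placement.
#'
#' @param ds A `labeled_dataset` of originals.
#' @param cfg A [protocol_config()].
#' @param fold Fold index in `1..cfg$k`.
#' @return A list with elements `train`, `validation`, `test`
#'   (`labeled_dataset`s) and `assignment`, a tibble
#'   (`image_id`, `parent_id`, `transform_id`, `class_label`, `subset`)
#'   describing the allocation-time assignment (before any test-set
#'   augmentation).
#' @export
build_fold_datasets <- function(ds, cfg, fold) {
  if (!inherits(cfg, "protocol_config")) {
    abort("`cfg` must be a protocol_config", class = "augsplit_parameter_error")
  }
  check_field(
    is.numeric(fold) && length(fold) == 1 && fold >= 1 && fold <= cfg$k,
    "fold", sprintf("must be in 1..%d", cfg$k)
  )
  if (is_augmented(ds)) {
    abort("`ds` must contain only originals", class = "augsplit_precondition_error")
  }
  way <- cfg$way
  seed <- cfg$seed

  if (way %in% c("A", "B", "C", "D")) {
    assign_k <- stratified_kfold(ds, cfg$k, derive_seed(seed, "kfold"))
    test <- subset_dataset(ds, assign_k$image_id[assign_k$fold == fold])
    rest <- subset_dataset(ds, assign_k$image_id[assign_k$fold != fold])
    tv <- split_train_val(rest, derive_seed(seed, "trainval", fold))
    train <- tv$train
    validation <- tv$validation
    if (way %in% c("C", "D")) train <- augment_dataset(train)
    if (way %in% c("A", "D")) validation <- augment_dataset(validation)
  } else if (way == "E") {
    assign_k <- stratified_kfold(ds, cfg$k, derive_seed(seed, "kfold"))
    test <- subset_dataset(ds, assign_k$image_id[assign_k$fold == fold])
    rest <- augment_dataset(subset_dataset(ds, assign_k$image_id[assign_k$fold != fold]))
    tv <- split_train_val(rest, derive_seed(seed, "trainval_aug", fold))
    train <- tv$train
    validation <- tv$validation
  } else { # way F
    pool <- augment_dataset(ds)
    assign_k <- stratified_kfold(pool, cfg$k, derive_seed(seed, "kfold_aug"))
    test <- subset_dataset(pool, assign_k$image_id[assign_k$fold == fold])
    rest <- subset_dataset(pool, assign_k$image_id[assign_k$fold != fold])
    tv <- split_train_val(rest, derive_seed(seed, "trainval_aug", fold))
    train <- tv$train
    validation <- tv$validation
  }

  assignment <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(train$records, -"pixels"), subset = "train"),
    dplyr::mutate(dplyr::select(validation$records, -"pixels"), subset = "validation"),
    dplyr::mutate(dplyr::select(test$records, -"pixels"), subset = "test")
  )

  if (cfg$test_augmented && way != "F") {
    test <- augment_dataset(test)
  }
  list(train = train, validation = validation, test = test, assignment = assignment)
}

#' Audit a split assignment for augmentation-induced information leakage
#'
#' Leakage is the presence of augmentation derivatives of the same parent
#' image in more than one of the three subsets: evaluation on one subset is
#' then optimistically dependent on another. For each subset pair, counts
#' the parents whose orbit members occupy both subsets.
#'
#' @param assignment A tibble with columns `image_id`, `parent_id` and
#'   `subset` (values `train`, `validation`, `test`), e.g. the `assignment`
#'   element of [build_fold_datasets()].
#' @return An object of class `leakage_report`: a list with counts
#'   `parents_train_val`, `parents_train_test`, `parents_val_test`.
#' @export
leakage_audit <- function(assignment) {
  parents_of <- function(s) unique(assignment$parent_id[assignment$subset == s])
  tr <- parents_of("train")
  va <- parents_of("validation")
  te <- parents_of("test")
  structure(list(
    parents_train_val = length(intersect(tr, va)),
    parents_train_test = length(intersect(tr, te)),
    parents_val_test = length(intersect(va, te))
  ), class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat(sprintf(
    "<leakage_report> train/val: %d  train/test: %d  val/test: %d parents shared\n",
    x$parents_train_val, x$parents_train_test, x$parents_val_test
  ))
  invisible(x)
}
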