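test_that("protocol enumeration matches the design's cardinalities", {
  protos <- enumerate_protocols()
  expect_equal(nrow(protos), 11)
  expect_equal(length(unique(protos$way)), 6)
  expect_equal(sum(table(protos$way) == 2), 5)
  expect_true(all(protos$test_augmented[protos$way == "F"]))
  expect_error(protocol_config("F", test_augmented = FALSE),
    class = "augsplit_parameter_error"
  )
})

test_that("stratified k-fold spreads each class evenly, remainder by at most one", {
  ds <- make_ds(n_per_class = 50, image_size = 8)
  folds <- stratified_kfold(ds, 5, seed = 11)
  expect_setequal(folds$image_id, ds$records$image_id)
  tab <- table(
    ds$records$class_label[match(folds$image_id, ds$records$image_id)],
    folds$fold
  )
  expect_true(all(tab == 10))

  # 52 positives + 50 negatives: positive part sizes must be {11,11,10,10,10}
  extra <- labeled_dataset(dplyr::bind_rows(
    ds$records,
    dplyr::mutate(ds$records[ds$records$class_label == "positive", ][1:2, ],
      image_id = c("extra1", "extra2"), parent_id = c("extra1", "extra2")
    )
  ))
  folds2 <- stratified_kfold(extra, 5, seed = 11)
  labs <- extra$records$class_label[match(folds2$image_id, extra$records$image_id)]
  pos_sizes <- sort(as.vector(table(folds2$fold[labs == "positive"])))
  expect_equal(pos_sizes, c(10, 10, 10, 11, 11))

  small <- make_ds(n_per_class = 4, image_size = 8)
  expect_error(stratified_kfold(small, 5, seed = 1),
    class = "augsplit_stratification_error"
  )
})

test_that("the 3:1 train/validation split is stratified with largest-remainder rounding", {
  ds <- make_ds(n_per_class = 40, image_size = 8)
  tv <- split_train_val(ds, seed = 2)
  expect_equal(unname(class_counts(tv$train)), c(30, 30))
  expect_equal(unname(class_counts(tv$validation)), c(10, 10))
  expect_setequal(
    c(tv$train$records$image_id, tv$validation$records$image_id),
    ds$records$image_id
  )

  # same sizes, generally different membership under another seed
  tv2 <- split_train_val(ds, seed = 3)
  expect_equal(class_counts(tv2$train), class_counts(tv$train))
  expect_false(setequal(tv$train$records$image_id, tv2$train$records$image_id))

  # 5 positives + 3 negatives: largest remainder gives train 4+2, val 1+1
  uneven <- labeled_dataset(dplyr::bind_rows(
    ds$records[ds$records$class_label == "positive", ][1:5, ],
    ds$records[ds$records$class_label == "negative", ][1:3, ]
  ))
  tvu <- split_train_val(uneven, seed = 1)
  expect_equal(unname(class_counts(tvu$train)), c(2, 4))
  expect_equal(unname(class_counts(tvu$validation)), c(1, 1))

  mono <- labeled_dataset(ds$records[ds$records$class_label == "positive", ])
  expect_error(split_train_val(mono, 1), class = "augsplit_stratification_error")
})

test_that("fold construction realizes each way's sizes and augmentation placement", {
  ds <- make_ds(n_per_class = 20, image_size = 8) # 40 originals
  sizes <- function(b) c(n_records(b$train), n_records(b$validation), n_records(b$test))

  b <- build_fold_datasets(ds, protocol_config("B", seed = 5), 1)
  expect_equal(sizes(b), c(24, 8, 8))
  expect_false(any(vapply(b[1:3], is_augmented, logical(1))))

  a <- build_fold_datasets(ds, protocol_config("A", seed = 5), 1)
  expect_equal(sizes(a), c(24, 64, 8))
  expect_true(is_augmented(a$validation) && !is_augmented(a$train))

  cc <- build_fold_datasets(ds, protocol_config("C", seed = 5), 1)
  expect_equal(sizes(cc), c(192, 8, 8))
  expect_true(is_augmented(cc$train) && !is_augmented(cc$validation))

  d <- build_fold_datasets(ds, protocol_config("D", seed = 5), 1)
  expect_equal(sizes(d), c(192, 64, 8))

  e <- build_fold_datasets(ds, protocol_config("E", seed = 5), 1)
  expect_equal(sizes(e), c(192, 64, 8))
  expect_false(is_augmented(e$test))
  # the augmented pool is split at the individual-image level: some parent
  # must have members on both sides of the train/validation split
  shared <- intersect(e$train$records$parent_id, e$validation$records$parent_id)
  expect_gt(length(shared), 0)

  f <- build_fold_datasets(ds, protocol_config("F", TRUE, seed = 5), 1)
  expect_equal(sizes(f), c(192, 64, 64))
  expect_true(is_augmented(f$test))

  # augmented test condition for an A-D/E way: test grows eight-fold
  bt <- build_fold_datasets(ds, protocol_config("B", TRUE, seed = 5), 1)
  expect_equal(sizes(bt), c(24, 8, 64))

  expect_error(build_fold_datasets(ds, protocol_config("B"), 7), "fold")
  expect_error(
    build_fold_datasets(augment_dataset(ds), protocol_config("B"), 1),
    class = "augsplit_precondition_error"
  )
})

test_that("subsets partition the pool and test parts are disjoint across folds", {
  ds <- make_ds(n_per_class = 20, image_size = 8)
  for (way in augmentation_ways()) {
    cfg <- protocol_config(way, test_augmented = (way == "F"), seed = 9)
    test_ids <- list()
    for (fold in 1:5) {
      built <- build_fold_datasets(ds, cfg, fold)
      ids <- built$assignment$image_id
      expect_false(anyDuplicated(ids) > 0) # disjoint subsets
      # E: 8 test originals + 8 x 32 augmented rest; F: 8 x 40 split in full
      if (way == "E") expect_length(ids, 264)
      if (way == "F") expect_length(ids, 320)
      test_ids[[fold]] <- built$assignment$image_id[built$assignment$subset == "test"]
    }
    expect_false(anyDuplicated(unlist(test_ids)) > 0)
    if (way != "F") {
      expect_setequal(unlist(test_ids), ds$records$image_id)
    }
  }
})

test_that("fold construction is deterministic given the configuration", {
  ds <- make_ds(n_per_class = 10, image_size = 8)
  cfg <- protocol_config("E", seed = 4)
  b1 <- build_fold_datasets(ds, cfg, 2)
  b2 <- build_fold_datasets(ds, cfg, 2)
  expect_identical(b1$assignment, b2$assignment)
})

test_that("leakage audits show each way's structural zero pattern", {
  ds <- make_ds(n_per_class = 20, image_size = 8)
  for (way in c("A", "B", "C", "D")) {
    rep <- leakage_audit(
      build_fold_datasets(ds, protocol_config(way, seed = 3), 1)$assignment
    )
    expect_equal(rep$parents_train_val, 0)
    expect_equal(rep$parents_train_test, 0)
    expect_equal(rep$parents_val_test, 0)
  }
  rep_e <- leakage_audit(
    build_fold_datasets(ds, protocol_config("E", seed = 3), 1)$assignment
  )
  expect_gt(rep_e$parents_train_val, 0)
  expect_equal(rep_e$parents_train_test, 0)
  expect_equal(rep_e$parents_val_test, 0)

  rep_f <- leakage_audit(
    build_fold_datasets(ds, protocol_config("F", TRUE, seed = 3), 1)$assignment
  )
  expect_gt(rep_f$parents_train_test, 0)
})
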