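#' Structural cardinalities of the protocol matrix
#'
#' The evaluation design implies fixed counts before any training happens:
#' 6 model-building ways; 11 testing protocols (5 ways under both test-set
#' conditions plus way F under one); and, for `n_classifiers` classifiers,
#' `6 * n_classifiers` model groups and `11 * n_classifiers` testing groups
#' (24 and 44 for four classifiers).
#'
#' @param n_classifiers Number of classifier configurations.
#' @return A list: `model_ways`, `testing_protocols`, `both_condition_ways`,
#'   `model_groups`, `testing_groups`.
#' @export
protocol_cardinalities <- function(n_classifiers = 1L) {
  protos <- enumerate_protocols()
  list(
    model_ways = length(unique(protos$way)),
    testing_protocols = nrow(protos),
    both_condition_ways = sum(table(protos$way) == 2),
    model_groups = length(unique(protos$way)) * n_classifiers,
    testing_groups = nrow(protos) * n_classifiers
  )
}

#' Configuration of a full experiment matrix
#'
#' @param synth A [synth_params()] object describing the dataset to
#'   generate, or a `labeled_dataset` of originals to use directly.
#' @param classifiers Named list of `augsplit_classifier` objects.
#' @param ways Subset of [augmentation_ways()] to run (default all 6).
#' @param training A [training_config()].
#' @param k Fold count (default 5).
#' @param seed Master seed; per-classifier, per-way, per-fold sub-seeds are
#'   derived deterministically from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(synth, classifiers = list(logistic = logistic_pixel_classifier()),
                              ways = augmentation_ways(), training = training_config(),
                              k = 5L, seed = 1L) {
  check_field(length(classifiers) >= 1, "classifiers", "need at least one classifier")
  check_field(
    all(vapply(classifiers, inherits, logical(1), "augsplit_classifier")),
    "classifiers", "every element must be an augsplit_classifier"
  )
  check_field(!is.null(names(classifiers)) && all(nzchar(names(classifiers))),
    "classifiers", "must be a named list"
  )
  ways <- match.arg(ways, augmentation_ways(), several.ok = TRUE)
  check_field(length(ways) >= 1, "ways", "need at least one way")
  structure(list(
    synth = synth, classifiers = classifiers, ways = ways,
    training = training, k = as.integer(k), seed = as.integer(seed)
  ), class = "experiment_config")
}

#' Run the full augmentation-placement experiment matrix
#'
#' For every classifier and model-building way: trains the k folds once and
#' evaluates each trained model under every permitted test-set condition,
#' then pools the cross-fold statistics per testing group. The structural
#' cardinalities of the matrix are asserted before any training begins. A
#' failure in one cell is recorded and does not abort the others.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `matrix_bundle`: `testing_groups` (tibble, one
#'   row per classifier x way x test condition), `way_results` (nested
#'   list), `cardinalities`, `errors` (tibble of failed cells), `seed`.
#' @export
run_matrix <- function(cfg) {
  if (!inherits(cfg, "experiment_config")) {
    abort("`cfg` must be an experiment_config", class = "augsplit_parameter_error")
  }
  cards <- protocol_cardinalities(length(cfg$classifiers))
  stopifnot(
    cards$model_ways == 6, cards$testing_protocols == 11,
    cards$both_condition_ways == 5
  )
  ds <- if (inherits(cfg$synth, "labeled_dataset")) {
    cfg$synth
  } else {
    generate_synthetic_dataset(cfg$synth)
  }
  way_results <- list()
  groups <- list()
  errors <- list()
  for (cl_name in names(cfg$classifiers)) {
    way_results[[cl_name]] <- list()
    for (way in cfg$ways) {
      cell <- tryCatch(
        {
          res <- run_experiment(
            ds, way, cfg$classifiers[[cl_name]], cfg$training,
            k = cfg$k, seed = derive_seed(cfg$seed, "cell", cl_name)
          )
          res$classifier <- cl_name
          res
        },
        error = function(e) e
      )
      if (inherits(cell, "error")) {
        errors[[length(errors) + 1]] <- tibble::tibble(
          classifier = cl_name, way = way, message = conditionMessage(cell)
        )
        next
      }
      way_results[[cl_name]][[way]] <- cell
      conds <- if (way == "F") "augmented" else c("original", "augmented")
      for (cond in conds) {
        groups[[length(groups) + 1]] <- pool_fold_results(cell, cond)
      }
    }
  }
  structure(list(
    testing_groups = dplyr::bind_rows(groups),
    way_results = way_results,
    cardinalities = cards,
    errors = dplyr::bind_rows(errors),
    seed = cfg$seed
  ), class = "matrix_bundle")
}

#' Summarize an experiment bundle as one table row per testing group
#'
#' @param bundle A `matrix_bundle` from [run_matrix()].
#' @param expected_ways Ways expected to be present (default: every way
#'   appearing in the bundle plus any recorded failures); if any expected
#'   cell is missing its summary row, an error lists the missing cells.
#' @return A tibble sorted by classifier, way and test condition.
#' @export
summarize_matrix <- function(bundle, expected_ways = NULL) {
  if (!inherits(bundle, "matrix_bundle")) {
    abort("`bundle` must come from run_matrix()", class = "augsplit_parameter_error")
  }
  tbl <- bundle$testing_groups
  if (is.null(tbl) || nrow(tbl) == 0) {
    abort("bundle contains no testing groups; every cell is missing",
      class = "augsplit_incomplete_bundle"
    )
  }
  if (!is.null(expected_ways)) {
    have <- unique(paste(tbl$classifier, tbl$way))
    want <- as.vector(outer(unique(tbl$classifier), expected_ways, paste))
    missing_cells <- setdiff(want, have)
    if (length(missing_cells) > 0) {
      abort(paste0(
        "bundle is missing cell(s): ",
        paste(missing_cells, collapse = ", ")
      ), class = "augsplit_incomplete_bundle")
    }
  }
  dplyr::arrange(tbl, .data$classifier, .data$way, .data$test_condition)
}

#' Serialize a bundle's testing groups to JSON (and read them back)
#'
#' The summary table round-trips through JSON without loss of any
#' statistic.
#'
#' @param bundle A `matrix_bundle`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_matrix_json <- function(bundle, path) {
  jsonlite::write_json(summarize_matrix(bundle), path, digits = NA)
  invisible(path)
}

#' @rdname write_matrix_json
#' @export
read_matrix_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
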