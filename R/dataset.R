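#' Construct a labeled image dataset
#'
#' The central container of the package: a tibble of image records, each
#' carrying its pixels, binary class label, and augmentation provenance
#' (parent image and dihedral transform). An image is an *original* when
#' `transform_id == "e"`, in which case `image_id == parent_id`; otherwise it
#' is a derivative of `parent_id`. The set of 8 records sharing a
#' `parent_id` is that parent's *orbit* under the dihedral group.
#'
#' @param records A tibble (or data frame) with columns `image_id`,
#'   `parent_id`, `transform_id`, `class_label` (one of `"negative"`,
#'   `"positive"`) and `pixels` (list of square numeric matrices).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("image_id", "parent_id", "transform_id", "class_label", "pixels")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "augsplit_format_error"
    )
  }
  if (anyDuplicated(records$image_id) > 0) {
    abort("image_ids must be unique", class = "augsplit_format_error")
  }
  bad <- xor(records$transform_id == "e", records$image_id == records$parent_id)
  if (any(bad)) {
    abort("transform_id == 'e' must hold exactly when image_id == parent_id",
      class = "augsplit_format_error"
    )
  }
  if (!all(records$class_label %in% c("negative", "positive"))) {
    abort("class_label must be 'negative' or 'positive'", class = "augsplit_format_error")
  }
  structure(list(records = records), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf(
    "<labeled_dataset> %d records (%d negative, %d positive)%s\n",
    n_records(x), cc[["negative"]], cc[["positive"]],
    if (is_augmented(x)) ", augmented" else ", originals only"
  ))
  invisible(x)
}

#' Number of records in a dataset
#' @param ds A `labeled_dataset`.
#' @return Integer count.
#' @export
n_records <- function(ds) nrow(ds$records)

#' Per-class record counts
#' @param ds A `labeled_dataset`.
#' @return Named integer vector with entries `negative` and `positive`.
#' @export
class_counts <- function(ds) {
  c(
    negative = sum(ds$records$class_label == "negative"),
    positive = sum(ds$records$class_label == "positive")
  )
}

#' Does the dataset contain augmentation derivatives?
#' @param ds A `labeled_dataset`.
#' @return Logical.
#' @export
is_augmented <- function(ds) any(ds$records$transform_id != "e")

# Subset by image_id, preserving the requested order of ids.
subset_dataset <- function(ds, ids) {
  idx <- match(ids, ds$records$image_id)
  if (anyNA(idx)) abort("unknown image_id in subset", class = "augsplit_parameter_error")
  labeled_dataset(ds$records[idx, , drop = FALSE])
}

#' Write a dataset to disk as PNG files plus a manifest
#'
#' Folder-per-class layout: `<root>/<class>/<image_id>.png`, 8-bit grayscale,
#' plus a `manifest.csv` recording provenance
#' (`image_id,parent_id,transform_id,class_label,path`).
#'
#' @param ds A non-empty `labeled_dataset`.
#' @param root Directory to write into (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, root) {
  if (n_records(ds) == 0) {
    abort("refusing to write an empty dataset", class = "augsplit_parameter_error")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) {
    abort(sprintf("cannot create directory '%s'", root), class = "augsplit_io_error")
  }
  for (cl in unique(ds$records$class_label)) {
    dir.create(file.path(root, cl), showWarnings = FALSE)
  }
  rel <- file.path(ds$records$class_label, paste0(ds$records$image_id, ".png"))
  for (i in seq_len(n_records(ds))) {
    png::writePNG(clamp01(ds$records$pixels[[i]]), file.path(root, rel[i]))
  }
  manifest <- dplyr::mutate(
    dplyr::select(ds$records, "image_id", "parent_id", "transform_id", "class_label"),
    path = rel
  )
  manifest_path <- file.path(root, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a dataset from disk
#'
#' With a manifest (given explicitly or found as `<root>/manifest.csv`),
#' records recover full provenance. Without one, a folder-per-class layout
#' with exactly two class folders is expected and every image is treated as
#' an original.
#'
#' @param root Dataset root directory.
#' @param manifest Optional path to a manifest CSV.
#' @return A `labeled_dataset`.
#' @export
read_dataset <- function(root, manifest = NULL) {
  if (is.null(manifest) && file.exists(file.path(root, "manifest.csv"))) {
    manifest <- file.path(root, "manifest.csv")
  }
  if (!is.null(manifest)) {
    man <- readr::read_csv(manifest, show_col_types = FALSE)
    paths <- file.path(root, man$path)
    gone <- !file.exists(paths)
    if (any(gone)) {
      abort(sprintf("manifest references missing file(s): %s",
        paste(man$path[gone], collapse = ", ")
      ), class = "augsplit_io_error")
    }
    px <- lapply(paths, read_png_gray)
    return(labeled_dataset(tibble::tibble(
      image_id = man$image_id, parent_id = man$parent_id,
      transform_id = man$transform_id, class_label = man$class_label,
      pixels = px
    )))
  }
  class_dirs <- list.dirs(root, recursive = FALSE)
  if (length(class_dirs) != 2) {
    abort(sprintf(
      "expected exactly 2 class folders under '%s', found %d",
      root, length(class_dirs)
    ), class = "augsplit_format_error")
  }
  recs <- purrr::map_dfr(class_dirs, function(d) {
    files <- list.files(d, pattern = "\\.png$", full.names = TRUE)
    tibble::tibble(
      image_id = sub("\\.png$", "", basename(files)),
      parent_id = sub("\\.png$", "", basename(files)),
      transform_id = "e",
      class_label = basename(d),
      pixels = lapply(files, read_png_gray)
    )
  })
  labeled_dataset(recs)
}

read_png_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px
}

#' Resize every image in a dataset
#'
#' Bilinear interpolation (via EBImage); metadata is unchanged. Resizing to
#' the current size is pixel-identical, and for square images resizing
#' commutes with the dihedral transforms.
#'
#' @param ds A `labeled_dataset`.
#' @param side Target side length in pixels, at least 8.
#' @return A `labeled_dataset` with `side` x `side` images.
#' @export
resize_dataset <- function(ds, side) {
  check_field(is.numeric(side) && length(side) == 1 && side >= 8, "side", "must be >= 8")
  side <- as.integer(side)
  recs <- ds$records
  recs$pixels <- lapply(recs$pixels, function(px) {
    if (nrow(px) == side && ncol(px) == side) return(px)
    EBImage::imageData(EBImage::resize(EBImage::Image(px), w = side, h = side,
      filter = "bilinear"
    ))
  })
  labeled_dataset(recs)
}
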