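#' Eight-fold dihedral augmentation of a dataset of originals
#'
#' Each original is replaced by its complete dihedral orbit: the original
#' itself (transform `e`) plus the 7 rotated/flipped derivatives, every
#' derivative carrying the `parent_id` of its source and its transform code.
#' Class labels are preserved, so per-class proportions are unchanged and the
#' dataset grows by exactly a factor of 8. Record identity is by
#' `(parent_id, transform_id)` regardless of pixel content, so even a fully
#' symmetric image still yields 8 records.
#'
#' @param ds A `labeled_dataset` containing only originals.
#' @return A `labeled_dataset` with `8 * n_records(ds)` records.
#' @export
augment_dataset <- function(ds) {
  if (is_augmented(ds)) {
    abort("dataset already contains augmentation derivatives; augmenting again would inflate it 64-fold",
      class = "augsplit_precondition_error"
    )
  }
  codes <- dihedral_elements()
  recs <- ds$records
  out <- purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    parent <- recs$image_id[i]
    tibble::tibble(
      image_id = ifelse(codes == "e", parent, paste(parent, codes, sep = "_")),
      parent_id = parent,
      transform_id = codes,
      class_label = recs$class_label[i],
      pixels = lapply(codes, function(tc) apply_transform(recs$pixels[[i]], tc))
    )
  })
  labeled_dataset(out)
}
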