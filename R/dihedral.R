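#' The eight dihedral transform codes
#'
#' The symmetry group of the square (order 8): the identity `e`, counter-
#' clockwise rotations by 90, 180 and 270 degrees (`r90`, `r180`, `r270`),
#' and the horizontal flip of each of those four (`f`, `fr90`, `fr180`,
#' `fr270`). `fr90` denotes flipping the already-rotated image. Because
#' histological diagnosis is invariant under all eight, they are the standard
#' lossless augmentation set for histopathology patches.
#'
#' @return Character vector of the 8 transform codes, identity first.
#' @export
dihedral_elements <- function() {
  c("e", "r90", "r180", "r270", "f", "fr90", "fr180", "fr270")
}

# Counter-clockwise quarter rotation of a matrix (row 1 = top of the image).
rot90_ccw <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

# Horizontal flip: mirror left-right.
flip_h <- function(m) {
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Apply a dihedral transform to a square pixel array
#'
#' A lossless permutation of pixels: no interpolation is involved, so the
#' transform of a transform is always another exact group element.
#'
#' @param pixels Square numeric matrix of intensities.
#' @param transform One of [dihedral_elements()].
#' @return The transformed matrix, same dimensions.
#' @examples
#' m <- matrix(1:9, 3, 3)
#' identical(apply_transform(m, "e"), m)
#' @export
apply_transform <- function(pixels, transform) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    abort("`pixels` must be a square matrix", class = "augsplit_shape_error")
  }
  transform <- match.arg(transform, dihedral_elements())
  rot_part <- sub("^f", "", transform)
  n_rot <- c(e = 0L, r90 = 1L, r180 = 2L, r270 = 3L)[[if (nzchar(rot_part)) rot_part else "e"]]
  out <- pixels
  for (i in seq_len(n_rot)) out <- rot90_ccw(out)
  if (startsWith(transform, "f")) out <- flip_h(out)
  out
}

# Composition table, derived once by brute force on an asymmetric probe whose
# 8 transforms are pairwise distinct; the permutation structure is the same
# for every square size.
dihedral_env <- new.env(parent = emptyenv())

dihedral_table <- function() {
  if (is.null(dihedral_env$tbl)) {
    codes <- dihedral_elements()
    probe <- matrix(seq_len(9), 3, 3)
    canon <- lapply(codes, function(tc) apply_transform(probe, tc))
    names(canon) <- codes
    tbl <- matrix("", 8, 8, dimnames = list(codes, codes))
    for (a in codes) {
      for (b in codes) {
        res <- apply_transform(apply_transform(probe, b), a)
        hit <- names(canon)[vapply(canon, function(x) identical(x, res), logical(1))]
        tbl[a, b] <- hit
      }
    }
    dihedral_env$tbl <- tbl
  }
  dihedral_env$tbl
}

#' Compose two dihedral transforms
#'
#' `dihedral_compose(a, b)` is the single group element equivalent to applying
#' `b` first and `a` second, i.e. `a(b(x))`.
#'
#' @param a,b Transform codes from [dihedral_elements()].
#' @return A single transform code.
#' @export
dihedral_compose <- function(a, b) {
  a <- match.arg(a, dihedral_elements())
  b <- match.arg(b, dihedral_elements())
  dihedral_table()[a, b]
}

# Average of the 8 dihedral transforms of a matrix; exactly invariant under
# every element of the group.
dihedral_symmetrize <- function(m) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (tc in dihedral_elements()) acc <- acc + apply_transform(m, tc)
  acc / 8
}
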