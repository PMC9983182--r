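# Generator composition constants. Amplitudes are pixel-intensity units on
# the [0,1] scale at strength 1; see the methods vignette for the rationale.
SIGNAL_AMP <- 0.03 # class-pattern amplitude per unit class_signal_strength
FP_AMP <- 0.12 # fingerprint amplitude per unit fingerprint_strength
FP_SYM_W <- 0.8 # share of fingerprint power in the dihedral-invariant field
FP_ANISO_W <- 0.6 # share in the per-image plane-wave clutter
BIAS_AMP <- 0.18 # amplitude of the fixed oriented bias field common to all images
CLASS_CYCLES <- c(negative = 4, positive = 6) # radial frequency, cycles per image width

#' Parameters of the synthetic image generator
#'
#' Describes a balanced two-class set of square grayscale images. Each image
#' is composed of (i) a class-dependent radially symmetric texture whose
#' class-conditional distribution is exactly invariant under the 8 dihedral
#' transforms, (ii) a per-image identity fingerprint, (iii) a fixed oriented
#' bias field shared by every image, and (iv) iid pixel noise. The
#' fingerprint mixes a dihedral-invariant random field (which makes the
#' derivatives of one parent mutually recognizable, the mechanism that
#' renders split leakage measurable) with low-dimensional plane-wave
#' clutter (which an unaugmented training set lets a classifier overfit,
#' so that training-set augmentation measurably improves generalization).
#' The constant bias field plays the role of the orientation statistics of
#' real photographic datasets: a model trained only on originals silently
#' calibrates to it and degrades on rotated or flipped inputs.
#'
#' @param n_per_class Original images per class, at least 1.
#' @param image_size Pixels per side, at least 8. Default 32.
#' @param class_signal_strength Dimensionless scaling (>= 0) of the
#'   class-discriminative texture amplitude. At 0 the classes are
#'   indistinguishable.
#' @param fingerprint_strength Dimensionless scaling (>= 0) of the per-image
#'   fingerprint amplitude.
#' @param noise_sd Standard deviation of the iid pixel noise, in intensity
#'   units on the [0,1] scale.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   datasets.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_per_class, image_size = 32L, class_signal_strength = 1,
                         fingerprint_strength = 1, noise_sd = 0.05, seed = 1L) {
  check_field(
    is.numeric(n_per_class) && length(n_per_class) == 1 && n_per_class >= 1,
    "n_per_class", "must be a count >= 1"
  )
  check_field(
    is.numeric(image_size) && length(image_size) == 1 && image_size >= 8,
    "image_size", "must be >= 8"
  )
  check_field(
    is.numeric(class_signal_strength) && length(class_signal_strength) == 1 &&
      class_signal_strength >= 0,
    "class_signal_strength", "must be >= 0"
  )
  check_field(
    is.numeric(fingerprint_strength) && length(fingerprint_strength) == 1 &&
      fingerprint_strength >= 0,
    "fingerprint_strength", "must be >= 0"
  )
  check_field(
    is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
    "noise_sd", "must be >= 0"
  )
  check_field(
    is.numeric(seed) && length(seed) == 1 && is.finite(seed),
    "seed", "must be a finite integer"
  )
  structure(list(
    n_per_class = as.integer(n_per_class), image_size = as.integer(image_size),
    class_signal_strength = class_signal_strength,
    fingerprint_strength = fingerprint_strength,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synth_params")
}

# Radially symmetric class texture: cos(2*pi*f*r/n) about the grid center.
# Pointwise invariant under all 8 dihedral transforms.
radial_class_pattern <- function(n, cycles) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  cos(2 * pi * cycles * sqrt(d2) / n)
}

# Basis of horizontal and vertical plane waves at the class frequencies,
# each normalized to unit pixel sd. The span is closed under all 8 dihedral
# transforms (quarter rotations swap horizontal and vertical waves; flips
# reflect phases within each orientation), and iid coefficients make the
# resulting clutter field's distribution exactly transform-invariant. This
# is the low-dimensional, high-variance per-image clutter that an
# unaugmented training set lets a classifier overfit — and that training-set
# augmentation, by spreading each parent's coefficients around the
# subspace, forces it to ignore.
stripe_basis <- function(n, freqs = CLASS_CYCLES) {
  phase <- 2 * pi * (seq_len(n) - 1) / n
  out <- list()
  for (f in freqs) {
    for (fun in list(cos, sin)) {
      h <- matrix(fun(f * phase), n, n, byrow = TRUE)
      out[[length(out) + 1]] <- h / sd(as.numeric(h))
      out[[length(out) + 1]] <- t(h) / sd(as.numeric(h))
    }
  }
  out
}

# Random unit-sd combination of the stripe basis.
stripe_field <- function(basis) {
  a <- rnorm(length(basis))
  acc <- 0
  for (i in seq_along(basis)) acc <- acc + a[i] * basis[[i]]
  acc / sqrt(length(basis))
}

# Fixed oriented bias field shared by every image: a horizontal wave mixture
# at the class frequencies with phases chosen so that no dihedral transform
# (other than the identity) maps it onto itself. It plays the role of the
# orientation statistics of real photographic datasets (illumination
# gradients, scanning direction): constant within the population, displaced
# by every rotation or flip.
oriented_bias_field <- function(n, freqs = CLASS_CYCLES) {
  phase <- 2 * pi * (seq_len(n) - 1) / n
  v <- cos(freqs[[1]] * phase + 1.1) + cos(freqs[[2]] * phase + 2.3)
  b <- matrix(v, n, n, byrow = TRUE)
  b / sd(as.numeric(b))
}

#' Generate a synthetic labeled image dataset
#'
#' Produces `2 * n_per_class` original images (no augmentation derivatives),
#' exactly `n_per_class` per class, each composed of class texture, identity
#' fingerprint and pixel noise, clamped to the [0,1] intensity range. The
#' output is bit-identical for identical parameters and seed, and the global
#' RNG state is left untouched.
#'
#' @param params A [synth_params()] object.
#' @return A `labeled_dataset` of originals.
#' @examples
#' ds <- generate_synthetic_dataset(synth_params(n_per_class = 5, seed = 7))
#' n_records(ds)
#' @export
generate_synthetic_dataset <- function(params) {
  if (!inherits(params, "synth_params")) {
    params <- do.call(synth_params, as.list(params))
  }
  n <- params$image_size
  basis <- stripe_basis(n)
  bias <- BIAS_AMP * oriented_bias_field(n)
  patterns <- lapply(CLASS_CYCLES, function(f) radial_class_pattern(n, f))
  withr::with_seed(params$seed, {
    recs <- purrr::map_dfr(c("negative", "positive"), function(cl) {
      ids <- sprintf("%s%04d", substr(cl, 1, 3), seq_len(params$n_per_class))
      px <- lapply(seq_len(params$n_per_class), function(i) {
        fp_sym <- dihedral_symmetrize(matrix(rnorm(n * n), n, n))
        fp_sym <- fp_sym / sd(as.numeric(fp_sym))
        fp_aniso <- stripe_field(basis)
        img <- 0.5 + bias +
          params$class_signal_strength * SIGNAL_AMP * patterns[[cl]] +
          params$fingerprint_strength * FP_AMP *
            (FP_SYM_W * fp_sym + FP_ANISO_W * fp_aniso) +
          rnorm(n * n, sd = params$noise_sd)
        clamp01(matrix(img, n, n))
      })
      tibble::tibble(
        image_id = ids, parent_id = ids, transform_id = "e",
        class_label = cl, pixels = px
      )
    })
    labeled_dataset(recs)
  })
}
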