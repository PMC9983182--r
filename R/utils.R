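#' @importFrom rlang abort warn %||%
#' @importFrom stats qbeta qt sd cor fft plogis rnorm runif
NULL

# Deterministic sub-seed derivation. All randomness in the package flows from
# a master seed through this function, so any stage (a fold, an epoch) can be
# reproduced in isolation. Arithmetic stays below 2^53, result below 2^31.
derive_seed <- function(seed, ...) {
  parts <- list(seed, ...)
  h <- 0
  for (p in parts) {
    if (is.character(p)) {
      for (ch in utf8ToInt(p)) h <- (h * 31 + ch) %% 2147483629
    } else {
      h <- (h * 69069 + as.numeric(p) %% 2147483629) %% 2147483629
    }
  }
  as.integer(h %% 2147483629 + 1)
}

# x first so matrix attributes survive (pmin/pmax copy from the first arg)
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Shared validation helper: stop with the offending field named.
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "augsplit_parameter_error")
  }
  invisible(TRUE)
}
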