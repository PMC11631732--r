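# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (5.25 -> 5.3 at one
#' decimal), unlike [base::round()]'s round-half-even. Cohort percentages are
#' reported with this rule so that printed rates are reproducible from their
#' counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible child seed from a base seed and a stage tag.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be > 0", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
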