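# Internal helpers shared across the package.

.pkg <- new.env(parent = emptyenv())

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Resolve a count argument that may be a plain number or a count sampler.
# Returns a single non-negative integer.
#' @noRd
resolveN <- function(n, what = "n") {
  if (is.function(n)) n <- n()
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stopf("'%s' must be a single non-negative number or a count sampler", what)
  }
  as.integer(round(n))
}

# Resolve a proportion argument that may be a number or a proportion sampler.
# `strength` is forwarded to strength-aware samplers.
#' @noRd
resolveP <- function(p, strength = NULL, what = "p", open = TRUE) {
  if (is.function(p)) {
    p <- if ("strength" %in% names(formals(p))) p(strength = strength) else p()
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p)) {
    stopf("'%s' must be a single number or a proportion sampler", what)
  }
  if (open && (p <= 0 || p >= 1)) stopf("'%s' must lie strictly within (0, 1)", what)
  if (!open && (p < 0 || p > 1)) stopf("'%s' must lie within [0, 1]", what)
  as.numeric(p)
}

#' @noRd
isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
  x == round(x)

#' @noRd
isPowerOfTwo <- function(x) isCount(x) && x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
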