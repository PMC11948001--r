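# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this wrapper so that no call mutates the caller's RNG state and every
#' result is bit-reproducible given (parameters, seed).
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a master seed and a stage label, staying within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Collect multiple validation failures and raise them in one error.
validate_all <- function(checks) {
  bad <- vapply(checks, function(ch) !isTRUE(ch$ok), logical(1))
  if (any(bad)) {
    msgs <- vapply(checks[bad], function(ch) ch$msg, character(1))
    stop("validation failed:\n", paste0("  - ", msgs, collapse = "\n"),
         call. = FALSE)
  }
  invisible(TRUE)
}

check <- function(ok, msg) list(ok = ok, msg = msg)
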