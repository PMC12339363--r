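# Internal helpers: structured error conditions and argument checks.

st_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "stimtract_error", "error")))
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) st_stop(class, msg, ...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_point3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

# Derive a reproducible sub-seed for a named stage from a master seed.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
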