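# Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a master seed and string parts.
# Used so every well (and every plate x channel illumination field) gets an
# independent, reproducible RNG stream regardless of generation order.
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  parts <- paste(c(format(master_seed), ...), collapse = "|")
  h <- as.double(master_seed) %% 2147483629
  for (code in utf8ToInt(parts)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h) + 1L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Weighted-median-free simple median that tolerates empty input.
median_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ms <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
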