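# Internal helpers shared across modules.

#' @importFrom withr local_seed
NULL

# Centered moving average with edge truncation: at the ends the window is
# shortened to whatever fits inside the series, so output length == input
# length and a constant series is unchanged.
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Cosine similarity (normalized inner product) of two equal-length vectors.
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop2("chromqc_degenerate_series",
          "cosine similarity undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}

# Typed condition constructor so callers can distinguish degenerate-input
# failures (constant/all-zero series, failed fits) from programming errors.
stop2 <- function(class, message, call. = FALSE) {
  cond <- structure(
    class = c(class, "chromqc_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1))
  )
  stop(cond)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# All randomness in the package flows through this: it scopes a seed to the
# calling function and restores the caller's RNG state on exit.
local_rng <- function(seed, envir = parent.frame()) {
  stopifnot(is_scalar_number(seed))
  withr::local_seed(as.integer(seed), .local_envir = envir)
}
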