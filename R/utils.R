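# Internal helpers shared across modules.

# Derive a vector of reproducible child seeds from one master seed.
# Child seeds stay below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

# Stop with a classed condition so callers/tests can match on error type.
stop_siam <- function(message, class) {
  abort(message, class = c(class, "siamscreen_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_siam(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
      "siam_input_error"
    )
  }
  invisible(x)
}

# Population standard deviation (divisor n, not n - 1).
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
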