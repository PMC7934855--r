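## Internal numeric helpers shared across modules.

# Cumulative trapezoidal integral of y on a uniform grid with step dt.
# Returns a vector the same length as y; element i is the integral over
# samples 1..i, so segment integrals are simple differences.
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-n] + y[-1L]) / 2) * dt)
}

# Definite trapezoidal integral of y over a uniform grid with step dt.
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-n] + y[-1L]) / 2) * dt
}

# Stop with a configuration error naming the offending field.
check_positive <- function(value, field, strict = TRUE, what = "config") {
  bad <- !is.numeric(value) || length(value) != 1L || is.na(value) ||
    (if (strict) value <= 0 else value < 0)
  if (bad) {
    stop(sprintf("invalid %s: `%s` must be a %s number (got %s)",
                 what, field, if (strict) "positive" else "non-negative",
                 paste(format(value), collapse = ", ")),
         call. = FALSE)
  }
  invisible(value)
}

# Derive a per-stream seed from a master seed and a counter, kept inside
# the 32-bit signed range so set.seed() always accepts it. A fixed linear
# congruential step means adding animals to a cohort never perturbs the
# streams of animals already present.
derive_seed <- function(master_seed, counter) {
  m <- 2147483629 # largest prime below 2^31
  ((as.double(master_seed) %% m) * 48271 + as.double(counter) * 16807) %% m
}
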