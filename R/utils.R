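# internal helpers: classed conditions and seed scoping

sa_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "soilassembly_error"), call = call))
}

sa_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "soilassembly_warning")))
}

# Run expr with a locally-set RNG seed; the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Strict upper-triangle values of a square matrix, by column (pair order
# (1,2),(1,3),(2,3),... matching dist()).
upper_vals <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
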