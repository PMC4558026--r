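# internal helpers shared across modules

# all entries integer-valued (within fuzz); used by the count/frequency
# auto-detection rule
is_whole <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# stop with a consistent error class so tests can target our own failures
stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "slavstrata_error")
}

# upper-triangle vector of a square matrix, column-major (the pair order used
# by every matrix statistic in the package)
upper_vec <- function(m) m[upper.tri(m)]

# reorder a labelled square matrix to a given label order
align_labels <- function(m, labels) {
  if (!setequal(rownames(m), labels)) {
    stop_input("label mismatch: matrices do not share the same label set")
  }
  m[labels, labels, drop = FALSE]
}

# derive a fresh 31-bit seed for an internal stage from a user seed
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
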