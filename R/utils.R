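`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state; global seed untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic stream of sub-seeds (< 2^31) derived from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_subgrade <- function(msg, class) {
  stop(structure(class = c(class, "subgrade_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

hash_object <- function(x) digest::digest(x, algo = "md5")
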