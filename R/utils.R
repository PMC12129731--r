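# Internal helpers shared across modules.

.datatable.aware <- TRUE

# Derive an independent RNG sub-seed from a master seed. Each generated
# artifact (sample sheet, matrix, missingness mask, scores, CV folds) uses
# its own stream so that regenerating one artifact never shifts another.
# Result stays below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) %% 1000003) * 2099 + (offset %% 7919) * 257 + 1) %% 2147483549L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_phosphosig <- function(msg, class) {
  stop(structure(
    class = c(class, "phosphosig_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Numerically safe softplus; strictly increasing, non-negative.
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
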