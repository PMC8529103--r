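# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from the master seed and a stage
# label, so that adding a stage never perturbs the draws of earlier stages.
# The label is hashed with a small polynomial rolling hash; the result stays
# within the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483629
  }
  as.integer((abs(as.numeric(seed)) %% 1046527 * 2039 + h) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Stratified fold assignment: every class is spread as evenly as possible
# across `k` folds. Returns an integer vector of fold ids along `labels`.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed_(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# The one-decimal display convention for percentages: truncation, not
# rounding (42/44 -> 95.4545... is displayed "95.4").
truncate_pct <- function(x, digits = 1L) {
  sprintf(paste0("%.", digits, "f"), trunc(x * 10^digits) / 10^digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
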