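# Deterministically derive a sub-seed from a master seed and integer tags.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  tags <- unlist(list(...))
  off <- if (length(tags)) sum(as.numeric(tags) * 104729) else 0
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

rms <- function(x) sqrt(mean(x^2))
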