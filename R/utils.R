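# Derive reproducible 31-bit seed substreams from a master seed.
# A multiplicative scramble (Lehmer-style, modulus 2^31 - 1) decorrelates
# streams with nearby master seeds and distinct tags; all arithmetic
# stays below 2^53 so it is exact in doubles.
substream_seeds <- function(seed, n, tag = 0L) {
  m <- 2147483647
  state <- (abs(as.numeric(seed)) %% m) + 1
  state <- (state * 48271 + as.numeric(tag) * 7919) %% m
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 48271 + 1) %% m
    out[i] <- state
  }
  as.integer(out %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
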