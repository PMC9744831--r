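# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; with seed = NULL the global stream is used as-is.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
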