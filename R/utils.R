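## stage-prefixed logging: one stream, no silent drops
pgxLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

## deterministic sub-seed derivation: every stochastic stage draws its own
## seed from the master seed so stages stay reproducible independently
subSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

withSeed <- function(seed, expr) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
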