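# Seed-stream discipline: one master seed spawns named substreams (frailty,
# covariate, treatment, event, censoring) so toggling one model component does
# not shift the draws of the others.  Derived seeds stay below 2^31 - 1.

derive_stream_seeds <- function(seed, streams) {
  seed <- as.numeric(seed)
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  out <- vapply(seq_along(streams), function(i) {
    h <- sum(utf8ToInt(streams[i]) * seq_along(utf8ToInt(streams[i])))
    as.integer((abs(seed) * 48271 + h * 16807 + i) %% 2147483629)
  }, integer(1))
  names(out) <- streams
  out
}

# per-replicate master seed for study loops
derive_replicate_seed <- function(seed, r) {
  as.integer((abs(as.numeric(seed)) * 69621 + r * 7919 + 13) %% 2147483629)
}
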