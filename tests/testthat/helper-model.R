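# Shared fixtures: protocols and lazily cached simulation traces. All
# fixtures are generated in code; the model is deterministic, so cached
# traces are bit-reproducible.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# standard 80 Hz excitotoxic protocol, full length
proto80 <- function(mg = 0.2, t_end = 3000) {
  stim_protocol(freq = 80, stim_end = t_end, t_end = t_end, mg = mg)
}

# short protocol for cheap tests
proto_short <- function(freq = 80, mg = 0.2, t_end = 200) {
  stim_protocol(freq = freq, stim_end = t_end, t_end = t_end, mg = mg)
}

trace80 <- function(mg, t_end = 3000) {
  cached(sprintf("trace80_%g_%g", mg, t_end),
         rgc_integrate(proto80(mg, t_end)))
}

# quiescent run (no glutamate) from rest over 3 s
trace_rest <- function() {
  cached("trace_rest", {
    pr <- stim_protocol(freq = 80, pulse_amp = 0, stim_end = 3000,
                        t_end = 3000, mg = 1.0)
    rgc_integrate(pr)
  })
}
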