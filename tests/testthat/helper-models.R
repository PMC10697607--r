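# Shared model objects for the test suite (population-mean morphometry,
# seawater, representative beat parameters).

tm <- morphometry()
tfluid <- fluid_properties()
tbody <- build_body(tm, tfluid)
tcoef <- default_coefficients(tbody$a, tbody$b)
tplac <- place_ctenes(tm)
tbeat <- beat_params(f = 30)

# deterministic pseudo-random draws for property-style tests
rand_angles <- function(n, seed) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -1.3, 1.3), ncol = 3)
}

# short simulation used by several tests (cached per session)
short_run <- local({
  cache <- new.env()
  function(mode = "mode1", f_out = 30, f_in = 0, direction = 1,
           duration = 0.5) {
    key <- paste(mode, f_out, f_in, direction, duration, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_swim(
        assign_mode(mode, f_out, f_in, direction = direction),
        duration = duration, halting = "none")
    cache[[key]]
  }
})
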