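# Shared fixtures: small montages and a noise-free parameter set so the
# signal chain can be checked against exact oracles.

montage4 <- function() default_montage(c("S3-D2", "S3-D5", "S5-D4", "S5-D5"))
montage2 <- function() default_montage(c("S3-D2", "S5-D5"))

silent_noise <- function(seed = 1L) {
  noise_params(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
               drift_slope = 0, white_sd = 0, motion_spike_amp = 0,
               rng_seed = seed)
}

# One clean simulated session on a 2-channel montage (cached per run).
clean_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tl <- build_session_timeline(protocol_config(), 1)
      cache <<- simulate_session(tl, 1, montage = montage2(),
                                 noise = silent_noise())
    }
    cache
  }
})
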