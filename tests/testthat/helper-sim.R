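# Shared fixtures: all synthetic, generated in code.

# A small, fast synthetic subject for module tests.
small_subject <- function(seed = 1L, duration = 180, n_channels = 8L,
                          rec = recovery_params(), snr_db = -10) {
  cfg <- sim_config(duration = duration, n_channels = n_channels,
                    noise = list(exponent = 1, snr_db = snr_db))
  simulate_subject(cfg, rec, seed = seed)
}

# Deterministic onset table from explicit times.
events_at <- function(times) compute_ioi(onset_events(times))

norm01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}
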