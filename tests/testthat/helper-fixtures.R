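# Shared fixtures built in code at test time.

grid101 <- seq(0, 100, length.out = 101)

# a quiet (noise-free) profile for deterministic geometry checks
quiet_profile <- function(group = "healthy", ...) {
  make_profile(group, overrides = c(list(noise_sd = 0), list(...)))
}

# pure-sinusoid normalized cycle
sine_cycle <- function(freq = 1, phase = 0, amp = 1, offset = 0,
                       stance_end = 50) {
  normalized_cycle(offset + amp * sin(2 * pi * freq * grid101 / 100 - phase),
                   stance_end)
}

# bare crp_series wrapper for toy vectors
toy_crp <- function(values, stance_end = 50) {
  structure(list(crp = values, pair_label = c("a", "b"),
                 stance_end_pct = stance_end),
            class = "crp_series")
}
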