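# Shared fixture builders: everything is generated in code at test time.

# Paper-condition mixtures used across tests
full_length_mixture <- function() {
  exp_mixture(c(0.08, 0.74, 11), c(0.58, 0.27, 0.15))
}
c_terminal_mixture <- function() {
  exp_mixture(c(0.25, 2), c(0.78, 0.22))
}
tirf_bound_mixture <- function() {
  exp_mixture(c(0.9, 8), c(0.7, 0.3))
}

# A small static-binder scene: permanent emitters parked at nicks
static_scene <- function(duration_s = 40, arrival_rate = 0.05,
                         photon_rate = 80, seed = 33) {
  sp <- binding_kinetics(arrival_rate, 1, 0, 0,
                         dwell = list(static = exp_mixture(1e6, 1)),
                         photon_rate = photon_rate)
  kymo_scene(species = list(sp), duration_s = duration_s, seed = seed)
}

# Noiseless two-level trace with known state path
square_trace <- function(states, lo = 100, hi = 400) {
  ifelse(states == 1L, hi, lo)
}

# Alternating-renewal state path for HMM tests (frames)
renewal_states <- function(n_frames, p_on = 0.02, p_off = 0.2, seed = 1) {
  withr::with_seed(seed, {
    st <- integer(n_frames)
    cur <- 0L
    for (i in seq_len(n_frames)) {
      flip <- if (cur == 0L) p_on else p_off
      if (stats::runif(1) < flip) cur <- 1L - cur
      st[i] <- cur
    }
    st
  })
}
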