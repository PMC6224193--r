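# Small model fixtures shared across tests.

small_spec <- function(N = 200, frac_e = 0.8, in_e = 16, in_i = 4, ...) {
  NE <- round(frac_e * N)
  network_spec(N = N, NE = NE, NI = N - NE, in_degree_e = in_e, in_degree_i = in_i, ...)
}

# Trace containing one instantaneous-rise, single-exponential event: the
# closed-form fixture for decay fitting.
exp_decay_trace <- function(amp_pA, tau_ms, t0_ms = 100, duration_ms = 300,
                            dt_ms = 0.1, sign = -1) {
  t <- seq(0, duration_ms, by = dt_ms)
  cur <- numeric(length(t))
  on <- t >= t0_ms
  cur[on] <- sign * amp_pA * exp(-(t[on] - t0_ms) / tau_ms)
  new_trace(cur, dt_ms, holding_mV = if (sign < 0) -70 else 0)
}
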