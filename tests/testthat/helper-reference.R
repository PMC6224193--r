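# Independent reference implementations used as oracles.

# Forward-Euler reference integrator for the conductance-based LIF network.
# Deliberately a different scheme from the package integrator (explicit Euler
# voltage update instead of exponential-Euler), but with identical event
# semantics: conductances decay exponentially, increments arrive at step
# boundaries, recurrent spikes arrive `delay` later, reset/refractory as in
# the model. External drive must be supplied as an explicit event schedule
# (list of (time, weight) matrices, one per neuron) so both integrators see
# the same realization.
reference_lif_sim <- function(neuron, spec, conn, duration_ms, dt_ms,
                              ext_events, v0, weight_overrides = NULL) {
  N <- spec$N; NE <- spec$NE
  m <- l4ei:::identity_multipliers()
  if (!is.null(weight_overrides)) m[names(weight_overrides)] <- weight_overrides
  w_ee <- spec$j_nS * m$ee; w_ei <- spec$j_nS * m$ei
  w_ie <- spec$g_rc * spec$j_nS * m$ie; w_ii <- spec$g_rc * spec$j_nS * m$ii
  n_steps <- round(duration_ms / dt_ms)
  decay <- exp(-dt_ms / neuron$tau_syn_ms)
  ref_steps <- round(neuron$t_ref_ms / dt_ms)
  d_steps <- max(0L, round(spec$delay_ms / dt_ms))

  # per-step external conductance increments
  inc_ext <- matrix(0, n_steps, N)
  for (i in seq_len(N)) {
    ev <- ext_events[[i]]
    if (nrow(ev)) {
      st <- pmin(n_steps, floor(ev[, 1] / dt_ms) + 1L)
      for (k in seq_along(st)) inc_ext[st[k], i] <- inc_ext[st[k], i] + ev[k, 2]
    }
  }
  inc_ge <- matrix(0, n_steps + d_steps + 1L, N)
  inc_gi <- matrix(0, n_steps + d_steps + 1L, N)
  out_tgt <- lapply(seq_len(N), function(s) {
    if (is.null(conn)) integer(0) else
      conn$out_idx[(conn$out_ptr[s] + 1L):conn$out_ptr[s + 1L]] + 1L
  })
  if (!is.null(conn)) {
    # neurons with zero out-degree: guard the indexing above
    deg <- diff(conn$out_ptr)
    out_tgt[deg == 0L] <- list(integer(0))
  }
  V <- v0; ge <- numeric(N); gi <- numeric(N); refc <- integer(N)
  spikes_id <- integer(0); spikes_t <- numeric(0)
  arrival <- max(1L, d_steps)
  for (step in seq_len(n_steps)) {
    ge <- ge * decay + inc_ge[step, ] + inc_ext[step, ]
    gi <- gi * decay + inc_gi[step, ]
    active <- refc == 0L
    refc[!active] <- refc[!active] - 1L
    V[!active] <- neuron$Vreset_mV
    i_leak <- -neuron$gL_nS * (V - neuron$VL_mV)
    i_syn <- -ge * (V - neuron$Vexc_mV) - gi * (V - neuron$Vinh_mV)
    V[active] <- V[active] + dt_ms * (i_leak + i_syn)[active] / neuron$C_pF
    sp <- which(active & V >= neuron$Vtheta_mV)
    if (length(sp)) {
      spikes_id <- c(spikes_id, sp)
      spikes_t <- c(spikes_t, rep(step * dt_ms, length(sp)))
      V[sp] <- neuron$Vreset_mV
      refc[sp] <- ref_steps
      for (s in sp) {
        tg <- out_tgt[[s]]
        if (!length(tg)) next
        at <- step + arrival
        if (s <= NE) {
          w <- ifelse(tg <= NE, w_ee, w_ei)
          inc_ge[at, tg] <- inc_ge[at, tg] + w
        } else {
          w <- ifelse(tg <= NE, w_ie, w_ii)
          inc_gi[at, tg] <- inc_gi[at, tg] + w
        }
      }
    }
  }
  list(spikes = data.frame(neuron = spikes_id, time_ms = spikes_t),
       duration_ms = duration_ms, NE = NE, NI = spec$NI)
}

# Draw a per-neuron external event schedule matching the model's compound
# Poisson drive (thalamic + background, weights by population).
draw_ext_schedule <- function(spec, input, duration_ms, seed) {
  l4ei:::with_seed(seed, {
    lapply(seq_len(spec$N), function(i) {
      w_th <- if (i <= spec$NE) input$js_nS else input$g_fw * input$js_nS
      draw_train <- function(rate_hz, w) {
        if (rate_hz <= 0) return(cbind(numeric(0), numeric(0)))
        n_exp <- rate_hz * duration_ms / 1000
        t <- cumsum(rexp(ceiling(n_exp + 6 * sqrt(n_exp) + 20), rate_hz / 1000))
        t <- t[t < duration_ms]
        cbind(t, rep(w, length(t)))
      }
      ev <- rbind(draw_train(input$n_lgn * input$R_lgn_hz, w_th),
                  draw_train(input$n_bkg * input$R_bkg_hz, input$js_nS))
      ev[order(ev[, 1]), , drop = FALSE]
    })
  })
}
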