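# Conductance-based leaky integrate-and-fire network of layer 4: parameter
# containers, random wiring with exact in-degrees, and the exponential-Euler
# integrator (compiled; see src/lif_network.cpp).

#' Single-neuron parameters of the LIF model
#'
#' Defaults reproduce the layer 4 model cell: membrane equation
#' `C dV/dt = -gL (V - VL) + Isyn(t)` with conductance-based synapses
#' `Isyn = -gexc (V - Vexc) - ginh (V - Vinh)` and exponential conductance
#' decay (tau 5 ms). Reset potential and refractory period are not constrained
#' by the measured data; the defaults (reset to rest, 2 ms refractory) follow
#' standard sparse-random-network practice and are recorded in all outputs.
#'
#' @param C_pF Membrane capacitance (pF).
#' @param gL_nS Leak conductance (nS).
#' @param VL_mV Leak/resting potential (mV).
#' @param Vexc_mV Excitatory reversal potential (mV).
#' @param Vinh_mV Inhibitory reversal potential (mV).
#' @param Vtheta_mV Firing threshold (mV).
#' @param Vreset_mV Post-spike reset potential (mV).
#' @param t_ref_ms Absolute refractory period (ms).
#' @param tau_syn_ms Synaptic conductance decay constant (ms).
#' @return An object of class `l4_neuron_params`.
#' @examples
#' neuron_params()  # the layer 4 model cell
#' @export
neuron_params <- function(C_pF = 200, gL_nS = 10, VL_mV = -70, Vexc_mV = 0,
                          Vinh_mV = -85, Vtheta_mV = -50, Vreset_mV = -70,
                          t_ref_ms = 2, tau_syn_ms = 5) {
  check_positive_scalar(C_pF, "C_pF")
  check_positive_scalar(gL_nS, "gL_nS")
  check_positive_scalar(tau_syn_ms, "tau_syn_ms")
  if (t_ref_ms < 0) stop_l4ei("l4ei_invalid_spec", "`t_ref_ms` must be >= 0")
  if (!(Vinh_mV < VL_mV && VL_mV < Vtheta_mV && Vtheta_mV < Vexc_mV)) {
    stop_l4ei("l4ei_invalid_spec",
              "potentials must satisfy Vinh < VL < Vtheta < Vexc")
  }
  structure(list(C_pF = C_pF, gL_nS = gL_nS, VL_mV = VL_mV, Vexc_mV = Vexc_mV,
                 Vinh_mV = Vinh_mV, Vtheta_mV = Vtheta_mV, Vreset_mV = Vreset_mV,
                 t_ref_ms = t_ref_ms, tau_syn_ms = tau_syn_ms),
            class = "l4_neuron_params")
}

#' Network architecture parameters
#'
#' Defaults give the full-size circuit: 5000 cells (80% excitatory), every
#' cell receiving exactly 400 excitatory and 100 inhibitory recurrent
#' connections (fixed in-degree; the 10% connection probability is the
#' resulting density, not the wiring rule), excitatory peak conductance
#' `j = 0.3 nS` and inhibitory peak conductance `g_rc * j = 2.4 nS`.
#'
#' @param N Total number of cells.
#' @param NE,NI Number of excitatory / inhibitory cells (`NE + NI = N`).
#' @param in_degree_e,in_degree_i Exact excitatory / inhibitory in-degrees.
#' @param j_nS Excitatory peak conductance (nS).
#' @param g_rc Relative strength of recurrent inhibition (dimensionless);
#'   inhibitory peak conductance is `g_rc * j_nS`.
#' @param delay_ms Recurrent synaptic delay (ms). Not constrained by the
#'   measured data; a nonzero default (1 ms) avoids same-step feedback
#'   artifacts.
#' @return An object of class `l4_network_spec`.
#' @export
network_spec <- function(N = 5000, NE = round(0.8 * N), NI = N - NE,
                         in_degree_e = 400, in_degree_i = 100,
                         j_nS = 0.3, g_rc = 8, delay_ms = 1) {
  if (NE + NI != N) stop_l4ei("l4ei_invalid_spec", "`NE + NI` must equal `N`")
  if (NE < 1L || NI < 1L) stop_l4ei("l4ei_invalid_spec", "both populations must be non-empty")
  if (in_degree_e > NE - 1L || in_degree_i > NI - 1L) {
    stop_l4ei("l4ei_config_error",
              "in-degrees must be feasible without autapses (in_degree_e <= NE - 1, in_degree_i <= NI - 1)")
  }
  if (j_nS <= 0 || g_rc <= 0) stop_l4ei("l4ei_invalid_spec", "`j_nS` and `g_rc` must be > 0")
  if (delay_ms < 0) stop_l4ei("l4ei_invalid_spec", "`delay_ms` must be >= 0")
  structure(list(N = as.integer(N), NE = as.integer(NE), NI = as.integer(NI),
                 in_degree_e = as.integer(in_degree_e),
                 in_degree_i = as.integer(in_degree_i),
                 j_nS = j_nS, g_rc = g_rc, delay_ms = delay_ms),
            class = "l4_network_spec")
}

#' External (thalamic and background) input parameters
#'
#' Every cell receives `n_lgn` independent thalamic Poisson trains at
#' `R_lgn_hz` and `n_bkg` background trains at `R_bkg_hz`. Thalamic drive onto
#' inhibitory cells is scaled by the feedforward pre-factor `g_fw` (> 1,
#' reflecting the stronger thalamic recruitment of PV+ interneurons);
#' background weight is identical for both cell types and is never scaled by
#' any plasticity scenario.
#'
#' @param js_nS Thalamic/background input peak conductance (nS).
#' @param g_fw Feedforward pre-factor on thalamic drive to inhibitory cells
#'   (dimensionless; default 1.25 so that `g_fw * js = 0.625 nS`).
#' @param n_lgn,R_lgn_hz Number and rate of thalamic trains per neuron.
#' @param n_bkg,R_bkg_hz Number and rate of background trains per neuron.
#' @return An object of class `l4_input_spec`.
#' @export
input_spec <- function(js_nS = 0.5, g_fw = 1.25, n_lgn = 100, R_lgn_hz = 8,
                       n_bkg = 100, R_bkg_hz = 14.2) {
  check_positive_scalar(js_nS, "js_nS")
  check_positive_scalar(g_fw, "g_fw")
  if (n_lgn < 0 || n_bkg < 0 || R_lgn_hz < 0 || R_bkg_hz < 0) {
    stop_l4ei("l4ei_invalid_spec", "input counts and rates must be >= 0")
  }
  structure(list(js_nS = js_nS, g_fw = g_fw, n_lgn = n_lgn, R_lgn_hz = R_lgn_hz,
                 n_bkg = n_bkg, R_bkg_hz = R_bkg_hz),
            class = "l4_input_spec")
}

#' Build random connectivity with exact in-degrees
#'
#' For every neuron, samples exactly `in_degree_e` distinct excitatory and
#' `in_degree_i` distinct inhibitory presynaptic partners uniformly without
#' replacement, excluding the neuron itself. Neurons `1..NE` are excitatory,
#' `NE+1..N` inhibitory.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed; wiring is deterministic given `(spec, seed)`.
#' @return An object of class `l4_connectivity` holding the per-neuron source
#'   matrices (`exc_sources`, `inh_sources`) and a CSR outgoing-edge index
#'   used by the integrator.
#' @export
build_connectivity <- function(spec, seed) {
  stopifnot(inherits(spec, "l4_network_spec"))
  with_seed(seed, {
    N <- spec$N; NE <- spec$NE; NI <- spec$NI
    ke <- spec$in_degree_e; ki <- spec$in_degree_i
    exc <- matrix(0L, nrow = ke, ncol = N)
    inh <- matrix(0L, nrow = ki, ncol = N)
    for (tgt in seq_len(N)) {
      if (tgt <= NE) {
        s <- sample.int(NE - 1L, ke)          # sample among E excluding self
        s[s >= tgt] <- s[s >= tgt] + 1L
        exc[, tgt] <- s
        inh[, tgt] <- NE + sample.int(NI, ki)
      } else {
        exc[, tgt] <- sample.int(NE, ke)
        self_i <- tgt - NE
        s <- sample.int(NI - 1L, ki)
        s[s >= self_i] <- s[s >= self_i] + 1L
        inh[, tgt] <- NE + s
      }
    }
    # outgoing-edge CSR (0-based targets) for spike propagation
    src <- c(as.integer(exc), as.integer(inh))
    tgt <- c(rep(seq_len(N), each = ke), rep(seq_len(N), each = ki))
    ord <- order(src)
    counts <- tabulate(src, nbins = N)
    structure(list(exc_sources = exc, inh_sources = inh,
                   out_ptr = c(0L, cumsum(counts)),
                   out_idx = tgt[ord] - 1L,
                   spec = spec, seed = seed),
              class = "l4_connectivity")
  })
}

#' @export
print.l4_connectivity <- function(x, ...) {
  cat(sprintf("<l4_connectivity> N = %d (NE = %d, NI = %d), in-degrees %d E / %d I, seed %s\n",
              x$spec$N, x$spec$NE, x$spec$NI,
              x$spec$in_degree_e, x$spec$in_degree_i, format(x$seed)))
  invisible(x)
}

identity_multipliers <- function() {
  list(thal_e = 1, thal_i = 1, ee = 1, ei = 1, ie = 1, ii = 1, bkg = 1)
}

#' Simulate the layer 4 network
#'
#' Integrates all membranes with the exponential-Euler scheme (exact
#' exponential conductance decay between updates). Each presynaptic spike
#' increments the conductance of its targets by the pathway's peak conductance
#' after the recurrent delay; external thalamic and background drive are
#' compound Poisson processes (the per-neuron trains share one weight, so
#' collapsing them is distributionally exact). Initial voltages are drawn
#' uniformly on `[VL, Vtheta)` unless `init = "rest"`.
#'
#' @param neuron A [neuron_params()].
#' @param spec A [network_spec()].
#' @param input An [input_spec()].
#' @param conn A [build_connectivity()] result, or `NULL` for an unconnected
#'   (feedforward-only) population.
#' @param duration_ms Simulated time (ms).
#' @param seed Integer seed for the input realization and initial conditions.
#' @param weight_overrides Named list of per-pathway multipliers
#'   (`thal_e`, `thal_i`, `ee`, `ei`, `ie`, `ii`, `bkg`), as produced by
#'   [apply_scenario()]; missing entries default to 1.
#' @param dt_ms Integration step (default 0.1 ms).
#' @param transient_discard_ms Initial transient excluded from rate estimates.
#' @param init `"uniform"` (default) or `"rest"` initial voltages.
#' @param apply_threshold Set `FALSE` to integrate the free membrane potential
#'   (no spiking); used by analytic oracles.
#' @param record_vmean Record each neuron's time-averaged voltage after the
#'   transient.
#' @param record_v Record the full voltage matrix (small networks only).
#' @param ext_events Optional list of `N` two-column matrices
#'   `(time_ms, weight_nS)` replacing the internal Poisson drive; used to pin
#'   the input realization for integrator cross-checks.
#' @param i_ext_pA Constant injected current (pA).
#' @param g_exc_clamp_nS Constant clamped excitatory conductance (nS).
#' @return An object of class `sim_result`: `spikes` (data frame `neuron`,
#'   `time_ms`), steady-state `rate_e` and `rate_i` (Hz), and the run
#'   metadata.
#' @export
simulate_network <- function(neuron, spec, input, conn = NULL,
                             duration_ms = 9000, seed = 1,
                             weight_overrides = NULL, dt_ms = 0.1,
                             transient_discard_ms = 500,
                             init = c("uniform", "rest"),
                             apply_threshold = TRUE,
                             record_vmean = FALSE, record_v = FALSE,
                             ext_events = NULL, i_ext_pA = 0,
                             g_exc_clamp_nS = 0) {
  stopifnot(inherits(neuron, "l4_neuron_params"),
            inherits(spec, "l4_network_spec"),
            inherits(input, "l4_input_spec"))
  check_positive_scalar(duration_ms, "duration_ms")
  check_positive_scalar(dt_ms, "dt_ms")
  init <- match.arg(init)
  if (transient_discard_ms >= duration_ms) {
    stop_l4ei("l4ei_invalid_window", "`transient_discard_ms` must be < `duration_ms`")
  }
  m <- identity_multipliers()
  if (!is.null(weight_overrides)) {
    bad <- setdiff(names(weight_overrides), names(m))
    if (length(bad)) stop_l4ei("l4ei_invalid_spec",
                               paste("unknown pathway multiplier:", paste(bad, collapse = ", ")))
    m[names(weight_overrides)] <- weight_overrides
  }
  if (is.null(conn)) {
    out_ptr <- integer(spec$N + 1L)
    out_idx <- integer(0)
  } else {
    stopifnot(inherits(conn, "l4_connectivity"))
    if (conn$spec$N != spec$N || conn$spec$NE != spec$NE) {
      stop_l4ei("l4ei_config_error", "connectivity does not match the network spec")
    }
    out_ptr <- conn$out_ptr
    out_idx <- conn$out_idx
  }
  res <- with_seed(seed, {
    lif_simulate_cpp(
      C = neuron$C_pF, gL = neuron$gL_nS, VL = neuron$VL_mV,
      Vexc = neuron$Vexc_mV, Vinh = neuron$Vinh_mV,
      Vtheta = neuron$Vtheta_mV, Vreset = neuron$Vreset_mV,
      t_ref = neuron$t_ref_ms, tau_syn = neuron$tau_syn_ms,
      NE = spec$NE, NI = spec$NI,
      out_ptr = out_ptr, out_idx = out_idx,
      w_ee = spec$j_nS * m$ee, w_ei = spec$j_nS * m$ei,
      w_ie = spec$g_rc * spec$j_nS * m$ie, w_ii = spec$g_rc * spec$j_nS * m$ii,
      delay_ms = spec$delay_ms,
      rate_thal_hz = input$n_lgn * input$R_lgn_hz,
      rate_bkg_hz = input$n_bkg * input$R_bkg_hz,
      w_thal_e = input$js_nS * m$thal_e,
      w_thal_i = input$g_fw * input$js_nS * m$thal_i,
      w_bkg = input$js_nS * m$bkg,
      i_ext_pA = i_ext_pA, g_exc_clamp_nS = g_exc_clamp_nS,
      duration_ms = duration_ms, dt_ms = dt_ms,
      init_uniform = (init == "uniform"),
      apply_threshold = apply_threshold,
      record_v = record_v,
      vmean_discard_ms = if (record_vmean) transient_discard_ms else -1,
      ext_events_ = ext_events
    )
  })
  out <- structure(
    list(spikes = data.frame(neuron = res$spike_neuron, time_ms = res$spike_time),
         duration_ms = duration_ms,
         transient_discard_ms = transient_discard_ms,
         NE = spec$NE, NI = spec$NI,
         dt_ms = dt_ms, seed = seed,
         multipliers = m,
         decision_params = list(Vreset_mV = neuron$Vreset_mV,
                                t_ref_ms = neuron$t_ref_ms,
                                delay_ms = spec$delay_ms, dt_ms = dt_ms,
                                init = init)),
    class = "sim_result")
  rates <- population_rates(out, transient_discard_ms)
  out$rate_e <- rates[["rate_e"]]
  out$rate_i <- rates[["rate_i"]]
  if (record_vmean) out$vmean_mV <- res$vmean
  if (record_v) out$v_mV <- res$V
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.0f ms (transient %.0f ms), %d spikes; rate E %.2f Hz, I %.2f Hz\n",
              x$duration_ms, x$transient_discard_ms, nrow(x$spikes),
              x$rate_e, x$rate_i))
  invisible(x)
}

#' Steady-state population firing rates
#'
#' Mean rate per neuron of each population, counting spikes from
#' `transient_discard_ms` to the end of the simulation.
#'
#' @param result A `sim_result` (or any list with `spikes`, `duration_ms`,
#'   `NE`, `NI`).
#' @param transient_discard_ms Transient to discard (ms).
#' @return Named numeric vector `c(rate_e = , rate_i = )` in Hz.
#' @export
population_rates <- function(result, transient_discard_ms = result$transient_discard_ms) {
  window_ms <- result$duration_ms - transient_discard_ms
  if (window_ms <= 0) stop_l4ei("l4ei_invalid_window", "empty analysis window")
  keep <- result$spikes$time_ms >= transient_discard_ms
  ids <- result$spikes$neuron[keep]
  n_e <- sum(ids <= result$NE)
  n_i <- length(ids) - n_e
  c(rate_e = n_e / result$NE / (window_ms / 1000),
    rate_i = n_i / result$NI / (window_ms / 1000))
}

#' Analytic free-membrane statistics under Poisson drive
#'
#' Mean excitatory conductance by Campbell's theorem,
#' `mean_g = weight * tau_syn * total rate`, and the corresponding mean free
#' membrane potential (threshold ignored). Serves as the closed-form oracle
#' for the integrator.
#'
#' @param neuron A [neuron_params()].
#' @param input An [input_spec()].
#' @param is_inhibitory Whether the cell is inhibitory (thalamic weight is
#'   then scaled by `g_fw`).
#' @return List with `mean_g_exc_nS` and `mean_V_mV`.
#' @export
free_membrane_stats <- function(neuron, input, is_inhibitory = FALSE) {
  w_thal <- if (is_inhibitory) input$g_fw * input$js_nS else input$js_nS
  mean_g <- (w_thal * input$n_lgn * input$R_lgn_hz +
               input$js_nS * input$n_bkg * input$R_bkg_hz) *
    neuron$tau_syn_ms / 1000
  mean_v <- (neuron$gL_nS * neuron$VL_mV + mean_g * neuron$Vexc_mV) /
    (neuron$gL_nS + mean_g)
  list(mean_g_exc_nS = mean_g, mean_V_mV = mean_v)
}

# Single isolated LIF neuron under constant current / clamped conductance;
# shared by the FI protocol generator and the simulator oracle tests.
lif_single_neuron <- function(neuron, duration_ms, dt_ms = 0.05, i_ext_pA = 0,
                              g_exc_clamp_nS = 0, record_v = FALSE) {
  res <- lif_simulate_cpp(
    C = neuron$C_pF, gL = neuron$gL_nS, VL = neuron$VL_mV,
    Vexc = neuron$Vexc_mV, Vinh = neuron$Vinh_mV,
    Vtheta = neuron$Vtheta_mV, Vreset = neuron$Vreset_mV,
    t_ref = neuron$t_ref_ms, tau_syn = neuron$tau_syn_ms,
    NE = 1L, NI = 0L,
    out_ptr = integer(2), out_idx = integer(0),
    w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0, delay_ms = 0,
    rate_thal_hz = 0, rate_bkg_hz = 0,
    w_thal_e = 0, w_thal_i = 0, w_bkg = 0,
    i_ext_pA = i_ext_pA, g_exc_clamp_nS = g_exc_clamp_nS,
    duration_ms = duration_ms, dt_ms = dt_ms,
    init_uniform = FALSE, apply_threshold = TRUE,
    record_v = record_v, vmean_discard_ms = -1, ext_events_ = NULL
  )
  list(spike_times_ms = res$spike_time,
       v_mV = if (record_v) as.numeric(res$V) else NULL,
       dt_ms = dt_ms)
}
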