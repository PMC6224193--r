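# Synthetic-data generators: every recording paradigm the quantification
# pipeline consumes, with exact ground truth attached so parameter recovery
# can be tested without any real recordings.

#' Specification of a synthetic trace
#'
#' @param duration_ms Trace duration (ms), positive.
#' @param sample_interval_ms Sampling interval (ms); default 0.1 ms (10 kHz).
#' @param noise_sd_pA Standard deviation of i.i.d. Gaussian sample noise (pA).
#' @param baseline_pA Constant baseline (holding) current (pA).
#' @param seed Integer seed; identical spec + seed gives a bit-identical trace.
#' @return An object of class `synth_trace_spec`.
#' @export
trace_spec <- function(duration_ms, sample_interval_ms = 0.1, noise_sd_pA = 1,
                       baseline_pA = 0, seed = 1) {
  check_positive_scalar(duration_ms, "duration_ms")
  check_positive_scalar(sample_interval_ms, "sample_interval_ms")
  if (!is.numeric(noise_sd_pA) || noise_sd_pA < 0) {
    stop_l4ei("l4ei_invalid_spec", "`noise_sd_pA` must be >= 0")
  }
  structure(list(duration_ms = duration_ms,
                 sample_interval_ms = sample_interval_ms,
                 noise_sd_pA = noise_sd_pA,
                 baseline_pA = baseline_pA,
                 seed = seed),
            class = "synth_trace_spec")
}

new_ground_truth <- function(...) {
  structure(list(...), class = "ground_truth")
}

blank_trace_samples <- function(spec) {
  n <- floor(spec$duration_ms / spec$sample_interval_ms) + 1L
  cur <- rep(spec$baseline_pA, n)
  if (spec$noise_sd_pA > 0) cur <- cur + rnorm(n, 0, spec$noise_sd_pA)
  cur
}

#' Generate a miniature-EPSC trace
#'
#' Simulates a continuous voltage-clamp recording of quantal excitatory events
#' (mEPSCs): Gaussian baseline noise plus inward difference-of-exponentials
#' events at homogeneous-Poisson times, with lognormal peak amplitudes of the
#' requested mean and CV. Ground truth lists every seeded event, enabling
#' recall and amplitude-recovery tests of [detect_events()].
#'
#' @param spec A [trace_spec()].
#' @param kinetics An [event_kinetics()].
#' @param event_rate_hz Mean event rate in Hz (>= 0).
#' @return A list with elements `trace` (an `ephys_trace` at -70 mV) and
#'   `truth` (a `ground_truth` with `event_times`, `event_amps`).
#' @examples
#' out <- gen_mepsc_trace(trace_spec(2000, noise_sd_pA = 1, seed = 7),
#'                        event_kinetics(amp_mean_pA = 15), event_rate_hz = 4)
#' length(out$truth$event_times)
#' @export
gen_mepsc_trace <- function(spec, kinetics, event_rate_hz) {
  stopifnot(inherits(spec, "synth_trace_spec"), inherits(kinetics, "event_kinetics"))
  if (!is.numeric(event_rate_hz) || event_rate_hz < 0) {
    stop_l4ei("l4ei_invalid_spec", "`event_rate_hz` must be >= 0")
  }
  with_seed(spec$seed, {
    n_ev <- if (event_rate_hz > 0) rpois(1L, event_rate_hz * spec$duration_ms / 1000) else 0L
    times <- sort(runif(n_ev, 0, spec$duration_ms))
    amps <- rlnorm_mean_cv(n_ev, kinetics$amp_mean_pA, kinetics$amp_cv)
    cur <- blank_trace_samples(spec)
    cur <- add_kernel_events(cur, spec$sample_interval_ms, times, amps, kinetics, sign = -1)
    list(trace = new_trace(cur, spec$sample_interval_ms, holding_mV = -70),
         truth = new_ground_truth(event_times = times, event_amps = amps))
  })
}

#' Generate an optogenetically evoked quantal-event trace
#'
#' Emulates the desynchronized-release paradigm: spontaneous quantal events at
#' `base_rate_hz` throughout the sweep, elevated to `base_rate_hz *
#' evoked_factor` inside the laser window. Events are labelled spontaneous or
#' evoked in the ground truth.
#'
#' @inheritParams gen_mepsc_trace
#' @param base_rate_hz Spontaneous event rate (Hz).
#' @param evoked_factor Rate multiplier inside the laser window (>= 1).
#' @param laser_window Numeric `c(start, stop)` in ms, strictly inside the
#'   trace and of positive length.
#' @return A list with `trace` (markers at the window edges) and `truth`
#'   (`event_times`, `event_amps`, `epoch` labels, `true_factor`).
#' @export
gen_optogenetic_quantal_trace <- function(spec, kinetics, base_rate_hz,
                                          evoked_factor, laser_window) {
  stopifnot(inherits(spec, "synth_trace_spec"), inherits(kinetics, "event_kinetics"))
  if (!is.numeric(evoked_factor) || evoked_factor < 1) {
    stop_l4ei("l4ei_invalid_spec", "`evoked_factor` must be >= 1")
  }
  if (length(laser_window) != 2L || laser_window[2L] <= laser_window[1L] ||
      laser_window[1L] < 0 || laser_window[2L] > spec$duration_ms) {
    stop_l4ei("l4ei_invalid_window",
              "`laser_window` must be (start, stop) with start < stop, inside the trace")
  }
  with_seed(spec$seed, {
    segs <- rbind(c(0, laser_window[1L], base_rate_hz),
                  c(laser_window[1L], laser_window[2L], base_rate_hz * evoked_factor),
                  c(laser_window[2L], spec$duration_ms, base_rate_hz))
    times <- numeric(0)
    for (s in seq_len(nrow(segs))) {
      len <- segs[s, 2L] - segs[s, 1L]
      if (len <= 0 || segs[s, 3L] <= 0) next
      n <- rpois(1L, segs[s, 3L] * len / 1000)
      times <- c(times, runif(n, segs[s, 1L], segs[s, 2L]))
    }
    times <- sort(times)
    epoch <- ifelse(times >= laser_window[1L] & times < laser_window[2L],
                    "evoked", "spontaneous")
    amps <- rlnorm_mean_cv(length(times), kinetics$amp_mean_pA, kinetics$amp_cv)
    cur <- blank_trace_samples(spec)
    cur <- add_kernel_events(cur, spec$sample_interval_ms, times, amps, kinetics, sign = -1)
    markers <- data.frame(time_ms = laser_window, label = c("laser_on", "laser_off"))
    list(trace = new_trace(cur, spec$sample_interval_ms, holding_mV = -70, markers = markers),
         truth = new_ground_truth(event_times = times, event_amps = amps,
                                  epoch = epoch, true_factor = evoked_factor))
  })
}

#' Generate a family of paired EPSC/IPSC sweeps
#'
#' One EPSC sweep (holding -70 mV, inward) and one IPSC sweep (holding 0 mV,
#' outward) per stimulus intensity, with true charges scaling linearly with
#' intensity: `e_gain * level` and `i_gain * level` pC. Amplitudes are
#' calibrated on the sampling grid so the noiseless trapezoidal charge of each
#' evoked current equals its target exactly.
#'
#' @param intensities Strictly increasing vector of stimulus levels.
#' @param e_gain,i_gain Charge per intensity level (pC/level), >= 0.
#' @param kinetics_e,kinetics_i [event_kinetics()] of the evoked EPSC / IPSC.
#' @param noise_sd_pA Gaussian sample noise (pA).
#' @param seed Integer seed.
#' @param stim_time_ms Stimulus time within each sweep (default 20 ms).
#' @param sweep_duration_ms Sweep length (default 220 ms).
#' @param sample_interval_ms Sampling interval (default 0.1 ms).
#' @param latency_ms Synaptic onset latency after the stimulus (default 2 ms).
#' @return A list with `sweeps` (an `ei_sweep_set`) and `truth` holding the
#'   per-intensity true charges and `true_ratio = e_gain / i_gain`.
#' @export
gen_paired_ei_sweeps <- function(intensities, e_gain, i_gain,
                                 kinetics_e = event_kinetics(0.5, 5),
                                 kinetics_i = event_kinetics(0.5, 5),
                                 noise_sd_pA = 0, seed = 1,
                                 stim_time_ms = 20, sweep_duration_ms = 220,
                                 sample_interval_ms = 0.1, latency_ms = 2) {
  if (length(intensities) == 0L || any(diff(intensities) <= 0)) {
    stop_l4ei("l4ei_invalid_spec", "`intensities` must be non-empty and strictly increasing")
  }
  if (e_gain < 0 || i_gain < 0) {
    stop_l4ei("l4ei_invalid_spec", "gains must be >= 0")
  }
  dt <- sample_interval_ms
  n <- floor(sweep_duration_ms / dt) + 1L
  qe_unit <- kernel_unit_charge(kinetics_e, dt)   # pA*ms per unit peak
  qi_unit <- kernel_unit_charge(kinetics_i, dt)
  onset <- stim_time_ms + latency_ms
  markers <- data.frame(time_ms = stim_time_ms, label = "stim")
  with_seed(seed, {
    pairs <- lapply(intensities, function(level) {
      # 1 pC = 1000 pA*ms
      amp_e <- 1000 * e_gain * level / qe_unit
      amp_i <- 1000 * i_gain * level / qi_unit
      ce <- rnorm(n, 0, noise_sd_pA) * (noise_sd_pA > 0)
      ci <- rnorm(n, 0, noise_sd_pA) * (noise_sd_pA > 0)
      ce <- add_kernel_events(ce, dt, onset, amp_e, kinetics_e, sign = -1)
      ci <- add_kernel_events(ci, dt, onset, amp_i, kinetics_i, sign = +1)
      list(intensity = level,
           epsc = new_trace(ce, dt, holding_mV = -70, markers = markers),
           ipsc = new_trace(ci, dt, holding_mV = 0, markers = markers))
    })
    sweeps <- structure(list(pairs = pairs), class = "ei_sweep_set")
    truth <- new_ground_truth(
      true_e_charge_pC = e_gain * intensities,
      true_i_charge_pC = i_gain * intensities,
      true_ratio = if (i_gain > 0) e_gain / i_gain else NA_real_
    )
    list(sweeps = sweeps, truth = truth)
  })
}

#' @export
print.ei_sweep_set <- function(x, ...) {
  cat(sprintf("<ei_sweep_set> %d intensity pair(s)\n", length(x$pairs)))
  invisible(x)
}

#' Generate an LTD amplitude time series
#'
#' One evoked-EPSC amplitude per minute: `n_pre` baseline minutes, a 10 min
#' induction gap, then `n_post` post-induction minutes whose mean is
#' `baseline_amp_pA * post_factor`. Noise is multiplicative lognormal with the
#' given CV, so the recovered post/pre ratio is unbiased.
#'
#' @param n_pre Number of baseline minutes (>= 1).
#' @param n_post Number of post-induction minutes; at least 31 so the standard
#'   5-30 min analysis window exists.
#' @param baseline_amp_pA Baseline EPSC amplitude in pA; accepted range
#'   100-700 pA, matching the evoked-amplitude criterion of the protocol.
#' @param post_factor True post/pre amplitude ratio (dimensionless).
#' @param noise_cv Multiplicative noise CV (fraction).
#' @param seed Integer seed.
#' @param induction_duration_min Minutes occupied by the 1 Hz pairing
#'   induction (default 10).
#' @return A list with `experiment` (an `ltd_experiment`: per-minute
#'   amplitudes plus `induction_end`) and `truth` (`true_factor`).
#' @export
gen_ltd_series <- function(n_pre, n_post, baseline_amp_pA, post_factor,
                           noise_cv = 0, seed = 1, induction_duration_min = 10) {
  if (n_pre < 1L) stop_l4ei("l4ei_invalid_spec", "`n_pre` must be >= 1")
  if (n_post < 31L) {
    stop_l4ei("l4ei_window_infeasible",
              "`n_post` must be >= 31 so the 5-30 min post-induction window exists")
  }
  if (baseline_amp_pA < 100 || baseline_amp_pA > 700) {
    stop_l4ei("l4ei_invalid_spec", "`baseline_amp_pA` must lie in the accepted 100-700 pA range")
  }
  check_positive_scalar(post_factor, "post_factor")
  with_seed(seed, {
    pre_min <- seq_len(n_pre)
    induction_end <- n_pre + induction_duration_min
    post_min <- induction_end + seq_len(n_post)
    amp <- c(rlnorm_mean_cv(n_pre, baseline_amp_pA, noise_cv),
             rlnorm_mean_cv(n_post, baseline_amp_pA * post_factor, noise_cv))
    experiment <- structure(
      list(amplitudes = data.frame(minute = c(pre_min, post_min),
                                   amp_pA = amp,
                                   phase = rep(c("pre", "post"), c(n_pre, n_post))),
           induction_end = induction_end),
      class = "ltd_experiment")
    list(experiment = experiment, truth = new_ground_truth(true_factor = post_factor))
  })
}

#' Generate minimal-stimulation unitary-IPSC trials
#'
#' Each trial is a short sweep around one laser stimulus: with probability
#' `p_success` it contains a stereotyped unitary IPSC of peak `unitary_amp_pA`
#' (positive-going), otherwise noise only. Emulates tuning the stimulus until
#' roughly half the stimuli evoke a response.
#'
#' @param n_trials Number of trials (>= 1).
#' @param p_success Per-trial success probability in `[0, 1]`.
#' @param unitary_amp_pA Unitary IPSC peak amplitude (pA).
#' @param noise_sd_pA Gaussian sample noise (pA).
#' @param kinetics [event_kinetics()] of the IPSC waveform.
#' @param seed Integer seed.
#' @param stim_time_ms Stimulus time within the sweep (default 10 ms).
#' @param duration_ms Sweep length (default 60 ms).
#' @param latency_ms Onset latency after the stimulus (default 3 ms).
#' @return A list with `trials` (a `trial_set`) and `truth` (logical
#'   `success`, `true_amp_pA`).
#' @export
gen_minimal_stim_trials <- function(n_trials, p_success, unitary_amp_pA,
                                    noise_sd_pA = 2,
                                    kinetics = event_kinetics(0.8, 8),
                                    seed = 1, stim_time_ms = 10,
                                    duration_ms = 60, latency_ms = 3) {
  if (n_trials < 1L) stop_l4ei("l4ei_empty_trials", "`n_trials` must be >= 1")
  if (p_success < 0 || p_success > 1) {
    stop_l4ei("l4ei_invalid_spec", "`p_success` must lie in [0, 1]")
  }
  check_positive_scalar(unitary_amp_pA, "unitary_amp_pA")
  dt <- 0.1
  n <- floor(duration_ms / dt) + 1L
  markers <- data.frame(time_ms = stim_time_ms, label = "stim")
  with_seed(seed, {
    success <- rbinom(n_trials, 1L, p_success) == 1L
    trials <- lapply(seq_len(n_trials), function(k) {
      cur <- if (noise_sd_pA > 0) rnorm(n, 0, noise_sd_pA) else numeric(n)
      if (success[k]) {
        cur <- add_kernel_events(cur, dt, stim_time_ms + latency_ms,
                                 unitary_amp_pA, kinetics, sign = +1)
      }
      new_trace(cur, dt, holding_mV = -40, markers = markers)
    })
    trial_set <- structure(list(trials = trials, stim_time_ms = stim_time_ms),
                           class = "trial_set")
    list(trials = trial_set,
         truth = new_ground_truth(success = success, true_amp_pA = unitary_amp_pA))
  })
}

#' Simulate an FI (firing rate vs current) protocol
#'
#' Runs the single leaky integrate-and-fire neuron of the network model under
#' a family of 1 s square current injections (no synaptic input), recording
#' membrane voltage and spike times per step — the in-silico analogue of an
#' intrinsic-excitability experiment.
#'
#' @param neuron A [neuron_params()].
#' @param current_steps_pA Strictly increasing vector of injected currents (pA).
#' @param step_duration_ms Duration of each injection (default 1000 ms).
#' @param dt_ms Integration step (default 0.05 ms).
#' @return An object of class `fi_recording`: per-step voltage traces and
#'   spike times, plus the protocol metadata.
#' @export
gen_fi_protocol <- function(neuron, current_steps_pA, step_duration_ms = 1000,
                            dt_ms = 0.05) {
  stopifnot(inherits(neuron, "l4_neuron_params"))
  if (length(current_steps_pA) == 0L || any(diff(current_steps_pA) <= 0)) {
    stop_l4ei("l4ei_invalid_protocol",
              "`current_steps_pA` must be non-empty and strictly increasing")
  }
  check_positive_scalar(step_duration_ms, "step_duration_ms")
  steps <- lapply(current_steps_pA, function(i_pA) {
    sim <- lif_single_neuron(neuron, duration_ms = step_duration_ms,
                             dt_ms = dt_ms, i_ext_pA = i_pA, record_v = TRUE)
    list(current_pA = i_pA, spike_times_ms = sim$spike_times_ms, v_mV = sim$v_mV)
  })
  structure(list(steps = steps,
                 current_steps_pA = current_steps_pA,
                 step_duration_ms = step_duration_ms,
                 dt_ms = dt_ms,
                 neuron = neuron),
            class = "fi_recording")
}
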