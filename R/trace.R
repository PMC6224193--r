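# Containers for voltage-clamp recordings and the synaptic event kernel.

#' Construct a current trace
#'
#' A trace holds one voltage-clamp sweep: the recorded current in pA sampled at
#' a fixed interval, the holding potential, and optional stimulus markers.
#'
#' @param current_pA Numeric vector of sampled current (pA).
#' @param sample_interval_ms Sampling interval in ms (default 0.1 ms, i.e.
#'   10 kHz acquisition).
#' @param holding_mV Holding potential of the sweep (mV).
#' @param markers Data frame with columns `time_ms`, `label` marking stimulus
#'   onsets, or `NULL`.
#' @return An object of class `ephys_trace`.
#' @export
new_trace <- function(current_pA, sample_interval_ms = 0.1, holding_mV = -70,
                      markers = NULL) {
  check_positive_scalar(sample_interval_ms, "sample_interval_ms")
  if (!is.numeric(current_pA) || length(current_pA) == 0L) {
    stop_l4ei("l4ei_invalid_input", "`current_pA` must be a non-empty numeric vector")
  }
  dur <- (length(current_pA) - 1L) * sample_interval_ms
  if (!is.null(markers)) {
    stopifnot(is.data.frame(markers), all(c("time_ms", "label") %in% names(markers)))
    if (any(markers$time_ms < 0 | markers$time_ms > dur)) {
      stop_l4ei("l4ei_invalid_input", "stimulus markers must lie within the trace extent")
    }
  }
  structure(
    list(current_pA = as.numeric(current_pA),
         sample_interval_ms = sample_interval_ms,
         holding_mV = holding_mV,
         markers = markers),
    class = "ephys_trace"
  )
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %d samples @ %.3g ms (%.1f ms), holding %.0f mV, %d marker(s)\n",
              length(x$current_pA), x$sample_interval_ms,
              trace_duration(x), x$holding_mV,
              if (is.null(x$markers)) 0L else nrow(x$markers)))
  invisible(x)
}

#' Sample times of a trace
#' @param trace An `ephys_trace`.
#' @return Numeric vector of sample times in ms, starting at 0.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$current_pA) - 1L) * trace$sample_interval_ms
}

#' Duration of a trace in ms
#' @param trace An `ephys_trace`.
#' @export
trace_duration <- function(trace) {
  (length(trace$current_pA) - 1L) * trace$sample_interval_ms
}

#' Synaptic event kinetics
#'
#' Shape parameters of the stereotyped postsynaptic current used throughout
#' the synthetic generators: a difference-of-exponentials kernel with rise and
#' decay time constants, peak-normalized so that amplitude parameters are
#' literal peak amplitudes, plus the amplitude distribution (lognormal with
#' given mean and coefficient of variation).
#'
#' @param rise_tau_ms Rise time constant (ms); must be smaller than the decay.
#' @param decay_tau_ms Decay time constant (ms).
#' @param amp_mean_pA Mean peak amplitude (pA), positive.
#' @param amp_cv Coefficient of variation of the amplitude (dimensionless
#'   non-negative; 0 gives identical amplitudes).
#' @return An object of class `event_kinetics`.
#' @export
event_kinetics <- function(rise_tau_ms = 0.5, decay_tau_ms = 3,
                           amp_mean_pA = 10, amp_cv = 0.25) {
  check_positive_scalar(rise_tau_ms, "rise_tau_ms")
  check_positive_scalar(decay_tau_ms, "decay_tau_ms")
  check_positive_scalar(amp_mean_pA, "amp_mean_pA")
  if (rise_tau_ms >= decay_tau_ms) {
    stop_l4ei("l4ei_invalid_spec", "`rise_tau_ms` must be smaller than `decay_tau_ms`")
  }
  if (!is.numeric(amp_cv) || amp_cv < 0) {
    stop_l4ei("l4ei_invalid_spec", "`amp_cv` must be >= 0")
  }
  structure(list(rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 amp_mean_pA = amp_mean_pA, amp_cv = amp_cv),
            class = "event_kinetics")
}

# Time of the kernel peak: t* = a log(1 + b/a) for rise a, decay b.
kernel_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * log1p(decay_tau / rise_tau)
}

# Peak-normalized difference-of-exponentials kernel, zero for t < 0.
syn_kernel <- function(t, rise_tau, decay_tau) {
  k <- numeric(length(t))
  pos <- t >= 0
  k[pos] <- (1 - exp(-t[pos] / rise_tau)) * exp(-t[pos] / decay_tau)
  tp <- kernel_peak_time(rise_tau, decay_tau)
  kpk <- (1 - exp(-tp / rise_tau)) * exp(-tp / decay_tau)
  k / kpk
}

# Add peak-normalized kernel events (times in ms, amps in pA, sign +/-1) onto
# a current vector sampled at dt; events are truncated at the trace end.
add_kernel_events <- function(current, dt, times, amps, kinetics, sign = -1) {
  n <- length(current)
  span <- ceiling((3 * kinetics$rise_tau_ms + 18 * kinetics$decay_tau_ms) / dt)
  for (k in seq_along(times)) {
    i0 <- floor(times[k] / dt) + 1L
    if (i0 > n) next
    idx <- i0:min(n, i0 + span)
    tt <- (idx - 1L) * dt - times[k]
    current[idx] <- current[idx] +
      sign * amps[k] * syn_kernel(tt, kinetics$rise_tau_ms, kinetics$decay_tau_ms)
  }
  current
}

# Charge (pA*ms) of the unit-peak kernel on the sampling grid, used to
# calibrate amplitudes when a generator targets an exact charge.
kernel_unit_charge <- function(kinetics, dt) {
  span <- 3 * kinetics$rise_tau_ms + 18 * kinetics$decay_tau_ms
  tt <- seq(0, span, by = dt)
  trapz_uniform(syn_kernel(tt, kinetics$rise_tau_ms, kinetics$decay_tau_ms), dt)
}
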