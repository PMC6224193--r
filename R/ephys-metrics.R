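# Quantification rules that turn traces into the measured quantities:
# charges, E-I ratios, quantal statistics, LTD outcome, FI analysis,
# unitary IPSCs, and group comparisons.

# Sample indices of the half-open window [start, stop): adjacent response and
# baseline windows share no sample.
window_indices <- function(trace, window) {
  dt <- trace$sample_interval_ms
  dur <- trace_duration(trace)
  if (length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] < 0 || window[2L] > dur + dt / 2) {
    stop_l4ei("l4ei_invalid_window", "window must be (start, stop) inside the trace")
  }
  seq(ceiling(window[1L] / dt - 1e-9) + 1L, ceiling(window[2L] / dt - 1e-9))
}

#' Charge transferred in a response window
#'
#' Absolute trapezoidal integral of the baseline-subtracted current over the
#' response window, in pC. The baseline is the mean current over a separate
#' (disjoint) baseline window, conventionally the 10 ms preceding the
#' stimulus.
#'
#' @param trace An `ephys_trace`.
#' @param window Numeric `c(start, stop)` response window (ms).
#' @param baseline_window Numeric `c(start, stop)` baseline window (ms),
#'   disjoint from `window`.
#' @return Charge in pC (non-negative scalar).
#' @examples
#' tr <- new_trace(c(rep(0, 100), rep(100, 101), rep(0, 100)), 0.1)
#' charge(tr, c(10, 20.1), c(0, 9))  # 100 pA x 10 ms pulse = 1 pC
#' @export
charge <- function(trace, window, baseline_window) {
  stopifnot(inherits(trace, "ephys_trace"))
  idx <- window_indices(trace, window)
  bidx <- window_indices(trace, baseline_window)
  if (length(intersect(idx, bidx))) {
    stop_l4ei("l4ei_invalid_window", "response and baseline windows must be disjoint")
  }
  baseline <- mean(trace$current_pA[bidx])
  abs(trapz_uniform(trace$current_pA[idx] - baseline, trace$sample_interval_ms)) / 1000
}

peak_deflection <- function(trace, idx, baseline, direction) {
  d <- direction * (trace$current_pA[idx] - baseline)
  max(d, 0)
}

sweep_windows <- function(trace, window_ms, baseline_ms) {
  stim <- trace$markers$time_ms[1L]
  dur <- trace_duration(trace)
  list(resp = c(stim, min(dur, stim + window_ms)),
       base = c(max(0, stim - baseline_ms), stim))
}

#' E-I charge ratio from paired EPSC/IPSC sweeps
#'
#' Per stimulus intensity, computes the EPSC and IPSC charge (response window
#' from the stimulus marker; mean of the pre-stimulus baseline subtracted) and
#' keeps pairs whose peak amplitudes meet the acceptance minima — 150 pA
#' (EPSC) and 600 pA (IPSC) for thalamocortical recordings; use 50/600 for
#' intracortical. The ratio is EPSC charge / IPSC charge averaged over
#' surviving pairs, with linear-fit diagnostics (EPSC charge regressed on
#' IPSC charge).
#'
#' @param sweeps An `ei_sweep_set` from [gen_paired_ei_sweeps()] or built
#'   manually.
#' @param min_epsc,min_ipsc Minimum acceptable peak amplitudes (pA).
#' @param window_ms Response window length from the stimulus (default 100 ms).
#' @param baseline_ms Pre-stimulus baseline length (default 10 ms).
#' @return An `ei_ratio_result`: `mean_ratio`, `per_intensity` data frame,
#'   `fit_slope`, `fit_r2` (both `NA` with a single surviving pair).
#' @export
ei_charge_ratio <- function(sweeps, min_epsc = 150, min_ipsc = 600,
                            window_ms = 100, baseline_ms = 10) {
  stopifnot(inherits(sweeps, "ei_sweep_set"))
  rows <- lapply(sweeps$pairs, function(p) {
    we <- sweep_windows(p$epsc, window_ms, baseline_ms)
    wi <- sweep_windows(p$ipsc, window_ms, baseline_ms)
    be <- mean(p$epsc$current_pA[window_indices(p$epsc, we$base)])
    bi <- mean(p$ipsc$current_pA[window_indices(p$ipsc, wi$base)])
    data.frame(
      intensity = p$intensity,
      e_charge_pC = charge(p$epsc, we$resp, we$base),
      i_charge_pC = charge(p$ipsc, wi$resp, wi$base),
      e_peak_pA = peak_deflection(p$epsc, window_indices(p$epsc, we$resp), be, -1),
      i_peak_pA = peak_deflection(p$ipsc, window_indices(p$ipsc, wi$resp), bi, +1))
  })
  tab <- do.call(rbind, rows)
  tab$surviving <- tab$e_peak_pA >= min_epsc & tab$i_peak_pA >= min_ipsc
  if (!any(tab$surviving)) {
    n_e <- sum(tab$e_peak_pA < min_epsc)
    n_i <- sum(tab$i_peak_pA < min_ipsc)
    stop_l4ei("l4ei_all_excluded",
              sprintf("no pair meets the amplitude minima (%d below the %g pA EPSC minimum, %d below the %g pA IPSC minimum)",
                      n_e, min_epsc, n_i, min_ipsc))
  }
  s <- tab[tab$surviving, ]
  tab$ratio <- ifelse(tab$surviving, tab$e_charge_pC / tab$i_charge_pC, NA_real_)
  if (nrow(s) >= 2L) {
    fit <- lm(e_charge_pC ~ i_charge_pC, data = s)
    fit_slope <- coef(fit)[[2L]]
    fit_r2 <- cor(s$i_charge_pC, s$e_charge_pC)^2
  } else {
    fit_slope <- NA_real_
    fit_r2 <- NA_real_
  }
  structure(list(mean_ratio = mean(s$e_charge_pC / s$i_charge_pC),
                 per_intensity = tab,
                 fit_slope = fit_slope, fit_r2 = fit_r2,
                 n_surviving = nrow(s)),
            class = "ei_ratio_result")
}

#' @export
print.ei_ratio_result <- function(x, ...) {
  cat(sprintf("<ei_ratio_result> mean E-I charge ratio %.4g over %d pair(s); fit R^2 = %s\n",
              x$mean_ratio, x$n_surviving,
              ifelse(is.na(x$fit_r2), "NA", sprintf("%.3f", x$fit_r2))))
  invisible(x)
}

#' Pyramidal / PV EPSC charge ratio
#'
#' Ratio of thalamocortical EPSC charge onto a pyramidal neuron versus a
#' simultaneously recorded PV+ interneuron, per stimulus intensity, averaged
#' across intensities, with the same windows applied to both cells and
#' linear-fit diagnostics (pyramidal charge regressed on PV charge).
#'
#' @param pairs List with one element per intensity, each a list
#'   `(intensity, pyr = trace, pv = trace)`; both traces carry a stimulus
#'   marker.
#' @param window_ms,baseline_ms Response / baseline windows as in
#'   [ei_charge_ratio()].
#' @return List with `mean_ratio`, `per_intensity`, `fit_slope`, `fit_r2`.
#' @export
pyr_pv_charge_ratio <- function(pairs, window_ms = 100, baseline_ms = 10) {
  if (!length(pairs)) stop_l4ei("l4ei_invalid_input", "need at least one intensity pair")
  rows <- lapply(pairs, function(p) {
    w <- sweep_windows(p$pyr, window_ms, baseline_ms)
    data.frame(intensity = p$intensity,
               pyr_charge_pC = charge(p$pyr, w$resp, w$base),
               pv_charge_pC = charge(p$pv, w$resp, w$base))
  })
  tab <- do.call(rbind, rows)
  if (any(tab$pv_charge_pC == 0)) {
    stop_l4ei("l4ei_division_undefined", "zero PV charge: ratio undefined")
  }
  tab$ratio <- tab$pyr_charge_pC / tab$pv_charge_pC
  if (nrow(tab) >= 2L) {
    fit <- lm(pyr_charge_pC ~ pv_charge_pC, data = tab)
    fit_slope <- coef(fit)[[2L]]
    fit_r2 <- cor(tab$pv_charge_pC, tab$pyr_charge_pC)^2
  } else {
    fit_slope <- NA_real_
    fit_r2 <- NA_real_
  }
  list(mean_ratio = mean(tab$ratio), per_intensity = tab,
       fit_slope = fit_slope, fit_r2 = fit_r2)
}

#' Quantal amplitude and frequency statistics around a stimulation window
#'
#' Partitions included events into spontaneous (before the laser window) and
#' evoked (inside it) epochs and reports mean amplitudes and the frequency
#' elevation, `100 * evoked rate / spontaneous rate` (% of baseline).
#'
#' @param events An `event_table` of detected events.
#' @param laser_window Numeric `c(start, stop)` in ms.
#' @return List with `spont_mean_amp_pA`, `evoked_mean_amp_pA`,
#'   `freq_elevation_pct`, and the epoch event counts.
#' @export
quantal_amplitude_stats <- function(events, laser_window) {
  stopifnot(inherits(events, "event_table"))
  if (length(laser_window) != 2L || laser_window[2L] <= laser_window[1L] ||
      laser_window[1L] <= 0) {
    stop_l4ei("l4ei_invalid_window",
              "`laser_window` must be (start, stop) with 0 < start < stop")
  }
  ev <- events[events$included, , drop = FALSE]
  spont <- ev[ev$onset_ms < laser_window[1L], , drop = FALSE]
  evoked <- ev[ev$onset_ms >= laser_window[1L] & ev$onset_ms < laser_window[2L], , drop = FALSE]
  if (!nrow(spont)) stop_l4ei("l4ei_baseline_undefined", "no included events before the window")
  if (!nrow(evoked)) stop_l4ei("l4ei_baseline_undefined", "no included events inside the window")
  rate_spont <- nrow(spont) / laser_window[1L]
  rate_evoked <- nrow(evoked) / diff(laser_window)
  list(spont_mean_amp_pA = mean(spont$amp_pA),
       evoked_mean_amp_pA = mean(evoked$amp_pA),
       freq_elevation_pct = 100 * rate_evoked / rate_spont,
       n_spont = nrow(spont), n_evoked = nrow(evoked))
}

#' LTD outcome: post/pre amplitude ratio
#'
#' Post-induction amplitude averaged over minutes 5-30 after the end of
#' induction, divided by the mean pre-induction amplitude. Invariant to
#' amplitude units.
#'
#' @param exp An `ltd_experiment` (per-minute amplitudes plus
#'   `induction_end`).
#' @return List with `post_pre_ratio`, `pre_mean_pA`, `post_mean_pA`.
#' @export
ltd_outcome <- function(exp) {
  stopifnot(inherits(exp, "ltd_experiment"))
  a <- exp$amplitudes
  pre <- a$amp_pA[a$minute <= exp$induction_end & a$phase == "pre"]
  lo <- exp$induction_end + 5
  hi <- exp$induction_end + 30
  if (!length(pre)) stop_l4ei("l4ei_window_infeasible", "no pre-induction minutes")
  if (max(a$minute) < hi) {
    stop_l4ei("l4ei_window_infeasible",
              "series must cover 30 min after the end of induction")
  }
  post <- a$amp_pA[a$minute >= lo & a$minute <= hi]
  list(post_pre_ratio = mean(post) / mean(pre),
       pre_mean_pA = mean(pre), post_mean_pA = mean(post))
}

#' FI-curve analysis: firing rates, rheobase, input resistance
#'
#' Firing rate is the spike count divided by the step duration for each
#' current step; rheobase is the smallest step current eliciting at least one
#' spike; input resistance is the steady-state voltage deflection (mean over
#' the last 20% of the step) divided by the injected current on the
#' designated subthreshold step.
#'
#' @param rec An `fi_recording` from [gen_fi_protocol()].
#' @param resistance_step_pA Current of the step used for input resistance;
#'   defaults to the most negative (hyperpolarizing) step, or the largest
#'   spike-free step if none is hyperpolarizing.
#' @return List with `fi_curve` (data frame `current_pA`, `rate_hz`),
#'   `rheobase_pA` (`NA` with a warning when no step spikes) and
#'   `input_resistance_MOhm`.
#' @export
fi_analysis <- function(rec, resistance_step_pA = NULL) {
  stopifnot(inherits(rec, "fi_recording"))
  if (length(rec$steps) < 2L) {
    stop_l4ei("l4ei_invalid_protocol", "need at least two current steps")
  }
  counts <- vapply(rec$steps, function(s) length(s$spike_times_ms), integer(1))
  fi <- data.frame(current_pA = rec$current_steps_pA,
                   rate_hz = counts / (rec$step_duration_ms / 1000))
  spiking <- fi$current_pA[counts > 0]
  if (length(spiking)) {
    rheobase <- min(spiking)
  } else {
    warning("rheobase undefined: no step elicited a spike", call. = FALSE)
    rheobase <- NA_real_
  }
  if (is.null(resistance_step_pA)) {
    neg <- rec$current_steps_pA[rec$current_steps_pA < 0]
    if (length(neg)) {
      resistance_step_pA <- min(neg)
    } else {
      sub <- fi$current_pA[counts == 0 & fi$current_pA != 0]
      resistance_step_pA <- if (length(sub)) max(sub) else NA_real_
    }
  }
  rin <- NA_real_
  if (is.finite(resistance_step_pA)) {
    k <- match(resistance_step_pA, rec$current_steps_pA)
    if (is.na(k)) stop_l4ei("l4ei_invalid_protocol", "resistance step not in the protocol")
    v <- rec$steps[[k]]$v_mV
    vss <- mean(v[seq.int(ceiling(0.8 * length(v)), length(v))])
    # mV / pA = GOhm; report MOhm
    rin <- (vss - rec$neuron$VL_mV) / resistance_step_pA * 1000
  }
  list(fi_curve = fi, rheobase_pA = rheobase, input_resistance_MOhm = rin,
       resistance_step_pA = resistance_step_pA)
}

#' Unitary IPSC estimation from minimal-stimulation trials
#'
#' The trial sweep is lightly low-pass smoothed (1 ms boxcar); a trial counts
#' as a success when its peak post-stimulus deflection on the smoothed sweep
#' exceeds `threshold_k` times the trial's baseline noise SD (measured on the
#' smoothed pre-stimulus segment, so threshold and peak see the same
#' bandwidth). Reports the success rate and the mean amplitude of successes —
#' the putative unitary IPSC amplitude.
#'
#' @param trials A `trial_set` from [gen_minimal_stim_trials()].
#' @param response_window_ms Post-stimulus search window, relative to the
#'   stimulus (default 2-20 ms).
#' @param threshold_k Success threshold in baseline-noise SDs (default 3).
#' @return List with `success_rate`, `mean_success_amp_pA`, the per-trial
#'   `success` classification and `peak_pA`, and `n_trials`. With the default
#'   3-SD threshold a small fraction of pure-noise trials can cross (the peak
#'   is a maximum over the response window); raise `threshold_k` for a more
#'   conservative classification.
#' @export
unitary_ipsc <- function(trials, response_window_ms = c(2, 20), threshold_k = 3) {
  stopifnot(inherits(trials, "trial_set"))
  if (length(trials$trials) < 10L) {
    stop_l4ei("l4ei_invalid_input", "need at least 10 trials")
  }
  stim <- trials$stim_time_ms
  stats_per <- vapply(trials$trials, function(tr) {
    sm <- moving_average(tr$current_pA, max(1L, round(1 / tr$sample_interval_ms)))
    bidx <- window_indices(tr, c(0, stim))
    b <- sm[bidx]
    ridx <- window_indices(tr, stim + response_window_ms)
    peak <- max(sm[ridx] - mean(b))
    c(peak = peak, noise_sd = sd(b))
  }, numeric(2))
  success <- stats_per["peak", ] > threshold_k * stats_per["noise_sd", ]
  if (!any(success)) {
    stop_l4ei("l4ei_estimate_undefined", "no successful trials: amplitude estimate undefined")
  }
  list(success_rate = mean(success),
       mean_success_amp_pA = mean(stats_per["peak", success]),
       success = unname(success),
       peak_pA = unname(stats_per["peak", ]),
       n_trials = length(success))
}

#' Two-sample group comparison
#'
#' The statistical-test conventions of the analysis: a two-sample t-test for
#' normally distributed data, a Wilcoxon rank-sum test otherwise, and a
#' two-sample Kolmogorov-Smirnov test for distribution comparisons. All tests
#' are two-sided.
#'
#' @param x,y Numeric samples (each `n >= 2`, finite).
#' @param method One of `"t_test"`, `"rank_sum"`, `"ks"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(x, y, method = c("t_test", "rank_sum", "ks")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L || !all(is.finite(c(x, y)))) {
    stop_l4ei("l4ei_invalid_input", "both samples must have n >= 2 finite values")
  }
  res <- switch(method,
    t_test = {
      if (var(x) == 0 && var(y) == 0) {
        stop_l4ei("l4ei_degenerate_sample", "zero pooled variance: t-test undefined")
      }
      t.test(x, y, var.equal = TRUE)
    },
    rank_sum = wilcox.test(x, y, exact = FALSE, correct = TRUE),
    ks = suppressWarnings(ks.test(x, y))
  )
  list(statistic = unname(res$statistic), p_value = res$p.value, method = method)
}
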