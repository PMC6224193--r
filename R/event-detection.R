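# Automated detection and kinetic characterization of quantal synaptic events.

trace_polarity <- function(trace, polarity) {
  if (polarity == "auto") {
    if (trace$holding_mV <= -35) "negative" else "positive"
  } else {
    polarity
  }
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  xs
}

#' Detect quantal events in a current trace
#'
#' Detection runs on the low-pass-smoothed, baseline-subtracted trace: samples
#' exceeding an adaptive threshold (a multiple of the robust noise SD, with a
#' relative floor so noiseless traces are handled) are grouped into candidate
#' events; peak amplitude and 20-80% rise time are then measured on the raw
#' trace. The running baseline is a long median filter, so slow drift does not
#' produce false events. A candidate whose onset falls within one rise time of
#' the preceding peak is merged into that event. The `included` flag applies
#' the standard inclusion criteria: amplitude greater than `min_amp` and rise
#' time less than `max_rise`.
#'
#' @param trace An `ephys_trace`.
#' @param min_amp Minimum included amplitude (pA); default 5 pA.
#' @param max_rise Maximum included 20-80% rise time (ms); default 3 ms.
#' @param polarity `"auto"` (from the holding potential), `"negative"`
#'   (inward events) or `"positive"`.
#' @param smooth_ms Boxcar smoothing width for detection (ms).
#' @param threshold_k Detection threshold in units of the robust noise SD.
#' @param baseline_ms Running-median baseline window (ms); must be long
#'   relative to single events so the baseline does not track them.
#' @param pre_baseline_ms Look-back before the detected onset at which the
#'   local baseline is read for amplitude measurement (ms).
#' @return An `event_table` data frame: `onset_ms`, `peak_ms`, `amp_pA`,
#'   `rise_ms`, `decay_tau_ms` (filled by [fit_event_kinetics()]), `included`,
#'   `epoch`, `baseline_pA`. Detection parameters and polarity are attached as
#'   attributes.
#' @export
detect_events <- function(trace, min_amp = 5, max_rise = 3,
                          polarity = c("auto", "negative", "positive"),
                          smooth_ms = 1, threshold_k = 3.5,
                          baseline_ms = 250, pre_baseline_ms = 2) {
  stopifnot(inherits(trace, "ephys_trace"))
  polarity <- trace_polarity(trace, match.arg(polarity))
  dt <- trace$sample_interval_ms
  cur <- trace$current_pA
  n <- length(cur)
  if (n * dt < 5) stop_l4ei("l4ei_invalid_input", "trace shorter than one event kernel")
  sgn <- if (polarity == "negative") -1 else 1
  x <- sgn * cur

  kb <- min(n, max(3L, round(baseline_ms / dt)))
  if (kb %% 2L == 0L) kb <- kb - 1L
  base <- runmed(x, kb, endrule = "median")
  xs <- moving_average(x, max(1L, round(smooth_ms / dt)))
  dev <- xs - base
  raw_dev <- x - base

  sigma <- mad(dev)
  thr <- threshold_k * sigma
  if (thr <= 0) thr <- 0.05 * max(dev, 0)
  empty <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      amp_pA = numeric(0), rise_ms = numeric(0),
                      decay_tau_ms = numeric(0), included = logical(0),
                      epoch = character(0), baseline_pA = numeric(0))
  attr_out <- function(df) {
    structure(df, class = c("event_table", "data.frame"),
              polarity = polarity, sample_interval_ms = dt,
              params = list(min_amp = min_amp, max_rise = max_rise,
                            smooth_ms = smooth_ms, threshold_k = threshold_k))
  }
  if (thr <= 0) return(attr_out(empty))

  above <- dev > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_on <- starts[r$values]
  run_off <- ends[r$values]
  if (!length(run_on)) return(attr_out(empty))

  events <- vector("list", length(run_on))
  prev_peak_t <- -Inf
  prev_rise <- 0
  kept <- 0L
  for (k in seq_along(run_on)) {
    i_on <- run_on[k]
    i_off <- run_off[k]
    seg <- i_on:i_off
    ipk <- seg[which.max(raw_dev[seg])]
    b0 <- base[max(1L, i_on - round(pre_baseline_ms / dt))]
    # peak read as a short average around the raw peak sample (noise robustness)
    pk_idx <- max(1L, ipk - 2L):min(n, ipk + 2L)
    amp <- mean(x[pk_idx]) - b0
    if (!is.finite(amp) || amp <= 0) next

    # 20-80% rise on the raw trace, interpolated
    a20 <- b0 + 0.2 * amp
    a80 <- b0 + 0.8 * amp
    i0 <- max(1L, i_on - round(5 / dt))
    pre <- i0:ipk
    below20 <- pre[x[pre] <= a20]
    below80 <- pre[x[pre] <= a80]
    cross_t <- function(i_lo, level) {
      if (i_lo >= ipk) return((i_lo - 1L) * dt)
      x0 <- x[i_lo]; x1 <- x[i_lo + 1L]
      f <- if (x1 > x0) (level - x0) / (x1 - x0) else 0
      (i_lo - 1L + max(0, min(1, f))) * dt
    }
    if (!length(below20) || !length(below80)) {
      t20 <- NA_real_; t80 <- NA_real_; rise <- NA_real_
    } else {
      t20 <- cross_t(max(below20), a20)
      t80 <- cross_t(max(below80), a80)
      rise <- t80 - t20
    }
    onset_t <- if (is.finite(t20)) t20 else (i_on - 1L) * dt
    peak_t <- (ipk - 1L) * dt

    # merge: a second onset within one rise time of the previous peak
    if (kept > 0L && is.finite(prev_rise) &&
        (onset_t - prev_peak_t) <= prev_rise) {
      next
    }
    kept <- kept + 1L
    events[[kept]] <- data.frame(onset_ms = onset_t, peak_ms = peak_t,
                                 amp_pA = amp, rise_ms = rise,
                                 decay_tau_ms = NA_real_,
                                 included = is.finite(amp) && amp > min_amp &&
                                   is.finite(rise) && rise < max_rise,
                                 epoch = NA_character_,
                                 baseline_pA = b0)
    prev_peak_t <- peak_t
    prev_rise <- rise
  }
  if (kept == 0L) return(attr_out(empty))
  attr_out(do.call(rbind, events[seq_len(kept)]))
}

#' Fit single-exponential decay constants to detected events
#'
#' For each event, fits `A exp(-t/tau)` by log-linear least squares over a
#' fixed window after the peak, on the raw baseline-subtracted trace. Events
#' whose post-peak segment is truncated by the trace end, or does not decay
#' (non-positive samples before a minimal fit length is reached), are flagged
#' and keep `decay_tau_ms = NA`.
#'
#' @param trace The `ephys_trace` the events were detected in.
#' @param events An `event_table` from [detect_events()].
#' @param fit_window_ms Post-peak fit window (ms), default 10 ms.
#' @param min_points Minimum samples required for a fit.
#' @return The `event_table` with `decay_tau_ms` filled and a logical
#'   `decay_fit_ok` column added.
#' @export
fit_event_kinetics <- function(trace, events, fit_window_ms = 10, min_points = 10L) {
  stopifnot(inherits(trace, "ephys_trace"), inherits(events, "event_table"))
  dt <- trace$sample_interval_ms
  sgn <- if (attr(events, "polarity") == "negative") -1 else 1
  x <- sgn * trace$current_pA
  n <- length(x)
  win <- round(fit_window_ms / dt)
  tau <- rep(NA_real_, nrow(events))
  ok <- rep(FALSE, nrow(events))
  for (k in seq_len(nrow(events))) {
    ipk <- round(events$peak_ms[k] / dt) + 1L
    if (ipk + min_points > n) next          # truncated at the trace end
    idx <- (ipk + 1L):min(n, ipk + win)
    y <- x[idx] - events$baseline_pA[k]
    pos <- which(y <= 0)
    if (length(pos)) y <- y[seq_len(pos[1L] - 1L)]
    if (length(y) < min_points) next
    tt <- seq_along(y) * dt
    sl <- coef(lm(log(y) ~ tt))[[2L]]
    if (!is.finite(sl) || sl >= 0) next
    tau[k] <- -1 / sl
    ok[k] <- TRUE
  }
  events$decay_tau_ms <- tau
  events$decay_fit_ok <- ok
  events
}
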