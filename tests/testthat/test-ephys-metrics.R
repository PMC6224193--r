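# Charge-based quantification, LTD outcome, FI analysis, unitary IPSCs,
# group comparisons.

test_that("charge matches analytic values and is linear and offset-invariant", {
  dt <- 0.1
  zero <- new_trace(rep(0, 3001), dt)
  expect_equal(charge(zero, c(50, 150), c(0, 40)), 0)
  # rectangular 100 pA x 10 ms pulse = 1 pC
  t <- seq(0, 300, by = dt)
  rect <- ifelse(t >= 100 & t < 110, 100, 0)
  expect_equal(charge(new_trace(rect, dt), c(99, 115), c(0, 50)), 1, tolerance = 1e-3)
  # exponential 100 pA * exp(-t/5): integral A*tau = 0.5 pC
  dec <- exp_decay_trace(100, 5, t0_ms = 100, duration_ms = 300, sign = 1)
  expect_equal(charge(dec, c(100, 250), c(0, 90)), 0.5, tolerance = 1e-3)
  # linearity and offset invariance (random amplitudes, fixed seed)
  set.seed(42)
  for (a in runif(5, 0.5, 20)) {
    scaled <- new_trace(a * dec$current_pA, dt)
    expect_equal(charge(scaled, c(99, 250), c(0, 90)),
                 a * charge(dec, c(99, 250), c(0, 90)), tolerance = 1e-9)
    offset <- new_trace(dec$current_pA + 37, dt)
    expect_equal(charge(offset, c(99, 250), c(0, 90)),
                 charge(dec, c(99, 250), c(0, 90)), tolerance = 1e-9)
  }
  expect_error(charge(zero, c(250, 400), c(0, 40)), class = "l4ei_invalid_window")
  expect_error(charge(zero, c(50, 150), c(100, 160)), class = "l4ei_invalid_window")
})

test_that("E-I charge ratio recovers construction values and applies the minima", {
  # equal charges in every pair: ratio 1 and perfect linear fit
  eq <- gen_paired_ei_sweeps(1:5, 0.5, 0.5, noise_sd_pA = 0)
  res_eq <- ei_charge_ratio(eq$sweeps, min_epsc = 0, min_ipsc = 0)
  expect_equal(res_eq$mean_ratio, 1, tolerance = 1e-9)
  expect_equal(res_eq$fit_r2, 1, tolerance = 1e-9)
  # constructed thalamocortical ratio
  tc <- gen_paired_ei_sweeps(1:5, 0.106, 1, noise_sd_pA = 0)
  res_tc <- ei_charge_ratio(tc$sweeps, min_epsc = 0, min_ipsc = 0)
  expect_equal(res_tc$mean_ratio, 0.106, tolerance = 1e-6)
  # amplitude minima: weak EPSC pairs are dropped from the ratio
  mix <- gen_paired_ei_sweeps(1:5, 0.05, 0.5, noise_sd_pA = 0)
  peaks <- vapply(mix$sweeps$pairs, function(p) max(-p$epsc$current_pA), numeric(1))
  min_e <- sort(peaks)[3]  # threshold excluding the two weakest pairs
  res_mix <- ei_charge_ratio(mix$sweeps, min_epsc = min_e, min_ipsc = 0)
  expect_equal(res_mix$n_surviving, 3L)
  expect_identical(res_mix$per_intensity$surviving, peaks >= min_e)
  # all below minima: named error
  expect_error(ei_charge_ratio(mix$sweeps, min_epsc = 1e6, min_ipsc = 600),
               class = "l4ei_all_excluded")
  # a single surviving pair leaves the fit undefined
  one <- gen_paired_ei_sweeps(2, 0.3, 1, noise_sd_pA = 0)
  res_one <- ei_charge_ratio(one$sweeps, min_epsc = 0, min_ipsc = 0)
  expect_true(is.na(res_one$fit_r2))
  expect_equal(res_one$mean_ratio, 0.3, tolerance = 1e-6)
})

test_that("pyramidal/PV charge ratio recovers constructed ratios", {
  for (r in c(0.260, 0.369)) {
    gen <- gen_paired_ei_sweeps(1:4, r, 1, noise_sd_pA = 0)
    pairs <- lapply(gen$sweeps$pairs, function(p)
      list(intensity = p$intensity, pyr = p$epsc, pv = p$ipsc))
    res <- pyr_pv_charge_ratio(pairs)
    expect_equal(res$mean_ratio, r, tolerance = 1e-6)
    expect_equal(res$fit_r2, 1, tolerance = 1e-9)
  }
  # identical traces: ratio exactly 1
  gen <- gen_paired_ei_sweeps(1:3, 0.5, 1, noise_sd_pA = 0)
  same <- lapply(gen$sweeps$pairs, function(p)
    list(intensity = p$intensity, pyr = p$epsc, pv = p$epsc))
  expect_equal(pyr_pv_charge_ratio(same)$mean_ratio, 1)
  # zero PV charge is undefined
  flat <- lapply(gen$sweeps$pairs, function(p)
    list(intensity = p$intensity, pyr = p$epsc,
         pv = new_trace(rep(0, length(p$ipsc$current_pA)), 0.1,
                        markers = p$ipsc$markers)))
  expect_error(pyr_pv_charge_ratio(flat), class = "l4ei_division_undefined")
})

test_that("quantal statistics recover the constructed frequency elevation and amplitudes", {
  kin <- event_kinetics(0.5, 3, 9.7, 0)
  win <- c(8000, 16000)
  out <- gen_optogenetic_quantal_trace(trace_spec(20000, noise_sd_pA = 0.5, seed = 11),
                                       kin, 1.5, 4.85, win)
  ev <- detect_events(out$trace)
  qs <- quantal_amplitude_stats(ev, win)
  # sampling error of the rate ratio from the observed counts
  se_rel <- sqrt(1 / qs$n_evoked + 1 / qs$n_spont)
  expect_lt(abs(qs$freq_elevation_pct - 485), 3 * se_rel * 485)
  expect_equal(qs$evoked_mean_amp_pA, 9.7, tolerance = 0.5)
  expect_equal(qs$spont_mean_amp_pA, 9.7, tolerance = 0.5)
  # equal rates inside and outside: elevation about 100%
  out1 <- gen_optogenetic_quantal_trace(trace_spec(20000, noise_sd_pA = 0.5, seed = 12),
                                        kin, 4, 1, win)
  qs1 <- quantal_amplitude_stats(detect_events(out1$trace), win)
  se1 <- sqrt(1 / qs1$n_evoked + 1 / qs1$n_spont)
  expect_lt(abs(qs1$freq_elevation_pct - 100), 3 * se1 * 100)
})

test_that("LTD outcome is exact on noiseless series and unit-scale invariant", {
  for (f in c(0.644, 0.893, 1)) {
    exp_ <- gen_ltd_series(10, 45, 300, f, noise_cv = 0, seed = 1)$experiment
    expect_equal(ltd_outcome(exp_)$post_pre_ratio, f, tolerance = 1e-12)
    scaled <- exp_
    scaled$amplitudes$amp_pA <- scaled$amplitudes$amp_pA * 1000  # to fA
    expect_equal(ltd_outcome(scaled)$post_pre_ratio,
                 ltd_outcome(exp_)$post_pre_ratio, tolerance = 1e-12)
  }
  # insufficient post coverage
  short <- gen_ltd_series(10, 45, 300, 0.7, seed = 1)$experiment
  short$amplitudes <- short$amplitudes[short$amplitudes$minute <= short$induction_end + 20, ]
  expect_error(ltd_outcome(short), class = "l4ei_window_infeasible")
})

test_that("FI analysis reports rheobase within one step and the Ohmic input resistance", {
  np <- neuron_params()
  fi <- gen_fi_protocol(np, c(-50, 100, 200, 201, 300), 1000)
  res <- fi_analysis(fi)
  expect_equal(res$fi_curve$rate_hz[1:3], c(0, 0, 0))
  expect_lte(abs(res$rheobase_pA - np$gL_nS * (np$Vtheta_mV - np$VL_mV)), 1)
  expect_equal(res$input_resistance_MOhm, 1000 / np$gL_nS, tolerance = 1e-4)
  # no spikes anywhere: rheobase undefined, curve still returned
  quiet <- gen_fi_protocol(np, c(-50, 0, 100), 500)
  expect_warning(res_q <- fi_analysis(quiet), "rheobase")
  expect_true(is.na(res_q$rheobase_pA))
  expect_equal(nrow(res_q$fi_curve), 3L)
})

test_that("unitary IPSC estimation recovers success rate and amplitude", {
  gen <- gen_minimal_stim_trials(400, 0.5, 215, noise_sd_pA = 5, seed = 7)
  res <- unitary_ipsc(gen$trials)
  # every seeded IPSC is far above threshold: no false negatives; pure-noise
  # trials can occasionally cross the 3-SD bound, so the estimated rate may
  # only exceed the construction labels
  expect_true(all(res$success[gen$truth$success]))
  fp_rate <- mean(res$success[!gen$truth$success])
  expect_lt(fp_rate, 0.15)
  expect_gte(res$success_rate, mean(gen$truth$success))
  expect_equal(res$mean_success_amp_pA, 215, tolerance = 0.05 * 215)
  # noiseless: zero successes is an undefined estimate
  none <- gen_minimal_stim_trials(50, 0, 215, noise_sd_pA = 0, seed = 8)
  expect_error(unitary_ipsc(none$trials), class = "l4ei_estimate_undefined")
  # deterministic threshold contract: with a known baseline SD, a clean
  # response below 3 SD is a failure, one above is a success
  dt <- 0.1
  kin <- event_kinetics(0.8, 8)
  make_trial <- function(amp) {
    cur <- numeric(601)
    # deterministic square-wave baseline (2 ms period) surviving the 1 ms
    # detection smoothing with a known SD
    cur[1:100] <- rep(c(rep(4, 10), rep(-4, 10)), 5)
    if (amp > 0) cur <- l4ei:::add_kernel_events(cur, dt, 13, amp, kin, +1)
    new_trace(cur, dt, -40, markers = data.frame(time_ms = 10, label = "stim"))
  }
  crafted <- structure(list(trials = c(lapply(rep(5, 6), make_trial),
                                       lapply(rep(50, 6), make_trial)),
                            stim_time_ms = 10),
                       class = "trial_set")
  res_c <- unitary_ipsc(crafted)
  expect_identical(res_c$success, rep(c(FALSE, TRUE), each = 6))
  expect_equal(res_c$success_rate, 0.5)
})

test_that("group comparisons follow the stated test conventions", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), "t_test")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  rs <- compare_groups(1:10, 1:10, "rank_sum")
  expect_gt(rs$p_value, 0.99)
  set.seed(1)
  sep <- compare_groups(rnorm(50), rnorm(50, 5), "t_test")
  expect_lt(sep$p_value, 1e-10)
  ks <- compare_groups(rnorm(30), rnorm(30), "ks")
  expect_true(ks$p_value >= 0 && ks$p_value <= 1)
  expect_error(compare_groups(rep(1, 5), rep(1, 5), "t_test"),
               class = "l4ei_degenerate_sample")
  expect_error(compare_groups(1, 1:5, "t_test"), class = "l4ei_invalid_input")
})
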