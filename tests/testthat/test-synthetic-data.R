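# Generators: validation, ground-truth statistics, reproducibility.

test_that("invalid generator specifications are rejected", {
  expect_error(trace_spec(0), class = "l4ei_invalid_spec")
  expect_error(trace_spec(100, sample_interval_ms = 0), class = "l4ei_invalid_spec")
  expect_error(trace_spec(100, noise_sd_pA = -1), class = "l4ei_invalid_spec")
  expect_error(event_kinetics(3, 2), class = "l4ei_invalid_spec")
  sp <- trace_spec(1000, noise_sd_pA = 0)
  kin <- event_kinetics()
  expect_error(gen_mepsc_trace(sp, kin, -1), class = "l4ei_invalid_spec")
  expect_error(gen_optogenetic_quantal_trace(sp, kin, 2, 0.5, c(100, 200)),
               class = "l4ei_invalid_spec")
  expect_error(gen_optogenetic_quantal_trace(sp, kin, 2, 2, c(300, 300)),
               class = "l4ei_invalid_window")
  expect_error(gen_optogenetic_quantal_trace(sp, kin, 2, 2, c(900, 1100)),
               class = "l4ei_invalid_window")
  expect_error(gen_paired_ei_sweeps(c(2, 1), 1, 1), class = "l4ei_invalid_spec")
  expect_error(gen_paired_ei_sweeps(1:3, -1, 1), class = "l4ei_invalid_spec")
  expect_error(gen_ltd_series(10, 30, 300, 0.7), class = "l4ei_window_infeasible")
  expect_error(gen_ltd_series(0, 45, 300, 0.7), class = "l4ei_invalid_spec")
  expect_error(gen_ltd_series(10, 45, 50, 0.7), class = "l4ei_invalid_spec")
  expect_error(gen_minimal_stim_trials(0, 0.5, 200), class = "l4ei_empty_trials")
  expect_error(gen_minimal_stim_trials(10, 1.5, 200), class = "l4ei_invalid_spec")
  expect_error(gen_fi_protocol(neuron_params(), c(100, 50)),
               class = "l4ei_invalid_protocol")
})

test_that("zero event rate and zero noise give a flat trace with empty truth", {
  out <- gen_mepsc_trace(trace_spec(2000, noise_sd_pA = 0, baseline_pA = -5),
                         event_kinetics(), 0)
  expect_length(out$truth$event_times, 0)
  expect_true(all(out$trace$current_pA == -5))
})

test_that("seeded event counts follow the Poisson law (rate 2 Hz, 20 s)", {
  counts <- vapply(1:200, function(s) {
    length(gen_mepsc_trace(trace_spec(20000, noise_sd_pA = 0, seed = s),
                           event_kinetics(), 2)$truth$event_times)
  }, numeric(1))
  se <- sqrt(40 / 200)
  expect_lt(abs(mean(counts) - 40), 3 * se)
})

test_that("lognormal amplitudes recover the requested mean", {
  kin <- event_kinetics(amp_mean_pA = 10.7, amp_cv = 0.2)
  amps <- unlist(lapply(1:200, function(s) {
    gen_mepsc_trace(trace_spec(5000, noise_sd_pA = 0, seed = s), kin, 4)$truth$event_amps
  }))
  se <- 10.7 * 0.2 / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 10.7), 3 * se)
  expect_true(all(amps > 0))
})

test_that("identical spec and seed give bit-identical traces; event superposition is linear", {
  sp <- trace_spec(5000, noise_sd_pA = 1.5, seed = 33)
  kin <- event_kinetics(amp_mean_pA = 15)
  a <- gen_mepsc_trace(sp, kin, 3)
  b <- gen_mepsc_trace(sp, kin, 3)
  expect_identical(a$trace$current_pA, b$trace$current_pA)
  expect_identical(a$truth, b$truth)
  # event superposition is linear: a noiseless trace equals baseline plus the
  # sum of the seeded kernels, exactly
  sp0 <- trace_spec(5000, noise_sd_pA = 0, baseline_pA = -3, seed = 33)
  c0 <- gen_mepsc_trace(sp0, kin, 3)
  rebuilt <- l4ei:::add_kernel_events(rep(-3, length(c0$trace$current_pA)),
                                      sp0$sample_interval_ms,
                                      c0$truth$event_times, c0$truth$event_amps,
                                      kin, sign = -1)
  expect_equal(rebuilt, c0$trace$current_pA, tolerance = 1e-12)
})

test_that("optogenetic quantal generator labels epochs and scales the in-window rate", {
  sp <- trace_spec(20000, noise_sd_pA = 0, seed = 5)
  kin <- event_kinetics()
  win <- c(5000, 15000)
  # identity factor: rate uniform across the window boundary
  out1 <- gen_optogenetic_quantal_trace(sp, kin, 4, 1, win)
  n_in <- sum(out1$truth$epoch == "evoked")
  n_out <- sum(out1$truth$epoch == "spontaneous")
  # both epochs cover 10 s; difference scaled by its Poisson SE
  expect_lt(abs(n_in - n_out), 3 * sqrt(n_in + n_out))
  # elevated factor: in/out rate ratio recovers the construction value
  counts <- vapply(1:30, function(s) {
    tr <- gen_optogenetic_quantal_trace(trace_spec(20000, noise_sd_pA = 0, seed = s),
                                        kin, 2, 4.85, win)
    c(sum(tr$truth$epoch == "evoked"), sum(tr$truth$epoch == "spontaneous"))
  }, numeric(2))
  ratio <- sum(counts[1, ]) / sum(counts[2, ])   # equal epoch durations
  se_rel <- sqrt(1 / sum(counts[1, ]) + 1 / sum(counts[2, ]))
  expect_lt(abs(ratio - 4.85), 3 * se_rel * 4.85)
})

test_that("paired E-I sweeps encode the constructed charge ratio", {
  sym <- gen_paired_ei_sweeps(1:4, 0.2, 0.2, noise_sd_pA = 0)
  expect_equal(sym$truth$true_ratio, 1)
  asym <- gen_paired_ei_sweeps(1:4, 0.106, 1, noise_sd_pA = 0)
  expect_equal(asym$truth$true_ratio, 0.106)
  one <- gen_paired_ei_sweeps(2, 0.5, 1, noise_sd_pA = 0)
  expect_length(one$sweeps$pairs, 1L)
  # noiseless charges measured on the sweeps equal the targets
  p <- asym$sweeps$pairs[[3]]
  expect_equal(charge(p$epsc, c(20, 120), c(10, 20)),
               asym$truth$true_e_charge_pC[3], tolerance = 1e-6)
  expect_equal(charge(p$ipsc, c(20, 120), c(10, 20)),
               asym$truth$true_i_charge_pC[3], tolerance = 1e-6)
})

test_that("LTD series recovers its construction factor, unbiased under noise", {
  exact <- gen_ltd_series(10, 45, 300, 0.644, noise_cv = 0, seed = 1)
  expect_equal(ltd_outcome(exact$experiment)$post_pre_ratio, 0.644, tolerance = 1e-12)
  unity <- gen_ltd_series(10, 45, 300, 1, noise_cv = 0, seed = 1)
  expect_equal(ltd_outcome(unity$experiment)$post_pre_ratio, 1, tolerance = 1e-12)
  recovered <- vapply(1:200, function(s) {
    ltd_outcome(gen_ltd_series(10, 45, 300, 0.7, noise_cv = 0.1,
                               seed = s)$experiment)$post_pre_ratio
  }, numeric(1))
  se <- sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - 0.7), 3 * se)
})

test_that("minimal-stimulation trials follow the binomial success law", {
  none <- gen_minimal_stim_trials(50, 0, 200, seed = 2)
  expect_false(any(none$truth$success))
  half <- gen_minimal_stim_trials(400, 0.5, 209, noise_sd_pA = 5, seed = 3)
  se <- sqrt(0.25 / 400)
  expect_lt(abs(mean(half$truth$success) - 0.5), 3 * se)
  expect_length(half$trials$trials, 400L)
})

test_that("FI protocol reproduces closed-form single-neuron behaviour", {
  np <- neuron_params()
  # all-zero-equivalent: subthreshold steps produce no spikes
  quiet <- gen_fi_protocol(np, c(-20, 10, 50), 500)
  expect_true(all(vapply(quiet$steps, function(s) length(s$spike_times_ms), numeric(1)) == 0))
  # rheobase boundary gL * (Vtheta - VL) = 200 pA: silent at 200, fires at 201
  fi <- gen_fi_protocol(np, c(200, 201), 1000)
  expect_length(fi$steps[[1]]$spike_times_ms, 0L)
  expect_gt(length(fi$steps[[2]]$spike_times_ms), 0L)
  # Ohmic deflection: -50 pA -> steady state VL + I/gL = -75 mV
  hyp <- gen_fi_protocol(np, c(-50, 0), 1000)
  v <- hyp$steps[[1]]$v_mV
  vss <- mean(v[seq.int(ceiling(0.8 * length(v)), length(v))])
  expect_equal(vss, -75, tolerance = 1e-6)
})
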