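# Scenario application, paired comparisons, sweep and grid machinery.
# Full-scale directional results are exercised in test-acceptance.R; here the
# mechanics are verified on small networks.

test_that("scenario multipliers scale exactly the prescribed pathways", {
  f <- make_factors(0.9, 0.6, 1.5)
  bl <- apply_scenario(f, "BL")
  expect_true(all(unlist(bl) == 1))
  tc <- apply_scenario(f, "TC")
  inp <- input_spec()
  spec <- network_spec()
  expect_equal(tc$thal_e * inp$js_nS, 0.45)
  expect_equal(tc$thal_i * inp$g_fw * inp$js_nS, 0.375)
  expect_equal(tc$ei, 1)
  expect_equal(tc$bkg, 1)
  tcic <- apply_scenario(f, "TC_IC")
  expect_equal(tcic$ei * spec$j_nS, 0.45)
  expect_equal(tcic$ee * spec$j_nS, 0.3)
  expect_equal(tcic$ie, 1)
  expect_equal(tcic$ii, 1)
  # multiplicative composition: TC plus the feedback increment equals TC_IC
  tc_plus <- tc
  tc_plus$ei <- tc_plus$ei * f$pi_fb
  expect_equal(tc_plus, tcic)
})

test_that("null factors give identical rasters across scenarios under shared seeds", {
  cr <- run_condition_comparison(neuron_params(), small_spec(N = 100, in_e = 10, in_i = 3),
                                 input_spec(), make_factors(1, 1, 1),
                                 duration_ms = 600, seed = 5,
                                 transient_discard_ms = 200, keep_sims = TRUE)
  expect_identical(cr$sims$BL$spikes, cr$sims$TC$spikes)
  expect_identical(cr$sims$BL$spikes, cr$sims$TC_IC$spikes)
  expect_equal(cr$rates$pct_e, rep(100, 3))
})

test_that("uniform thalamocortical depression lowers rates below baseline", {
  # rho_EI = 1, pi = 1: all thalamic drive depressed by 0.9, nothing else
  cr <- run_condition_comparison(neuron_params(), small_spec(N = 400),
                                 input_spec(), make_factors(0.9, 0.9, 1),
                                 duration_ms = 2000, seed = 11,
                                 transient_discard_ms = 400)
  r <- cr$rates
  expect_lt(r$rate_e[r$scenario == "TC"], r$rate_e[r$scenario == "BL"])
})

test_that("Monte-Carlo sweep draws reproducibly and filters by the targets", {
  f <- make_factors(0.9, 0.6, 1.5)
  tmpl <- small_spec(N = 100, in_e = 8, in_i = 2)
  # +/-100% of a target above the attainable rates keeps every active network
  tgt_loose <- rate_targets(60, 60, tolerance = 1)
  empty <- monte_carlo_sweep(sweep_ranges(), 0, tgt_loose, f,
                             spec_template = tmpl, duration_ms = 400,
                             transient_discard_ms = 100, master_seed = 2)
  expect_equal(empty$n_matched, 0L)
  expect_null(empty$networks)
  sw <- monte_carlo_sweep(sweep_ranges(), 4, tgt_loose, f,
                          spec_template = tmpl, duration_ms = 600,
                          transient_discard_ms = 200, master_seed = 2)
  # tolerance 1 (+/-100%) keeps every network with nonzero rates
  expect_equal(sw$n_matched, sum(sw$networks$bl_rate_e > 0 & sw$networks$bl_rate_i > 0))
  sw2 <- monte_carlo_sweep(sweep_ranges(), 4, tgt_loose, f,
                           spec_template = tmpl, duration_ms = 600,
                           transient_discard_ms = 200, master_seed = 2)
  expect_identical(sw$networks, sw2$networks)
  # parameters drawn inside the declared ranges
  rng <- sweep_ranges()
  expect_true(all(sw$networks$j_nS >= rng$j_nS[1] & sw$networks$j_nS <= rng$j_nS[2]))
  expect_true(all(sw$networks$g_rc >= rng$g_rc[1] & sw$networks$g_rc <= rng$g_rc[2]))
  # an unmatchable target yields an empty-match result, not an error
  sw0 <- monte_carlo_sweep(sweep_ranges(), 2, rate_targets(1e4, 1e4, 0.01), f,
                           spec_template = tmpl, duration_ms = 400,
                           transient_discard_ms = 100, master_seed = 3)
  expect_equal(sw0$n_matched, 0L)
  expect_null(sw0$summary)
  expect_equal(nrow(sw0$networks), 2L)
})

test_that("grid scan normalizes to its (1,1) cell and matches the paired pipeline", {
  np <- neuron_params()
  spec <- small_spec(N = 200)
  inp <- input_spec()
  g <- grid_scan(c(1, 1.5), c(1, 1.5), np, spec, inp,
                 duration_ms = 1200, seed = 13, transient_discard_ms = 300)
  expect_equal(g$pct_e[["1", "1"]], 100)
  expect_equal(g$pct_i[["1", "1"]], 100)
  cr <- run_condition_comparison(np, spec, inp, make_factors(0.9, 0.9 / 1.5, 1.5),
                                 duration_ms = 1200, seed = 13,
                                 transient_discard_ms = 300)
  expect_identical(g$rate_e[["1.5", "1.5"]], cr$rates$rate_e[cr$rates$scenario == "TC_IC"])
  expect_identical(g$rate_i[["1.5", "1.5"]], cr$rates$rate_i[cr$rates$scenario == "TC_IC"])
  expect_warning(grid_scan(c(0.8, 1), 1, np, spec, inp, duration_ms = 400,
                           seed = 1, transient_discard_ms = 100),
                 "outside the declared range")
})
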