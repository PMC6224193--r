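# The three in-silico experiments: BL/TC/TC+IC condition comparison,
# Monte-Carlo robustness sweep with firing-rate matching, and the
# (rho_EI, pi) grid scan.

#' Translate scenario factors into per-pathway weight multipliers
#'
#' BL leaves every peak conductance untouched; TC multiplies thalamic drive
#' onto excitatory cells by `delta_e` and onto inhibitory cells by `delta_i`;
#' TC_IC additionally multiplies recurrent excitation onto inhibition by
#' `pi_fb`. Background drive and recurrent inhibition are never scaled.
#'
#' @param factors A [make_factors()] object.
#' @param scenario One of `"BL"`, `"TC"`, `"TC_IC"`.
#' @return Named list of multipliers consumed by [simulate_network()].
#' @examples
#' apply_scenario(make_factors(0.9, 0.6, 1.5), "TC_IC")
#' @export
apply_scenario <- function(factors, scenario = c("BL", "TC", "TC_IC")) {
  stopifnot(inherits(factors, "scenario_factors"))
  scenario <- match.arg(scenario)
  m <- identity_multipliers()
  if (scenario %in% c("TC", "TC_IC")) {
    m$thal_e <- factors$delta_e
    m$thal_i <- factors$delta_i
  }
  if (scenario == "TC_IC") {
    m$ei <- factors$pi_fb
  }
  m
}

scenario_seeds <- function(seed) {
  list(conn = derive_seed(seed, "connectivity"),
       input = derive_seed(seed, "input"))
}

#' Paired-seed comparison of the BL, TC and TC+IC scenarios
#'
#' Builds one connectivity, then simulates the three scenarios with identical
#' connectivity and input realizations, so rate differences reflect only the
#' synaptic weight changes. Rates are reported in Hz and as a percentage of
#' the baseline (BL) scenario.
#'
#' @param neuron,spec,input Model parameters ([neuron_params()],
#'   [network_spec()], [input_spec()]).
#' @param factors A [make_factors()] object.
#' @param duration_ms Simulated time per scenario.
#' @param seed Master seed; connectivity and input sub-seeds are derived from
#'   it.
#' @param dt_ms Integration step.
#' @param transient_discard_ms Transient excluded from rate estimates.
#' @param conn Optional pre-built connectivity (must match `spec`).
#' @param keep_sims Keep the three `sim_result` objects in the output.
#' @return A `condition_result`: data frame `rates` with one row per scenario
#'   (`rate_e`, `rate_i`, `pct_e`, `pct_i`), plus metadata. Percent-of-BL is
#'   `NA` (with the raw rates still reported) when the BL rate is zero.
#' @export
run_condition_comparison <- function(neuron, spec, input, factors,
                                     duration_ms = 9000, seed = 1,
                                     dt_ms = 0.1, transient_discard_ms = 500,
                                     conn = NULL, keep_sims = FALSE) {
  stopifnot(inherits(factors, "scenario_factors"))
  seeds <- scenario_seeds(seed)
  if (is.null(conn)) conn <- build_connectivity(spec, seeds$conn)
  scen <- c("BL", "TC", "TC_IC")
  sims <- lapply(scen, function(sc) {
    simulate_network(neuron, spec, input, conn,
                     duration_ms = duration_ms, seed = seeds$input,
                     weight_overrides = apply_scenario(factors, sc),
                     dt_ms = dt_ms, transient_discard_ms = transient_discard_ms)
  })
  names(sims) <- scen
  rate_e <- vapply(sims, function(s) s$rate_e, numeric(1))
  rate_i <- vapply(sims, function(s) s$rate_i, numeric(1))
  pct <- function(r) if (r[["BL"]] > 0) 100 * r / r[["BL"]] else rep(NA_real_, 3)
  rates <- data.frame(scenario = scen, rate_e = rate_e, rate_i = rate_i,
                      pct_e = pct(rate_e), pct_i = pct(rate_i),
                      row.names = NULL)
  if (all(rate_e == 0) || rate_e[["BL"]] == 0) {
    warning("BL rate is zero: percent-of-BL undefined", call. = FALSE)
  }
  structure(list(rates = rates, factors = factors, seed = seed,
                 seeds = seeds, duration_ms = duration_ms,
                 transient_discard_ms = transient_discard_ms,
                 sims = if (keep_sims) sims else NULL),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat("<condition_result>\n")
  print(x$rates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Ranges of the Monte-Carlo parameter sweep
#'
#' Defaults are the standard sweep intervals: coupling scale `j` 0.1-0.4 nS,
#' relative inhibitory strength `g_rc` 7-10, thalamic and background rates
#' 5-15 Hz.
#'
#' @param j_nS,g_rc,R_lgn_hz,R_bkg_hz Numeric `c(min, max)` ranges.
#' @return An object of class `sweep_ranges`.
#' @export
sweep_ranges <- function(j_nS = c(0.1, 0.4), g_rc = c(7, 10),
                         R_lgn_hz = c(5, 15), R_bkg_hz = c(5, 15)) {
  rng <- list(j_nS = j_nS, g_rc = g_rc, R_lgn_hz = R_lgn_hz, R_bkg_hz = R_bkg_hz)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || any(r <= 0) || r[1L] > r[2L]) {
      stop_l4ei("l4ei_invalid_spec", sprintf("`%s` must be a positive (min, max) pair", nm))
    }
  }
  structure(rng, class = "sweep_ranges")
}

#' Firing-rate matching targets
#'
#' Target steady-state rates the baseline scenario must match for a network
#' to enter the Monte-Carlo analysis. The reference in-vivo rates are not
#' part of the package: they must be supplied by the user.
#'
#' @param target_rate_e_hz,target_rate_i_hz Target E and I rates (Hz, > 0).
#' @param tolerance Allowed relative deviation (fraction in `(0, 1]`;
#'   default 0.10).
#' @param match One of `"both"` (joint matching, the default), `"e"`, `"i"`.
#' @return An object of class `rate_targets`.
#' @export
rate_targets <- function(target_rate_e_hz, target_rate_i_hz, tolerance = 0.10,
                         match = c("both", "e", "i")) {
  check_positive_scalar(target_rate_e_hz, "target_rate_e_hz")
  check_positive_scalar(target_rate_i_hz, "target_rate_i_hz")
  if (tolerance <= 0 || tolerance > 1) {
    stop_l4ei("l4ei_invalid_spec", "`tolerance` must lie in (0, 1]")
  }
  structure(list(target_rate_e_hz = target_rate_e_hz,
                 target_rate_i_hz = target_rate_i_hz,
                 tolerance = tolerance, match = match.arg(match)),
            class = "rate_targets")
}

#' Monte-Carlo robustness sweep with firing-rate matching
#'
#' Draws `(j, g_rc, R_lgn, R_bkg)` independently and uniformly from the sweep
#' ranges for each candidate network, simulates the baseline scenario, keeps
#' networks whose BL rates fall within the tolerance of the targets, and runs
#' the TC and TC+IC scenarios on every kept network (paired connectivity and
#' input seeds). Percent-of-BL uses each network's own BL as denominator.
#'
#' @param ranges A [sweep_ranges()].
#' @param n_draws Number of candidate networks.
#' @param targets A [rate_targets()]; there are no default targets.
#' @param factors A [make_factors()] object applied to matched networks.
#' @param neuron A [neuron_params()].
#' @param spec_template A [network_spec()] providing everything except the
#'   drawn `j` and `g_rc` (use a reduced `N` with proportional in-degrees for
#'   tractable sweeps).
#' @param input_template An [input_spec()] providing everything except the
#'   drawn rates.
#' @param duration_ms,transient_discard_ms,dt_ms Simulation settings
#'   (defaults 3000 / 500 / 0.1 ms — a documented scaled-down design).
#' @param master_seed Master seed; every per-network parameter tuple and
#'   sub-seed derives from it.
#' @return An `mc_sweep` object: `networks` (one row per draw: parameters, BL
#'   rates, matched flag, and for matched networks the TC and TC+IC rates and
#'   percent-of-BL), `summary` (median, quartiles and mean of percent-of-BL
#'   per scenario and population over matched networks), `n_matched`, and the
#'   call metadata. Zero matched networks gives an empty-match result (the BL
#'   rate table serves as the diagnostic), not an error.
#' @export
monte_carlo_sweep <- function(ranges, n_draws, targets, factors,
                              neuron = neuron_params(),
                              spec_template = network_spec(),
                              input_template = input_spec(),
                              duration_ms = 3000, transient_discard_ms = 500,
                              dt_ms = 0.1, master_seed = 1) {
  stopifnot(inherits(ranges, "sweep_ranges"), inherits(targets, "rate_targets"),
            inherits(factors, "scenario_factors"))
  if (n_draws < 0) stop_l4ei("l4ei_invalid_spec", "`n_draws` must be >= 0")
  if (n_draws == 0) {
    return(structure(list(networks = NULL, summary = NULL, n_matched = 0L,
                          targets = targets, master_seed = master_seed),
                     class = "mc_sweep"))
  }
  draws <- with_seed(master_seed, {
    data.frame(j_nS = runif(n_draws, ranges$j_nS[1], ranges$j_nS[2]),
               g_rc = runif(n_draws, ranges$g_rc[1], ranges$g_rc[2]),
               R_lgn_hz = runif(n_draws, ranges$R_lgn_hz[1], ranges$R_lgn_hz[2]),
               R_bkg_hz = runif(n_draws, ranges$R_bkg_hz[1], ranges$R_bkg_hz[2]))
  })
  rows <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    spec_k <- network_spec(N = spec_template$N, NE = spec_template$NE,
                           NI = spec_template$NI,
                           in_degree_e = spec_template$in_degree_e,
                           in_degree_i = spec_template$in_degree_i,
                           j_nS = draws$j_nS[k], g_rc = draws$g_rc[k],
                           delay_ms = spec_template$delay_ms)
    input_k <- input_spec(js_nS = input_template$js_nS, g_fw = input_template$g_fw,
                          n_lgn = input_template$n_lgn, R_lgn_hz = draws$R_lgn_hz[k],
                          n_bkg = input_template$n_bkg, R_bkg_hz = draws$R_bkg_hz[k])
    conn_seed <- derive_seed(master_seed, sprintf("net%d-connectivity", k))
    input_seed <- derive_seed(master_seed, sprintf("net%d-input", k))
    conn <- build_connectivity(spec_k, conn_seed)
    bl <- simulate_network(neuron, spec_k, input_k, conn,
                           duration_ms = duration_ms, seed = input_seed,
                           weight_overrides = apply_scenario(factors, "BL"),
                           dt_ms = dt_ms,
                           transient_discard_ms = transient_discard_ms)
    ok_e <- abs(bl$rate_e - targets$target_rate_e_hz) <=
      targets$tolerance * targets$target_rate_e_hz
    ok_i <- abs(bl$rate_i - targets$target_rate_i_hz) <=
      targets$tolerance * targets$target_rate_i_hz
    matched <- switch(targets$match, both = ok_e && ok_i, e = ok_e, i = ok_i)
    row <- cbind(draws[k, , drop = FALSE],
                 data.frame(network = k, matched = matched,
                            bl_rate_e = bl$rate_e, bl_rate_i = bl$rate_i,
                            tc_rate_e = NA_real_, tc_rate_i = NA_real_,
                            tcic_rate_e = NA_real_, tcic_rate_i = NA_real_))
    if (matched) {
      for (sc in c("TC", "TC_IC")) {
        s <- simulate_network(neuron, spec_k, input_k, conn,
                              duration_ms = duration_ms, seed = input_seed,
                              weight_overrides = apply_scenario(factors, sc),
                              dt_ms = dt_ms,
                              transient_discard_ms = transient_discard_ms)
        if (sc == "TC") {
          row$tc_rate_e <- s$rate_e; row$tc_rate_i <- s$rate_i
        } else {
          row$tcic_rate_e <- s$rate_e; row$tcic_rate_i <- s$rate_i
        }
      }
    }
    rows[[k]] <- row
  }
  networks <- do.call(rbind, rows)
  networks$tc_pct_e <- 100 * networks$tc_rate_e / networks$bl_rate_e
  networks$tc_pct_i <- 100 * networks$tc_rate_i / networks$bl_rate_i
  networks$tcic_pct_e <- 100 * networks$tcic_rate_e / networks$bl_rate_e
  networks$tcic_pct_i <- 100 * networks$tcic_rate_i / networks$bl_rate_i
  m <- networks[networks$matched, , drop = FALSE]
  summarise_pct <- function(v) {
    c(median = median(v), q25 = unname(quantile(v, 0.25)),
      q75 = unname(quantile(v, 0.75)), mean = mean(v))
  }
  summary <- if (nrow(m)) {
    cols <- c(tc_pct_e = "tc_pct_e", tc_pct_i = "tc_pct_i",
              tcic_pct_e = "tcic_pct_e", tcic_pct_i = "tcic_pct_i")
    as.data.frame(t(vapply(cols, function(cn) summarise_pct(m[[cn]]), numeric(4))))
  } else {
    NULL
  }
  structure(list(networks = networks, summary = summary,
                 n_matched = sum(networks$matched),
                 targets = targets, factors = factors,
                 master_seed = master_seed,
                 duration_ms = duration_ms),
            class = "mc_sweep")
}

#' @export
print.mc_sweep <- function(x, ...) {
  n <- if (is.null(x$networks)) 0L else nrow(x$networks)
  cat(sprintf("<mc_sweep> %d draw(s), %d matched\n", n, x$n_matched))
  if (!is.null(x$summary)) print(round(x$summary, 2))
  invisible(x)
}

#' Grid scan over the thalamocortical and intracortical E-I ratio shifts
#'
#' For each pair `(rho_EI, pi)` the TC+IC scenario is simulated with the
#' thalamocortical depression onto excitatory cells fixed at `delta_e_fixed`,
#' `delta_i = delta_e_fixed / rho_EI`, and feedback potentiation `pi`. All
#' cells of the grid share one connectivity and one input realization with
#' the reference cell `rho_EI = pi = 1` (uniform thalamocortical depression
#' by `delta_e_fixed`, no feedback change), which serves as the grid's
#' baseline: rates are reported as a percentage of that run, so the (1, 1)
#' cell is exactly 100 and the cell at the measured corner equals the paired
#' three-scenario pipeline bit for bit under the same master seed.
#'
#' @param rho_values,pi_values Grid values, conventionally within `[1, 1.5]`;
#'   `rho < 1` triggers a warning but is still computed.
#' @param neuron,spec,input Model parameters.
#' @param delta_e_fixed Fixed thalamocortical depression onto excitatory
#'   cells (default 0.9, the measured value).
#' @param duration_ms,transient_discard_ms,dt_ms Simulation settings.
#' @param seed Master seed (same derivation as
#'   [run_condition_comparison()]).
#' @return A `grid_result`: `rho_values`, `pi_values`, matrices `pct_e`,
#'   `pct_i`, `rate_e`, `rate_i` (rows = rho, columns = pi), and the BL
#'   rates.
#' @export
grid_scan <- function(rho_values, pi_values, neuron = neuron_params(),
                      spec = network_spec(), input = input_spec(),
                      delta_e_fixed = 0.9, duration_ms = 9000, seed = 1,
                      dt_ms = 0.1, transient_discard_ms = 500) {
  if (!length(rho_values) || !length(pi_values)) {
    stop_l4ei("l4ei_invalid_spec", "grid value lists must be non-empty")
  }
  if (any(rho_values < 1)) {
    warning("rho_EI below 1 is outside the declared range; computed anyway",
            call. = FALSE)
  }
  seeds <- scenario_seeds(seed)
  conn <- build_connectivity(spec, seeds$conn)
  run_cell <- function(rho, pi_fb) {
    # rho < 1 implies delta_i > 1; the range warning was already issued
    f <- suppressWarnings(make_factors(delta_e_fixed, delta_e_fixed / rho, pi_fb))
    simulate_network(neuron, spec, input, conn,
                     duration_ms = duration_ms, seed = seeds$input,
                     weight_overrides = apply_scenario(f, "TC_IC"),
                     dt_ms = dt_ms,
                     transient_discard_ms = transient_discard_ms)
  }
  bl <- run_cell(1, 1)
  nr <- length(rho_values); np <- length(pi_values)
  rate_e <- matrix(NA_real_, nr, np, dimnames = list(rho = rho_values, pi = pi_values))
  rate_i <- rate_e
  for (a in seq_len(nr)) {
    for (b in seq_len(np)) {
      s <- if (rho_values[a] == 1 && pi_values[b] == 1) bl else
        run_cell(rho_values[a], pi_values[b])
      rate_e[a, b] <- s$rate_e
      rate_i[a, b] <- s$rate_i
    }
  }
  structure(list(rho_values = rho_values, pi_values = pi_values,
                 rate_e = rate_e, rate_i = rate_i,
                 pct_e = 100 * rate_e / bl$rate_e,
                 pct_i = 100 * rate_i / bl$rate_i,
                 bl_rate_e = bl$rate_e, bl_rate_i = bl$rate_i,
                 delta_e_fixed = delta_e_fixed, seed = seed, seeds = seeds),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> excitatory percent-of-BL (rows rho_EI, cols pi):\n")
  print(round(x$pct_e, 1))
  invisible(x)
}
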