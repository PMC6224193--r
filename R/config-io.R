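# Structured-text configuration and result files. Config keys carry explicit
# unit suffixes (C_pF, gL_nS, ...) so unit mistakes fail loudly; every result
# file embeds the seed and the decision parameters of the run so it can be
# regenerated exactly.

required_config_keys <- list(
  neuron = c("C_pF", "gL_nS", "VL_mV", "Vexc_mV", "Vinh_mV", "Vtheta_mV"),
  network = c("N", "NE", "NI", "in_degree_e", "in_degree_i", "j_nS", "g_rc"),
  input = c("js_nS", "g_fw", "n_lgn", "R_lgn_hz", "n_bkg", "R_bkg_hz")
)

optional_config_keys <- list(
  neuron = c("Vreset_mV", "t_ref_ms", "tau_syn_ms"),
  network = "delay_ms",
  input = character(0)
)

#' Load and validate a model configuration
#'
#' Reads a YAML configuration with blocks `neuron`, `network`, `input` (key
#' names mirror the parameter-table symbols, with unit suffixes) and optional
#' blocks `factors`, `sweep_ranges`, `rate_targets` and `simulation`. Every
#' required key must be present; unknown keys are rejected; defaults are
#' filled only for the documented decision parameters (reset potential,
#' refractory period, delay, dt, transient). Rate targets are never
#' defaulted: a configuration without them is valid for simulation and grid
#' scans but cannot drive a Monte-Carlo sweep.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "table1.yaml", package = "l4ei")` for the
#'   full-size model.
#' @return An object of class `l4ei_config`: validated `neuron`, `spec`,
#'   `input` objects plus any optional blocks (`factors`, `ranges`,
#'   `targets`, `simulation`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_l4ei("l4ei_io_error", paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  known_blocks <- c("neuron", "network", "input", "factors", "sweep_ranges",
                    "rate_targets", "simulation")
  bad <- setdiff(names(raw), known_blocks)
  if (length(bad)) {
    stop_l4ei("l4ei_validation_error",
              paste("unknown configuration block(s):", paste(bad, collapse = ", ")))
  }
  for (blk in c("neuron", "network", "input")) {
    if (is.null(raw[[blk]])) {
      stop_l4ei("l4ei_validation_error", paste("missing required block:", blk))
    }
    missing <- setdiff(required_config_keys[[blk]], names(raw[[blk]]))
    if (length(missing)) {
      stop_l4ei("l4ei_validation_error",
                sprintf("block `%s` is missing key(s): %s", blk,
                        paste(missing, collapse = ", ")))
    }
    unknown <- setdiff(names(raw[[blk]]),
                       c(required_config_keys[[blk]], optional_config_keys[[blk]]))
    if (length(unknown)) {
      stop_l4ei("l4ei_validation_error",
                sprintf("block `%s` has unknown key(s): %s", blk,
                        paste(unknown, collapse = ", ")))
    }
    nonnum <- names(raw[[blk]])[!vapply(raw[[blk]], is.numeric, logical(1))]
    if (length(nonnum)) {
      stop_l4ei("l4ei_validation_error",
                sprintf("block `%s`: non-numeric value for %s", blk,
                        paste(nonnum, collapse = ", ")))
    }
  }
  neuron <- do.call(neuron_params, raw$neuron)
  spec <- do.call(network_spec, raw$network)
  input <- do.call(input_spec, raw$input)
  factors <- if (!is.null(raw$factors)) do.call(make_factors, raw$factors) else NULL
  ranges <- if (!is.null(raw$sweep_ranges)) {
    do.call(sweep_ranges, lapply(raw$sweep_ranges, unlist))
  } else {
    NULL
  }
  targets <- if (!is.null(raw$rate_targets)) do.call(rate_targets, raw$rate_targets) else NULL
  structure(list(neuron = neuron, spec = spec, input = input,
                 factors = factors, ranges = ranges, targets = targets,
                 simulation = raw$simulation, path = path),
            class = "l4ei_config")
}

#' @export
print.l4ei_config <- function(x, ...) {
  cat(sprintf("<l4ei_config> %s: N = %d, j = %g nS, g_rc = %g; targets %s\n",
              basename(x$path), x$spec$N, x$spec$j_nS, x$spec$g_rc,
              if (is.null(x$targets)) "unset" else "set"))
  invisible(x)
}

#' Load Monte-Carlo sweep ranges from a YAML file
#'
#' Reads a file containing (only) a `sweep_ranges` block, such as the shipped
#' `system.file("extdata", "table2.yaml", package = "l4ei")`.
#'
#' @param path Path to a YAML file.
#' @return A [sweep_ranges()] object.
#' @export
load_sweep_ranges <- function(path) {
  if (!file.exists(path)) stop_l4ei("l4ei_io_error", paste("file not found:", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sweep_ranges)) {
    stop_l4ei("l4ei_validation_error", "missing `sweep_ranges` block")
  }
  do.call(sweep_ranges, lapply(raw$sweep_ranges, unlist))
}

# Order-stable fingerprint of a configuration object, embedded in result
# files so a published result can be tied to the exact run settings.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  codes <- utf8ToInt(s)
  h1 <- sum(codes * (seq_along(codes) %% 7919 + 1)) %% 2147483647
  h2 <- sum(codes * (seq_along(codes) %% 104729 + 1)) %% 2147483647
  sprintf("%08x%08x", h1, h2)
}

#' Write analysis results to plain-text files
#'
#' Writes a result object to disk in round-trip-safe plain-text form, with a
#' JSON summary embedding the seed, the configuration fingerprint and the
#' decision parameters of the run.
#'
#' * `sim_result`: `<stem>_spikes.csv` (neuron, time_ms) and `<stem>.json`
#'   (rates, seeds, decision parameters).
#' * `event_table`: `<stem>.csv`, one row per event with the `included` flag.
#' * `grid_result`: `<stem>_pct_e.csv` / `<stem>_pct_i.csv` matrices with rho
#'   and pi headers, plus `<stem>.json`.
#'
#' @param x Result object.
#' @param stem Output path stem (directories must exist).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(x, stem) UseMethod("write_results")

#' @export
write_results.sim_result <- function(x, stem) {
  spk <- paste0(stem, "_spikes.csv")
  js <- paste0(stem, ".json")
  write.csv(x$spikes, spk, row.names = FALSE)
  meta <- list(rate_e_hz = x$rate_e, rate_i_hz = x$rate_i,
               duration_ms = x$duration_ms,
               transient_discard_ms = x$transient_discard_ms,
               NE = x$NE, NI = x$NI, seed = x$seed,
               multipliers = x$multipliers,
               decision_params = x$decision_params,
               config_hash = config_hash(x[c("NE", "NI", "multipliers",
                                             "decision_params", "seed")]))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(spk, js))
}

#' @export
write_results.event_table <- function(x, stem) {
  f <- paste0(stem, ".csv")
  write.csv(as.data.frame(x), f, row.names = FALSE)
  invisible(f)
}

#' @export
write_results.grid_result <- function(x, stem) {
  fe <- paste0(stem, "_pct_e.csv")
  fi <- paste0(stem, "_pct_i.csv")
  js <- paste0(stem, ".json")
  write.csv(x$pct_e, fe)
  write.csv(x$pct_i, fi)
  jsonlite::write_json(
    list(rho_values = x$rho_values, pi_values = x$pi_values,
         bl_rate_e_hz = x$bl_rate_e, bl_rate_i_hz = x$bl_rate_i,
         delta_e_fixed = x$delta_e_fixed, seed = x$seed,
         config_hash = config_hash(x[c("rho_values", "pi_values",
                                       "delta_e_fixed", "seed")])),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(fe, fi, js))
}

#' Read back spike data written by [write_results()]
#'
#' @param stem The stem the result was written under.
#' @return List with `spikes` data frame and the JSON metadata.
#' @export
read_sim_results <- function(stem) {
  list(spikes = read.csv(paste0(stem, "_spikes.csv")),
       meta = jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE))
}
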