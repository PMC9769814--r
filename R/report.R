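#' Run configuration
#'
#' A single object holding every input of the analysis: metabolic rates,
#' stoichiometric constants, simulation settings, sweep grids, and the
#' top-level seed. Defaults reproduce the reported parameter set verbatim;
#' any override travels with every result's metadata sidecar.
#'
#' @param rates Rate tibble. Default [tricho_rates()].
#' @param stoich A [stoichiometry()] object.
#' @param config A [sim_config()] object.
#' @param seed Top-level integer seed; per-scenario substreams are derived
#'   from it.
#' @param n_draws Draws for the theta scenario. Default 500.
#' @param f_res_max Upper respiration limit for the theta scenario.
#'   Default 0.02.
#' @param grids Named list overriding any of the default sweep grids:
#'   `f_res`, `theta`, `r_p` (the fine 0.001-step grid), `i_p`, `i_t`,
#'   `rp_values`, `tau_colony`, `tau_trichome`, `rp_shared`.
#' @return A list of class `"tricho_config"`.
#' @export
#' @examples
#' cfg <- tricho_config(seed = 7)
#' cfg$grids$theta[1:3]
tricho_config <- function(rates = tricho_rates(), stoich = stoichiometry(),
                          config = sim_config(), seed = 1, n_draws = 500,
                          f_res_max = 0.02, grids = list()) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  defaults <- list(
    f_res = make_grid(0, 0.02, 0.0005),
    theta = make_grid(0.01, 1, 0.01),
    r_p = make_grid(0.001, 1, 0.001),
    i_p = make_grid(-2, 2, 0.01),
    i_t = make_grid(-0.002, 0.002, 0.0001),
    rp_values = c(0, 0.3, 0.6, 0.9),
    tau_colony = make_grid(1, 5, 0.1),
    tau_trichome = make_grid(1, 5, 0.1),
    rp_shared = make_grid(0, 1, 0.01)
  )
  unknown <- setdiff(names(grids), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown grid override(s):", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      rates = rates, stoich = stoich, config = config,
      seed = as.integer(seed), n_draws = n_draws, f_res_max = f_res_max,
      grids = utils::modifyList(defaults, grids)
    ),
    class = "tricho_config"
  )
}

#' Read a run configuration from YAML
#'
#' Loads a human-editable YAML file and merges it over the built-in
#' defaults. Recognised top-level keys: `seed`, `n_draws`, `f_res_max`,
#' `rates` (list of `morphotype:`, `c_fix:`, `n_fix:` records),
#' `stoichiometry` (`y_cn`, `r_nc`), `simulation` (`c0`, `duration_hours`,
#' `dt_hours`), and `grids` (each either `{start, stop, step}` or an
#' explicit `values` list).
#'
#' @param path Path to a YAML file.
#' @return A `tricho_config` object.
#' @export
read_tricho_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rates <- if (is.null(raw$rates)) {
    tricho_rates()
  } else {
    metabolic_rates(
      morphotype = vapply(raw$rates, `[[`, character(1), "morphotype"),
      c_fix = vapply(raw$rates, `[[`, numeric(1), "c_fix"),
      n_fix = vapply(raw$rates, `[[`, numeric(1), "n_fix")
    )
  }
  st <- raw$stoichiometry
  stoich <- stoichiometry(
    y_cn = st$y_cn %||% 1,
    r_nc = st$r_nc %||% 0.159
  )
  sm <- raw$simulation
  config <- sim_config(
    c0 = sm$c0 %||% 100,
    duration_hours = sm$duration_hours %||% 720,
    dt_hours = sm$dt_hours %||% 1
  )
  grids <- lapply(raw$grids %||% list(), function(g) {
    if (!is.null(g$values)) {
      as.numeric(unlist(g$values))
    } else {
      make_grid(g$start, g$stop, g$step)
    }
  })
  tricho_config(
    rates = rates, stoich = stoich, config = config,
    seed = raw$seed %||% 1, n_draws = raw$n_draws %||% 500,
    f_res_max = raw$f_res_max %||% 0.02, grids = grids
  )
}

#' Run one scenario (or all) from a configuration
#'
#' Dispatches to the scenario runners with the configuration's rates,
#' grids and seed. With an `outdir`, each result is also written as a CSV
#' plus JSON metadata sidecar via [write_scenario_result()], and a
#' machine-parsable `key=value` ledger line is logged to `stderr`.
#'
#' @param scenario One of `"fixed_equal"`, `"theta"`, `"rp"`, `"ip"`,
#'   `"it"`, `"tau"`, `"thresholds"`, `"all"` (hyphens accepted).
#' @param config A [tricho_config()] object.
#' @param outdir Optional output directory, created if needed.
#' @param overwrite Overwrite existing output files?
#' @return The scenario result (a named list of results for `"all"`),
#'   invisibly when written to disk.
#' @export
#' @examples
#' thr <- run_scenario("thresholds")
#' thr$value
run_scenario <- function(scenario, config = tricho_config(), outdir = NULL,
                         overwrite = FALSE) {
  if (!inherits(config, "tricho_config")) {
    abort("`config` must be created by tricho_config() or read_tricho_config()")
  }
  scenario <- gsub("-", "_", scenario)
  ids <- c("fixed_equal", "theta", "rp", "ip", "it", "tau", "thresholds")
  if (identical(scenario, "all")) {
    out <- lapply(ids, run_scenario, config = config, outdir = outdir,
                  overwrite = overwrite)
    names(out) <- ids
    return(invisible(out))
  }
  if (!scenario %in% ids) {
    abort(paste0(
      "unknown scenario '", scenario, "'; expected one of: ",
      paste(c(ids, "all"), collapse = ", ")
    ))
  }
  t0 <- proc.time()[["elapsed"]]
  g <- config$grids
  result <- switch(scenario,
    fixed_equal = run_fixed_equal(config$rates, config$stoich, config$config,
                                  f_res_grid = g$f_res),
    theta = run_theta(config$rates, config$stoich, config$config,
                      n_draws = config$n_draws, f_res_max = config$f_res_max,
                      theta_grid = g$theta, seed = config$seed),
    rp = run_rp(config$rates, config$stoich, config$config, rp_grid = g$r_p),
    ip = run_ip(config$rates, config$stoich, config$config, ip_grid = g$i_p,
                rp_values = g$rp_values),
    it = run_it(config$rates, config$stoich, config$config, it_grid = g$i_t,
                rp_values = g$rp_values),
    tau = run_tau(config$rates, config$stoich, config$config,
                  tau_grid_colony = g$tau_colony,
                  tau_grid_trichome = g$tau_trichome, rp_grid = g$rp_shared),
    thresholds = threshold_ledger(config$rates, config$stoich,
                                  f_res_max = config$f_res_max)
  )
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(outdir, paste0(scenario, ".csv"))
    write_scenario_result(result, path, overwrite = overwrite)
    message(sprintf(
      "scenario=%s rows=%d seed=%s elapsed_s=%.2f out=%s",
      scenario, nrow(result), config$seed, elapsed, path
    ))
    return(invisible(result))
  }
  result
}

#' Write a result table with its metadata sidecar
#'
#' Writes the table as RFC-4180 CSV ('.' decimal, no thousands separators)
#' with shortest round-trippable number rendering, and — for scenario
#' results — a JSON sidecar (`<path>.json`) recording seed, grids, rates,
#' stoichiometry, simulation settings and package version, enough to
#' regenerate the CSV byte-identically.
#'
#' @param result A `scenario_result` or plain data frame (e.g. the
#'   threshold ledger).
#' @param path Output CSV path.
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_scenario_result <- function(result, path, overwrite = FALSE) {
  stopifnot(is.data.frame(result))
  if (file.exists(path) && !overwrite) {
    abort(paste0("output exists: ", path, " (use overwrite = TRUE)"))
  }
  readr::write_csv(tibble::as_tibble(as.data.frame(result)), path)
  meta <- attr(result, "meta")
  if (!is.null(meta)) {
    jsonlite::write_json(
      meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = I(17), pretty = TRUE
    )
  }
  invisible(path)
}
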