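#' Scenario sweeps
#'
#' Each runner reproduces one published experiment as a tidy sweep table:
#' it expands a parameter grid, integrates the storage pool for 30 days of
#' hourly steps per grid point and morphotype, and reports end-of-run
#' storage changes (and, where the experiment is competitive, the colony
#' success proportion). Results carry their full parameter provenance
#' (seed, grids, rates, stoichiometry, configuration) as attributes, so any
#' table can be regenerated exactly.
#'
#' @name scenarios
NULL

new_scenario_result <- function(data, scenario, seed = NULL, grids = list(),
                                rates, stoich, config, extra = list()) {
  meta <- c(
    list(
      scenario = scenario, seed = seed, grids = grids,
      rates = rates,
      stoich = list(y_cn = stoich$y_cn, r_nc = stoich$r_nc),
      config = list(
        c0 = config$c0, duration_hours = config$duration_hours,
        dt_hours = config$dt_hours
      ),
      version = as.character(utils::packageVersion("trichoflux"))
    ),
    extra
  )
  structure(
    data,
    meta = meta,
    class = c("scenario_result", class(data))
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("Scenario sweep:", meta$scenario, "\n")
  NextMethod()
}

#' Tidiers for trichoflux results
#'
#' `tidy()` returns the underlying sweep table (or trajectory) as a plain
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x A `scenario_result` or `storage_trajectory`.
#' @param ... Unused.
#' @name tidy-trichoflux
NULL

#' @rdname tidy-trichoflux
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  out <- x
  attr(out, "meta") <- NULL
  class(out) <- setdiff(class(out), "scenario_result")
  tibble::as_tibble(out)
}

#' One-row summaries for trichoflux results
#'
#' @param x A `scenario_result` or `storage_trajectory`.
#' @param ... Unused.
#' @name glance-trichoflux
NULL

#' @rdname glance-trichoflux
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble::tibble(
    scenario = meta$scenario,
    n_rows = nrow(x),
    seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed),
    max_success = if ("success_proportion" %in% names(x)) {
      max(x$success_proportion)
    } else {
      NA_real_
    },
    version = meta$version
  )
}

#' Metadata of a scenario result
#'
#' @param x A `scenario_result`.
#' @return The provenance list (scenario id, seed, grids, rates,
#'   stoichiometry, simulation configuration, package version).
#' @export
scenario_meta <- function(x) {
  stopifnot(inherits(x, "scenario_result"))
  attr(x, "meta")
}

#' Proportion of paired runs won by colonies
#'
#' Colony success is the fraction of paired simulations in which colony
#' end-of-run storage strictly exceeds the trichome value; exact ties count
#' as failures.
#'
#' @param data Data frame of paired end-of-run storages.
#' @param colony,trichome Columns holding colony and trichome storage
#'   (tidy-eval). Defaults `c_sto_colony`, `c_sto_trichome`.
#' @return A single proportion in \[0, 1\].
#' @export
#' @examples
#' colony_success_proportion(
#'   data.frame(c_sto_colony = c(2, 1, 3), c_sto_trichome = c(1, 1, 4))
#' )
colony_success_proportion <- function(data, colony = c_sto_colony,
                                      trichome = c_sto_trichome) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) {
    abort("no paired records: success proportion is undefined")
  }
  col <- dplyr::pull(data, {{ colony }})
  tri <- dplyr::pull(data, {{ trichome }})
  mean(col > tri)
}

# Expand a grid against the rate table and integrate every cell.
sweep_deltas <- function(rates, stoich, config, params, f_res, i_p = 0,
                         i_t = 0) {
  net <- net_flux(params$c_fix, params$n_fix, f_res = f_res, i_p = i_p,
                  stoich = stoich)
  params$c_sto_final <- euler_final(net, i_t = i_t, config = config)
  params$delta_c_sto <- params$c_sto_final - config$c0
  params
}

#' Fixed and equal respiration rates
#'
#' Both morphotypes share each fixed respiration rate on the grid. At the
#' reported rates trichomes finish ahead everywhere; storage turns to net
#' loss above 0.009 (colonies) and 0.0135 (trichomes) on the default
#' 0.0005-step grid.
#'
#' @param rates Rate tibble with `"colony"` and `"trichome"` rows.
#' @param stoich A [stoichiometry()] object.
#' @param config A [sim_config()] object.
#' @param f_res_grid Respiration grid, mol C h\eqn{^{-1}} mol C\eqn{^{-1}}.
#'   Default 0 to 0.02 in steps of 0.0005.
#' @return A `scenario_result` tibble with columns `scenario`, `f_res`,
#'   `morphotype`, `c_sto_final`, `delta_c_sto`.
#' @export
#' @examples
#' res <- run_fixed_equal()
#' dplyr::filter(res, f_res == 0)
run_fixed_equal <- function(rates = tricho_rates(), stoich = stoichiometry(),
                            config = sim_config(),
                            f_res_grid = make_grid(0, 0.02, 0.0005)) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  params <- tidyr::expand_grid(
    f_res = f_res_grid,
    rates
  )
  out <- sweep_deltas(rates, stoich, config, params, f_res = params$f_res)
  out <- dplyr::mutate(out, scenario = "fixed_equal", .before = 1)
  out <- dplyr::select(out, "scenario", "f_res", "morphotype",
                       "c_sto_final", "delta_c_sto")
  new_scenario_result(
    out, "fixed_equal",
    grids = list(f_res = f_res_grid),
    rates = rates, stoich = stoich, config = config
  )
}

#' Fixed but unequal respiration rates (theta sweep)
#'
#' Trichome respiration rates are drawn uniformly on `[0, f_res_max]`;
#' colonies respire a fraction `theta` of each draw. Per `theta`, the
#' colony success proportion over the draws is reported, alongside the
#' analytic uniform-tail probability
#' `P(draw > gap / (1 - theta))` that a draw is large enough for the
#' colony's respiration saving to overcome its fixation deficit. The same
#' seeded draws are reused across the whole `theta` grid.
#'
#' @inheritParams run_fixed_equal
#' @param n_draws Number of trichome respiration draws. Default 500.
#' @param f_res_max Upper limit of the draw interval. Default 0.02; raising
#'   it raises the feasibility ceiling (see [theta_feasibility_limit()]).
#' @param theta_grid Ratio grid. Default 0.01 to 1 in steps of 0.01.
#' @param seed Integer seed for the draws.
#' @return A `scenario_result` tibble with columns `scenario`, `theta`,
#'   `n_draws`, `success_proportion`, `analytic_tail_prob`. The draws are
#'   recorded in the metadata.
#' @export
run_theta <- function(rates = tricho_rates(), stoich = stoichiometry(),
                      config = sim_config(), n_draws = 500,
                      f_res_max = 0.02,
                      theta_grid = make_grid(0.01, 1, 0.01), seed = 1) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  if (!is.numeric(n_draws) || n_draws < 1) {
    abort("`n_draws` must be a positive count")
  }
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  draws <- uniform_draws(n_draws, 0, f_res_max,
                         seed = substream_seed(seed, "theta"))
  gap <- net_flux_gap(rates, stoich)

  grid <- tidyr::expand_grid(theta = theta_grid, draw = draws)
  final_col <- euler_final(
    net_flux(col$c_fix, col$n_fix, f_res = grid$theta * grid$draw,
             stoich = stoich),
    config = config
  )
  final_tri <- euler_final(
    net_flux(tri$c_fix, tri$n_fix, f_res = grid$draw, stoich = stoich),
    config = config
  )
  grid$win <- final_col > final_tri
  out <- dplyr::summarise(
    dplyr::group_by(grid, .data$theta),
    success_proportion = mean(.data$win),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    scenario = "theta", .before = 1
  )
  out <- dplyr::mutate(
    out,
    n_draws = as.integer(n_draws), .after = "theta"
  )
  out <- dplyr::mutate(
    out,
    analytic_tail_prob = pmax(
      0, pmin(1, 1 - (gap / (1 - .data$theta)) / f_res_max)
    )
  )
  new_scenario_result(
    out, "theta", seed = seed,
    grids = list(theta = theta_grid, f_res_max = f_res_max,
                 n_draws = n_draws),
    rates = rates, stoich = stoich, config = config,
    extra = list(draws = draws)
  )
}

#' Respiration proportional to carbon fixation (r_p sweep)
#'
#' Each morphotype respires a fraction `r_p` of its own carbon fixation
#' rate. Because the colony's lower fixation rate also buys it lower
#' respiratory losses, colonies overtake trichomes above the crossover
#' (88.87% of fixation at the reported rates) and remain viable slightly
#' longer (up to 93.64% vs 92.05%).
#'
#' @inheritParams run_fixed_equal
#' @param rp_grid Respiration coefficient grid. Default 0.001 to 1 in steps
#'   of 0.001.
#' @return A `scenario_result` tibble with columns `scenario`, `r_p`,
#'   `morphotype`, `c_sto_final`, `delta_c_sto`.
#' @export
run_rp <- function(rates = tricho_rates(), stoich = stoichiometry(),
                   config = sim_config(),
                   rp_grid = make_grid(0.001, 1, 0.001)) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  params <- tidyr::expand_grid(r_p = rp_grid, rates)
  out <- sweep_deltas(rates, stoich, config, params,
                      f_res = params$r_p * params$c_fix)
  out <- dplyr::mutate(out, scenario = "rp", .before = 1)
  out <- dplyr::select(out, "scenario", "r_p", "morphotype",
                       "c_sto_final", "delta_c_sto")
  new_scenario_result(
    out, "rp",
    grids = list(r_p = rp_grid),
    rates = rates, stoich = stoich, config = config
  )
}

#' External influence on metabolic rates (i_p sweep)
#'
#' Scales the whole metabolic term by `(1 + i_p)` while respiration is a
#' fraction `r_p` of carbon fixation. With no metabolic costs colonies can
#' never catch up; at high `r_p` the crossover approaches `i_p = 0` and
#' negative external influence (stress, micronutrient limitation) favours
#' colony formation.
#'
#' @inheritParams run_fixed_equal
#' @param ip_grid Interaction-strength grid. Default -2 to 2 in steps of
#'   0.01.
#' @param rp_values Respiration coefficients, one panel each. Default
#'   `c(0, 0.3, 0.6, 0.9)`.
#' @return A `scenario_result` tibble with columns `scenario`, `r_p`,
#'   `i_p`, `morphotype`, `c_sto_final`, `delta_c_sto`.
#' @export
run_ip <- function(rates = tricho_rates(), stoich = stoichiometry(),
                   config = sim_config(),
                   ip_grid = make_grid(-2, 2, 0.01),
                   rp_values = c(0, 0.3, 0.6, 0.9)) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  params <- tidyr::expand_grid(r_p = rp_values, i_p = ip_grid, rates)
  out <- sweep_deltas(rates, stoich, config, params,
                      f_res = params$r_p * params$c_fix, i_p = params$i_p)
  out <- dplyr::mutate(out, scenario = "ip", .before = 1)
  out <- dplyr::select(out, "scenario", "r_p", "i_p", "morphotype",
                       "c_sto_final", "delta_c_sto")
  new_scenario_result(
    out, "ip",
    grids = list(i_p = ip_grid, r_p = rp_values),
    rates = rates, stoich = stoich, config = config
  )
}

#' External influence on total biomass (i_t sweep)
#'
#' Adds a flux `i_t * C_sto` that grows or erodes the storage pool itself
#' (mortality, subsidy) without touching metabolic rates. Because both
#' morphotypes share the initial pool and `i_t`, the winner is decided by
#' the sign of the net-flux difference and is invariant to `i_t`:
#' trichomes win for `r_p` up to 0.6, colonies for `r_p = 0.9`.
#'
#' @inheritParams run_fixed_equal
#' @param it_grid Biomass interaction grid, h\eqn{^{-1}}. Default -0.002 to
#'   0.002 in steps of 0.0001.
#' @param rp_values Respiration coefficients. Default `c(0, 0.3, 0.6, 0.9)`.
#' @return A `scenario_result` tibble, one row per `(r_p, i_t)` pair, with
#'   end-of-run storages `c_sto_colony` and `c_sto_trichome`, their signed
#'   `difference` (colony minus trichome), and `log10_difference`, a signed
#'   log magnitude `sign(d) * log10(|d|)` with exact zeros mapped to `NA`.
#' @export
run_it <- function(rates = tricho_rates(), stoich = stoichiometry(),
                   config = sim_config(),
                   it_grid = make_grid(-0.002, 0.002, 0.0001),
                   rp_values = c(0, 0.3, 0.6, 0.9)) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  out <- tidyr::expand_grid(r_p = rp_values, i_t = it_grid)
  out$c_sto_colony <- euler_final(
    net_flux(col$c_fix, col$n_fix, f_res = out$r_p * col$c_fix,
             stoich = stoich),
    i_t = out$i_t, config = config
  )
  out$c_sto_trichome <- euler_final(
    net_flux(tri$c_fix, tri$n_fix, f_res = out$r_p * tri$c_fix,
             stoich = stoich),
    i_t = out$i_t, config = config
  )
  out <- dplyr::mutate(
    out,
    difference = .data$c_sto_colony - .data$c_sto_trichome,
    log10_difference = dplyr::if_else(
      .data$difference == 0,
      NA_real_,
      sign(.data$difference) * log10(abs(.data$difference))
    )
  )
  out <- dplyr::mutate(out, scenario = "it", .before = 1)
  new_scenario_result(
    out, "it",
    grids = list(i_t = it_grid, r_p = rp_values),
    rates = rates, stoich = stoich, config = config
  )
}

#' Variable C:N fixation ratios (tau sweep)
#'
#' Holds each morphotype's carbon fixation at its reported value, rederives
#' nitrogen fixation as `c_fix / tau` for every pair of target ratios, and
#' scores colony success over a shared respiration-coefficient grid.
#' Success decays as `tau_trichome / tau_colony` grows and is exactly zero
#' once the ratio reaches `c_fix_trichome / c_fix_colony` (1.5 at the
#' reported rates); the maximum over the default grids is ~41.6%.
#'
#' @inheritParams run_fixed_equal
#' @param tau_grid_colony,tau_grid_trichome Ratio grids. Default 1 to 5 in
#'   steps of 0.1; values below 1 are rejected unless
#'   `allow_tau_below_one = TRUE`.
#' @param rp_grid Shared respiration-coefficient grid. Default 0 to 1 in
#'   steps of 0.01.
#' @param allow_tau_below_one Permit ratios below 1 (nitrogen fixation
#'   exceeding carbon fixation)?
#' @return A `scenario_result` tibble with columns `scenario`,
#'   `tau_colony`, `tau_trichome`, `tau_ratio` (trichome over colony) and
#'   `success_proportion` over the `r_p` grid.
#' @export
run_tau <- function(rates = tricho_rates(), stoich = stoichiometry(),
                    config = sim_config(),
                    tau_grid_colony = make_grid(1, 5, 0.1),
                    tau_grid_trichome = make_grid(1, 5, 0.1),
                    rp_grid = make_grid(0, 1, 0.01),
                    allow_tau_below_one = FALSE) {
  check_rates(rates); check_stoich(stoich); check_config(config)
  if (!allow_tau_below_one &&
      (any(tau_grid_colony < 1) || any(tau_grid_trichome < 1))) {
    abort(
      "tau values below 1 are outside the studied range; set allow_tau_below_one = TRUE to override"
    )
  }
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  cells <- tidyr::expand_grid(
    tau_colony = tau_grid_colony,
    tau_trichome = tau_grid_trichome,
    r_p = rp_grid
  )
  final_col <- euler_final(
    net_flux(col$c_fix, col$c_fix / cells$tau_colony,
             f_res = cells$r_p * col$c_fix, stoich = stoich),
    config = config
  )
  final_tri <- euler_final(
    net_flux(tri$c_fix, tri$c_fix / cells$tau_trichome,
             f_res = cells$r_p * tri$c_fix, stoich = stoich),
    config = config
  )
  cells$win <- final_col > final_tri
  out <- dplyr::summarise(
    dplyr::group_by(cells, .data$tau_colony, .data$tau_trichome),
    success_proportion = mean(.data$win),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    tau_ratio = .data$tau_trichome / .data$tau_colony,
    .after = "tau_trichome"
  )
  out <- dplyr::mutate(out, scenario = "tau", .before = 1)
  new_scenario_result(
    out, "tau",
    grids = list(tau_colony = tau_grid_colony,
                 tau_trichome = tau_grid_trichome, r_p = rp_grid),
    rates = rates, stoich = stoich, config = config
  )
}
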