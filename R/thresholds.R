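#' Closed-form break-even and crossover thresholds
#'
#' Every quantitative threshold in the scenario analyses has a closed form,
#' because end-of-run storage is linear (or, under a biomass interaction,
#' monotone) in the constant net flux. These functions derive each
#' threshold analytically; the scenario sweeps in [run_fixed_equal()] and
#' friends recover the same numbers empirically and are tested against
#' these as oracles.
#'
#' All functions take a rate tibble whose rows are labelled `"colony"` and
#' `"trichome"` (as produced by [tricho_rates()]) and return a tidy
#' threshold report: columns `name`, `morphotype`, `value`, `units`,
#' `derivation`.
#'
#' @name thresholds
NULL

threshold_report <- function(name, morphotype, value, units, derivation) {
  tibble::tibble(
    name = name, morphotype = morphotype, value = value,
    units = units, derivation = derivation
  )
}

#' Respiration rate at which net carbon flux is zero
#'
#' For a fixed respiration rate, storage declines over the run exactly when
#' `f_res` exceeds `c_fix - n_fix * y_cn * r_nc`. At the reported rates the
#' break-even is 0.009364 for colonies and 0.0138075 for trichomes; on the
#' 0.0005-step sweep grid the last non-losing points are 0.009 and 0.0135.
#'
#' @param rates Rate tibble (one row per morphotype; all rows are reported).
#' @param stoich A [stoichiometry()] object.
#' @return A threshold report tibble, one row per morphotype.
#' @export
#' @examples
#' breakeven_respiration(tricho_rates())
breakeven_respiration <- function(rates, stoich = stoichiometry()) {
  check_rates(rates)
  threshold_report(
    name = "breakeven_respiration",
    morphotype = rates$morphotype,
    value = net_flux(rates$c_fix, rates$n_fix, stoich = stoich),
    units = "mol C h-1 mol C-1",
    derivation = "c_fix - n_fix * y_cn * r_nc"
  )
}

#' Ceiling on the colony:trichome respiration ratio
#'
#' When trichome respiration rates are bounded by `f_res_max` and colonies
#' respire at a fraction `theta` of each trichome rate, colonies can only
#' finish ahead if some admissible trichome rate `d` satisfies
#' `d * (1 - theta) > gap`, where `gap` is the zero-respiration net-flux
#' advantage of trichomes. The feasibility ceiling is therefore
#' `theta* = 1 - gap / f_res_max`: 0.777825 at the reported rates with
#' `f_res_max = 0.02`, i.e. colony respiration must stay below ~78% of the
#' trichome rate for any chance of success. Raising `f_res_max` raises the
#' ceiling (0.8889 at 0.04).
#'
#' @inheritParams breakeven_respiration
#' @param f_res_max Upper limit of trichome respiration rates, mol C
#'   h\eqn{^{-1}} mol C\eqn{^{-1}}. Default 0.02.
#' @return A one-row threshold report.
#' @export
theta_feasibility_limit <- function(rates, stoich = stoichiometry(),
                                    f_res_max = 0.02) {
  stopifnot(is.numeric(f_res_max), length(f_res_max) == 1L, f_res_max > 0)
  gap <- net_flux_gap(rates, stoich)
  if (gap > f_res_max) {
    abort(
      "colonies can never win: the zero-respiration net-flux gap exceeds f_res_max"
    )
  }
  threshold_report(
    name = "theta_feasibility_limit",
    morphotype = NA_character_,
    value = 1 - gap / f_res_max,
    units = "dimensionless",
    derivation = "1 - (net0_trichome - net0_colony) / f_res_max"
  )
}

#' Respiration coefficient above which colonies overtake trichomes
#'
#' When both morphotypes respire the same fraction `r_p` of their own
#' carbon fixation rate, the colony's smaller fixation machinery also incurs
#' smaller respiratory losses. End-of-run storages cross at
#' `r_p* = 1 - (cost_t - cost_c) / (c_fix_t - c_fix_c)` with
#' `cost = n_fix * y_cn * r_nc`; colonies strictly win above it. 0.8887 at
#' the reported rates.
#'
#' @inheritParams breakeven_respiration
#' @return A one-row threshold report.
#' @export
rp_crossover <- function(rates, stoich = stoichiometry()) {
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  if (tri$c_fix == col$c_fix) {
    abort("carbon fixation rates are equal: no crossover exists")
  }
  dc <- nfix_carbon_cost(tri$n_fix, stoich) - nfix_carbon_cost(col$n_fix, stoich)
  threshold_report(
    name = "rp_crossover",
    morphotype = NA_character_,
    value = 1 - dc / (tri$c_fix - col$c_fix),
    units = "dimensionless",
    derivation = "1 - (nfix_cost_trichome - nfix_cost_colony) / (c_fix_trichome - c_fix_colony)"
  )
}

#' Largest sustainable respiration coefficient
#'
#' The largest fraction of its own carbon fixation a morphotype can respire
#' while keeping net flux non-negative: `1 - nfix_cost / c_fix`. Colonies
#' sustain up to 93.64% of their fixation rate, trichomes up to 92.05%, at
#' the reported rates.
#'
#' @inheritParams breakeven_respiration
#' @return A threshold report tibble, one row per morphotype.
#' @export
rp_sustain_limit <- function(rates, stoich = stoichiometry()) {
  check_rates(rates)
  if (any(rates$c_fix <= 0)) {
    abort("rp_sustain_limit requires c_fix > 0")
  }
  threshold_report(
    name = "rp_sustain_limit",
    morphotype = rates$morphotype,
    value = 1 - nfix_carbon_cost(rates$n_fix, stoich) / rates$c_fix,
    units = "dimensionless",
    derivation = "1 - nfix_cost / c_fix"
  )
}

#' Supremum of the tau ratio compatible with colony success
#'
#' With nitrogen fixation re-derived as `c_fix / tau` per morphotype and a
#' shared respiration coefficient on \[0, 1\], colonies can win for some
#' coefficient iff `tau_trichome / tau_colony < c_fix_trichome /
#' c_fix_colony` (the win threshold reaches `r_p = 1` exactly at that
#' ratio). At the reported fixation rates the bound is 1.5.
#'
#' @param rates Rate tibble with `"colony"` and `"trichome"` rows; only
#'   `c_fix` enters the bound.
#' @return A one-row threshold report.
#' @export
tau_ratio_bound <- function(rates) {
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  stopifnot(col$c_fix > 0, tri$c_fix > 0)
  threshold_report(
    name = "tau_ratio_bound",
    morphotype = NA_character_,
    value = tri$c_fix / col$c_fix,
    units = "dimensionless",
    derivation = "c_fix_trichome / c_fix_colony"
  )
}

#' Shared respiration coefficient above which tau-modulated colonies win
#'
#' Applies the [rp_crossover()] formula after replacing each morphotype's
#' nitrogen fixation with `c_fix / tau`:
#' `1 - r_nc * y_cn * (c_fix_t / tau_t - c_fix_c / tau_c) /
#' (c_fix_t - c_fix_c)`. Values above 1 mean colonies never win on
#' \eqn{r_p \in [0, 1]}. Vectorized over tau pairs.
#'
#' @inheritParams breakeven_respiration
#' @param tau_colony,tau_trichome Target C:N fixation ratios, recycled
#'   against each other.
#' @return A threshold report tibble with one row per tau pair and extra
#'   columns `tau_colony`, `tau_trichome`.
#' @export
#' @examples
#' tau_win_threshold(tricho_rates(), tau_colony = 2.5, tau_trichome = 2)
tau_win_threshold <- function(rates, tau_colony, tau_trichome,
                              stoich = stoichiometry()) {
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  stopifnot(
    tri$c_fix > col$c_fix,
    is.numeric(tau_colony), all(tau_colony > 0),
    is.numeric(tau_trichome), all(tau_trichome > 0)
  )
  len <- max(length(tau_colony), length(tau_trichome))
  tau_colony <- rep_len(tau_colony, len)
  tau_trichome <- rep_len(tau_trichome, len)
  value <- 1 - stoich$r_nc * stoich$y_cn *
    (tri$c_fix / tau_trichome - col$c_fix / tau_colony) /
    (tri$c_fix - col$c_fix)
  dplyr::mutate(
    threshold_report(
      name = "tau_win_threshold",
      morphotype = NA_character_,
      value = value,
      units = "dimensionless",
      derivation = "1 - r_nc * y_cn * (c_fix_t/tau_t - c_fix_c/tau_c) / (c_fix_t - c_fix_c)"
    ),
    tau_colony = tau_colony, tau_trichome = tau_trichome
  )
}

#' Interaction strength at which colony and trichome storage are equal
#'
#' Under a shared respiration coefficient `r_p` and a metabolic interaction
#' strength `i_p`, end-of-run storages are equal at
#' `i_p* = r_p * (c_fix_t - c_fix_c) / (net0_t - net0_c) - 1`, with `net0`
#' the zero-respiration net flux. Colonies win below it: negative external
#' influence on rates favours colony formation. At `r_p = 0` the crossover
#' sits at -1 (the metabolic term must vanish entirely); at
#' `r_p = rp_crossover` it sits at 0 by construction.
#'
#' @inheritParams breakeven_respiration
#' @param r_p Shared respiration coefficient(s) in \[0, 1\]. Vectorized.
#' @return A threshold report tibble with one row per `r_p` and an `r_p`
#'   column.
#' @export
ip_crossover <- function(rates, r_p, stoich = stoichiometry()) {
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  stopifnot(is.numeric(r_p), all(r_p >= 0), all(r_p <= 1))
  gap <- net_flux_gap(rates, stoich)
  dplyr::mutate(
    threshold_report(
      name = "ip_crossover",
      morphotype = NA_character_,
      value = r_p * (tri$c_fix - col$c_fix) / gap - 1,
      units = "dimensionless",
      derivation = "r_p * (c_fix_t - c_fix_c) / (net0_t - net0_c) - 1"
    ),
    r_p = r_p
  )
}

#' Snap an analytic threshold to a sweep grid
#'
#' The sweeps report thresholds at grid resolution: the last grid point on
#' the non-losing (or winning) side. `snap_to_grid()` returns the largest
#' grid value not exceeding `value` (`strict = TRUE` requires strictly
#' below, appropriate for feasibility ceilings that are themselves
#' infeasible).
#'
#' @param value Analytic threshold(s), vectorized.
#' @param grid Numeric grid (need not be sorted).
#' @param strict Require grid point strictly below `value`?
#' @return Numeric vector of snapped values; `NA` if no grid point
#'   qualifies.
#' @export
#' @examples
#' snap_to_grid(0.009364, make_grid(0, 0.02, 0.0005))
snap_to_grid <- function(value, grid, strict = FALSE) {
  stopifnot(is.numeric(value), is.numeric(grid), length(grid) > 0)
  vapply(value, function(v) {
    keep <- if (strict) grid < v else grid <= v
    if (!any(keep)) NA_real_ else max(grid[keep])
  }, numeric(1))
}

#' All analytic thresholds in one tidy ledger
#'
#' Binds every threshold report at the supplied rates, including
#' grid-snapped variants at the default sweep resolutions (respiration grid
#' step 0.0005, theta grid step 0.01).
#'
#' @inheritParams breakeven_respiration
#' @param f_res_max Upper respiration limit for the theta ceiling.
#' @param r_p Respiration coefficient at which to evaluate [ip_crossover()].
#' @return A threshold report tibble.
#' @export
#' @examples
#' threshold_ledger(tricho_rates())
threshold_ledger <- function(rates = tricho_rates(), stoich = stoichiometry(),
                             f_res_max = 0.02, r_p = 0.9) {
  fres_grid <- make_grid(0, f_res_max, 0.0005)
  theta_grid <- make_grid(0.01, 1, 0.01)
  bk <- breakeven_respiration(rates, stoich)
  th <- theta_feasibility_limit(rates, stoich, f_res_max)
  snapped <- dplyr::bind_rows(
    dplyr::mutate(bk,
      name = "breakeven_respiration_grid",
      value = snap_to_grid(.data$value, fres_grid),
      derivation = "last non-losing point, respiration grid step 0.0005"
    ),
    dplyr::mutate(th,
      name = "theta_feasibility_limit_grid",
      value = snap_to_grid(.data$value, theta_grid, strict = TRUE),
      derivation = "last feasible point, theta grid step 0.01"
    )
  )
  dplyr::bind_rows(
    bk, th,
    rp_crossover(rates, stoich),
    rp_sustain_limit(rates, stoich),
    tau_ratio_bound(rates),
    dplyr::select(
      ip_crossover(rates, r_p, stoich),
      -dplyr::any_of("r_p")
    ),
    snapped
  )
}

# Zero-respiration net-flux advantage of trichomes over colonies.
net_flux_gap <- function(rates, stoich = stoichiometry()) {
  col <- rate_row(rates, "colony")
  tri <- rate_row(rates, "trichome")
  gap <- net_flux(tri$c_fix, tri$n_fix, stoich = stoich) -
    net_flux(col$c_fix, col$n_fix, stoich = stoich)
  if (gap <= 0) {
    abort("expected the trichome zero-respiration net flux to exceed the colony's")
  }
  gap
}
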