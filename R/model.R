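#' Carbon cost of nitrogen fixation
#'
#' The carbon drain imposed by diazotrophy per unit biomass carbon:
#' `n_fix * y_cn * r_nc`. The N:C quota converts nitrogen fixed per mol
#' biomass N into the carbon currency of the storage pool, and `y_cn` prices
#' each mol of fixed N in mol C of respired substrate.
#'
#' @param n_fix Nitrogen fixation rate(s), mol N h\eqn{^{-1}} mol
#'   N\eqn{^{-1}}. Vectorized.
#' @param stoich A [stoichiometry()] object.
#' @return Carbon cost rate(s), mol C h\eqn{^{-1}} mol C\eqn{^{-1}}.
#' @export
#' @examples
#' nfix_carbon_cost(0.004) # colony cost at default stoichiometry
nfix_carbon_cost <- function(n_fix, stoich = stoichiometry()) {
  check_stoich(stoich)
  stopifnot(is.numeric(n_fix), all(n_fix >= 0))
  n_fix * stoich$y_cn * stoich$r_nc
}

#' Net carbon flux into storage
#'
#' The instantaneous rate of change of the storage pool:
#' \deqn{(1 + i_p)\,(F_{cfix} - F_{nfix} Y^{C:N} R_{N:C}) - F_{res}}
#' With `i_p = 0` this is the core balance (carbon fixed, minus the carbon
#' cost of nitrogen fixation, minus respiration). Nonzero `i_p` scales the
#' whole metabolic term up or down, the coarse-grained stand-in for external
#' influence on fixation rates (nutrient limitation, light, temperature,
#' interactions with other organisms).
#'
#' All numeric arguments are vectorized and recycled.
#'
#' @param c_fix Carbon fixation rate(s), mol C h\eqn{^{-1}} mol C\eqn{^{-1}}.
#' @param n_fix Nitrogen fixation rate(s), mol N h\eqn{^{-1}} mol
#'   N\eqn{^{-1}}.
#' @param f_res Respiration rate(s), mol C h\eqn{^{-1}} mol C\eqn{^{-1}},
#'   non-negative. Default 0.
#' @param i_p Interaction strength on metabolic rates, dimensionless;
#'   typically in \[-2, 2\]. Default 0.
#' @param stoich A [stoichiometry()] object.
#' @return Net flux rate(s), mol C h\eqn{^{-1}} mol C\eqn{^{-1}}.
#' @export
#' @examples
#' net_flux(c_fix = 0.010, n_fix = 0.004) # colony, no respiration
net_flux <- function(c_fix, n_fix, f_res = 0, i_p = 0,
                     stoich = stoichiometry()) {
  check_stoich(stoich)
  stopifnot(
    is.numeric(c_fix), is.numeric(n_fix), is.numeric(f_res), is.numeric(i_p),
    all(f_res >= 0)
  )
  (1 + i_p) * (c_fix - nfix_carbon_cost(n_fix, stoich)) - f_res
}

#' Forward-Euler integration of the storage pool
#'
#' Integrates `dC_sto/dt = net + i_t * C_sto` with the explicit Euler
#' recurrence `C[k+1] = C[k] + dt * (net + i_t * C[k])` from `config$c0`.
#' The metabolic net flux is constant over the run; only the biomass
#' interaction term `i_t * C_sto` couples to the current state, so growth is
#' linear in time except under nonzero `i_t`. Storage may go negative: net
#' carbon loss is reported as such, with no extinction floor.
#'
#' @param net Constant net metabolic flux, mol C h\eqn{^{-1}} mol
#'   C\eqn{^{-1}} (see [net_flux()]). Scalar.
#' @param i_t Interaction strength on total biomass, h\eqn{^{-1}};
#'   typically in \[-0.002, 0.002\]. Default 0.
#' @param config A [sim_config()] object.
#' @return A tibble of class `"storage_trajectory"` with columns `time_h`
#'   and `c_sto`, one row per step plus the initial state. Attributes
#'   `delta_c_sto` (final minus initial storage), `net`, `i_t` and `config`
#'   are attached.
#' @seealso [closed_form_final()] for the exact fixed-point solution of the
#'   same recurrence.
#' @export
#' @examples
#' traj <- integrate_storage(net = 0.009364)
#' attr(traj, "delta_c_sto")
integrate_storage <- function(net, i_t = 0, config = sim_config()) {
  check_config(config)
  stopifnot(
    is.numeric(net), length(net) == 1L, is.finite(net),
    is.numeric(i_t), length(i_t) == 1L, is.finite(i_t)
  )
  n <- config$n_steps
  dt <- config$dt_hours
  c_sto <- numeric(n + 1L)
  c_sto[1L] <- config$c0
  for (k in seq_len(n)) {
    c_sto[k + 1L] <- c_sto[k] + dt * (net + i_t * c_sto[k])
  }
  out <- tibble::tibble(time_h = dt * (0:n), c_sto = c_sto)
  structure(
    out,
    delta_c_sto = c_sto[n + 1L] - c_sto[1L],
    net = net, i_t = i_t, config = config,
    class = c("storage_trajectory", class(out))
  )
}

#' Exact final storage of the Euler recurrence
#'
#' Closed-form fixed-point solution of the discrete recurrence that
#' [integrate_storage()] iterates, used as its independent oracle. With
#' `i_t = 0` the recurrence telescopes to `c0 + net * duration`; otherwise
#' `C[N] = g^N (c0 + net/i_t) - net/i_t` with per-step gain
#' `g = 1 + i_t * dt`.
#'
#' @param net Net metabolic flux(es), vectorized.
#' @param i_t Biomass interaction strength(s), h\eqn{^{-1}}, vectorized.
#' @param config A [sim_config()] object.
#' @return Final storage value(s), mol C.
#' @export
#' @examples
#' closed_form_final(net = 0.0138075) # trichome, 30 days, no respiration
closed_form_final <- function(net, i_t = 0, config = sim_config()) {
  check_config(config)
  stopifnot(is.numeric(net), all(is.finite(net)),
            is.numeric(i_t), all(is.finite(i_t)))
  n <- length(net)
  m <- length(i_t)
  len <- max(n, m)
  net <- rep_len(net, len)
  i_t <- rep_len(i_t, len)
  out <- numeric(len)
  zero <- i_t == 0
  out[zero] <- config$c0 + net[zero] * config$duration_hours
  if (any(!zero)) {
    g <- (1 + i_t[!zero] * config$dt_hours)^config$n_steps
    fp <- net[!zero] / i_t[!zero]
    out[!zero] <- g * (config$c0 + fp) - fp
  }
  out
}

# Vectorized Euler endpoint: same recurrence as integrate_storage(), iterated
# over whole parameter vectors at once. Backbone of the scenario sweeps.
euler_final <- function(net, i_t = 0, config = sim_config()) {
  check_config(config)
  stopifnot(is.numeric(net), all(is.finite(net)),
            is.numeric(i_t), all(is.finite(i_t)))
  len <- max(length(net), length(i_t))
  net <- rep_len(net, len)
  i_t <- rep_len(i_t, len)
  dt <- config$dt_hours
  c_sto <- rep_len(config$c0, len)
  for (k in seq_len(config$n_steps)) {
    c_sto <- c_sto + dt * (net + i_t * c_sto)
  }
  c_sto
}

#' @export
print.storage_trajectory <- function(x, ...) {
  cat(
    "Storage trajectory: net =", attr(x, "net"), "mol C/h/mol C; i_t =",
    attr(x, "i_t"), "/h; delta C_sto =", attr(x, "delta_c_sto"), "mol C\n"
  )
  NextMethod()
}

#' @rdname tidy-trichoflux
#' @method tidy storage_trajectory
#' @export
tidy.storage_trajectory <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time_h", "c_sto")])
}

#' @rdname glance-trichoflux
#' @method glance storage_trajectory
#' @export
glance.storage_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    net = attr(x, "net"),
    i_t = attr(x, "i_t"),
    c0 = cfg$c0,
    duration_hours = cfg$duration_hours,
    dt_hours = cfg$dt_hours,
    c_sto_final = x$c_sto[nrow(x)],
    delta_c_sto = attr(x, "delta_c_sto")
  )
}
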