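#' Metabolic rate table for one or more morphotypes
#'
#' Builds the per-morphotype table of biomass-normalized fixation rates that
#' drives every simulation: a carbon fixation rate `c_fix`
#' (mol C h\eqn{^{-1}} mol C\eqn{^{-1}}) and a nitrogen fixation rate `n_fix`
#' (mol N h\eqn{^{-1}} mol N\eqn{^{-1}}).
#'
#' @param morphotype Character vector of morphotype labels
#'   (e.g. `"colony"`, `"trichome"`).
#' @param c_fix Numeric vector of carbon fixation rates, non-negative.
#' @param n_fix Numeric vector of nitrogen fixation rates, non-negative.
#'
#' @return A tibble with columns `morphotype`, `c_fix`, `n_fix`.
#' @seealso [tricho_rates()] for the reported *Trichodesmium* values.
#' @export
#' @examples
#' metabolic_rates("colony", c_fix = 0.010, n_fix = 0.004)
metabolic_rates <- function(morphotype, c_fix, n_fix) {
  stopifnot(is.character(morphotype), is.numeric(c_fix), is.numeric(n_fix))
  out <- tibble::tibble(morphotype = morphotype, c_fix = c_fix, n_fix = n_fix)
  if (anyNA(out) || any(!is.finite(out$c_fix)) || any(!is.finite(out$n_fix))) {
    abort("metabolic rates must be finite and non-missing")
  }
  if (any(out$c_fix < 0) || any(out$n_fix < 0)) {
    abort("metabolic rates must be non-negative")
  }
  if (anyDuplicated(out$morphotype)) {
    abort("morphotype labels must be unique")
  }
  out
}

#' Reported metabolic rates for Trichodesmium colonies and free trichomes
#'
#' The measured biomass-normalized rates used throughout: free trichomes fix
#' carbon at 0.015 mol C h\eqn{^{-1}} mol C\eqn{^{-1}} and nitrogen at
#' 0.0075 mol N h\eqn{^{-1}} mol N\eqn{^{-1}}; colonies at 0.010 and 0.004
#' respectively. Colony formation lowers both rates, and lowers nitrogen
#' fixation proportionally more, so colonies carry a higher C:N fixation
#' ratio (2.5 vs 2).
#'
#' @return A two-row rate tibble (see [metabolic_rates()]).
#' @export
#' @examples
#' tricho_rates()
tricho_rates <- function() {
  metabolic_rates(
    morphotype = c("colony", "trichome"),
    c_fix = c(0.010, 0.015),
    n_fix = c(0.004, 0.0075)
  )
}

#' C:N fixation ratio (tau) of each morphotype
#'
#' Adds `tau = c_fix / n_fix`, the ratio of carbon to nitrogen fixation
#' rates. Defined only where `n_fix > 0`.
#'
#' @param rates A rate tibble from [metabolic_rates()].
#' @return The input with an added `tau` column.
#' @export
#' @examples
#' fixation_ratio(tricho_rates())
fixation_ratio <- function(rates) {
  check_rates(rates)
  if (any(rates$n_fix <= 0)) {
    abort("tau is undefined where n_fix is zero")
  }
  dplyr::mutate(rates, tau = .data$c_fix / .data$n_fix)
}

#' Re-derive nitrogen fixation from a target C:N fixation ratio
#'
#' Holds each morphotype's carbon fixation rate fixed and sets
#' `n_fix = c_fix / tau`, the manipulation used in the variable-ratio
#' scenario.
#'
#' @param rates A rate tibble.
#' @param tau Numeric vector of target ratios, recycled against the rows of
#'   `rates`. Must be strictly positive.
#' @return A rate tibble with modified `n_fix`.
#' @export
#' @examples
#' set_fixation_ratio(tricho_rates(), tau = c(2.5, 2))
set_fixation_ratio <- function(rates, tau) {
  check_rates(rates)
  stopifnot(is.numeric(tau), all(is.finite(tau)), all(tau > 0))
  dplyr::mutate(rates, n_fix = .data$c_fix / rep_len(tau, nrow(rates)))
}

#' Stoichiometric constants
#'
#' `y_cn` is the carbon cost of nitrogen fixation (mol C per mol N fixed),
#' set to 1 from the electron balance of reducing dinitrogen with
#' carbohydrate-derived electrons. `r_nc` is the cellular N:C quota ratio
#' (mol N per mol C), 0.159 for *Trichodesmium*.
#'
#' @param y_cn Carbon cost of N fixation, mol C mol N\eqn{^{-1}}. Default 1.
#' @param r_nc Cellular N:C quota, mol N mol C\eqn{^{-1}}. Default 0.159.
#' @return A list of class `"stoichiometry"`.
#' @export
stoichiometry <- function(y_cn = 1, r_nc = 0.159) {
  stopifnot(
    is.numeric(y_cn), length(y_cn) == 1L, is.finite(y_cn), y_cn > 0,
    is.numeric(r_nc), length(r_nc) == 1L, is.finite(r_nc), r_nc > 0
  )
  structure(list(y_cn = y_cn, r_nc = r_nc), class = "stoichiometry")
}

#' Simulation configuration
#'
#' Initial storage and time discretisation for the forward integration.
#' Defaults run 30 days of hourly steps from 100 mol C.
#'
#' @param c0 Initial carbon storage, mol C. Default 100.
#' @param duration_hours Total simulated time, h. Default 720 (30 days).
#' @param dt_hours Step size, h. Default 1. `duration_hours` must be a
#'   positive integer multiple of `dt_hours`.
#' @return A list of class `"sim_config"` with an `n_steps` element.
#' @export
sim_config <- function(c0 = 100, duration_hours = 720, dt_hours = 1) {
  stopifnot(
    is.numeric(c0), length(c0) == 1L, is.finite(c0),
    is.numeric(duration_hours), length(duration_hours) == 1L,
    duration_hours >= 0, is.finite(duration_hours),
    is.numeric(dt_hours), length(dt_hours) == 1L,
    dt_hours > 0, is.finite(dt_hours)
  )
  n_steps <- duration_hours / dt_hours
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    abort("duration_hours must be an integer multiple of dt_hours")
  }
  structure(
    list(
      c0 = c0, duration_hours = duration_hours,
      dt_hours = dt_hours, n_steps = as.integer(round(n_steps))
    ),
    class = "sim_config"
  )
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(
    "Stoichiometry: Y^C:N =", x$y_cn, "mol C/mol N;",
    "R_N:C =", x$r_nc, "mol N/mol C\n"
  )
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "Simulation: c0 =", x$c0, "mol C;", x$duration_hours, "h in",
    x$n_steps, "steps of", x$dt_hours, "h\n"
  )
  invisible(x)
}

check_rates <- function(rates, call = caller_env()) {
  if (!is.data.frame(rates) ||
      !all(c("morphotype", "c_fix", "n_fix") %in% names(rates))) {
    abort(
      "`rates` must have columns morphotype, c_fix, n_fix (see metabolic_rates())",
      call = call
    )
  }
  invisible(rates)
}

check_stoich <- function(stoich, call = caller_env()) {
  if (!inherits(stoich, "stoichiometry")) {
    abort("`stoich` must be created by stoichiometry()", call = call)
  }
  invisible(stoich)
}

check_config <- function(config, call = caller_env()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config()", call = call)
  }
  invisible(config)
}

# Extract the single row for one morphotype as a plain list.
rate_row <- function(rates, morphotype) {
  check_rates(rates)
  i <- which(rates$morphotype == morphotype)
  if (length(i) != 1L) {
    abort(paste0("expected exactly one row labelled '", morphotype, "'"))
  }
  as.list(rates[i, ])
}
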