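#' Plot a scenario sweep
#'
#' One ggplot per scenario family: storage change against the swept
#' parameter (coloured by morphotype) for the fixed-equal, `r_p` and `i_p`
#' sweeps; success proportion against the ratio for the theta and tau
#' sweeps; signed log storage difference against `i_t` for the biomass
#' interaction sweep.
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  meta <- attr(object, "meta")
  df <- tidy(object)
  switch(meta$scenario,
    fixed_equal = ggplot2::ggplot(
      df,
      ggplot2::aes(x = .data$f_res, y = .data$delta_c_sto,
                   colour = .data$morphotype)
    ) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = expression(F[res] ~ "(mol C" ~ h^-1 ~ "mol" ~ C^-1 * ")"),
        y = expression(Delta * C[sto] ~ "(mol C)"),
        colour = NULL
      ),
    theta = ggplot2::ggplot(
      df, ggplot2::aes(x = .data$theta, y = .data$success_proportion)
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = expression(theta), y = "colony success proportion"),
    rp = ggplot2::ggplot(
      df,
      ggplot2::aes(x = .data$r_p, y = .data$delta_c_sto,
                   colour = .data$morphotype)
    ) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = expression(r[p]), y = expression(Delta * C[sto] ~ "(mol C)"),
        colour = NULL
      ),
    ip = ggplot2::ggplot(
      df,
      ggplot2::aes(x = .data$i_p, y = .data$delta_c_sto,
                   colour = .data$morphotype)
    ) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~r_p, labeller = ggplot2::label_both) +
      ggplot2::labs(
        x = expression(i[p]), y = expression(Delta * C[sto] ~ "(mol C)"),
        colour = NULL
      ),
    it = ggplot2::ggplot(
      df,
      ggplot2::aes(x = .data$i_t, y = .data$log10_difference,
                   colour = factor(.data$r_p))
    ) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = expression(i[t] ~ (h^-1)),
        y = expression(sign %*% log[10] * "|" * Delta * "|"),
        colour = expression(r[p])
      ),
    tau = ggplot2::ggplot(
      df,
      ggplot2::aes(x = .data$tau_ratio, y = .data$success_proportion)
    ) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::labs(
        x = expression(tau[trichome] / tau[colony]),
        y = "colony success proportion"
      ),
    abort(paste0("no plot defined for scenario '", meta$scenario, "'"))
  )
}

#' Plot a storage trajectory
#'
#' @param object A `storage_trajectory` from [integrate_storage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot storage_trajectory
#' @export
autoplot.storage_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time_h, y = .data$c_sto)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = expression(C[sto] ~ "(mol C)"))
}
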