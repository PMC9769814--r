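# Shared fixtures: the reported rate table and hand-derived constants used
# as frozen oracles across test files.
rates_tbl <- tricho_rates()
stoich_default <- stoichiometry()
config_default <- sim_config()

# Hand arithmetic at the reported rates (y_cn = 1, r_nc = 0.159):
COST_COLONY <- 0.004 * 1 * 0.159 # 0.000636
COST_TRICHOME <- 0.0075 * 1 * 0.159 # 0.0011925
NET0_COLONY <- 0.010 - COST_COLONY # 0.009364
NET0_TRICHOME <- 0.015 - COST_TRICHOME # 0.0138075
NET0_GAP <- NET0_TRICHOME - NET0_COLONY # 0.0044435

# Pivot a long sweep into colony/trichome storage columns per grid point.
wide_storage <- function(result, param) {
  tidyr::pivot_wider(
    tidy(result)[, c(param, "morphotype", "c_sto_final")],
    names_from = "morphotype", values_from = "c_sto_final"
  )
}
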