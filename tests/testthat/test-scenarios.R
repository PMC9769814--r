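test_that("fixed-equal sweep reproduces storage changes and loss onsets", {
  fe <- run_fixed_equal()
  expect_s3_class(fe, "scenario_result")
  expect_identical(nrow(fe), 82L) # 41 grid points x 2 morphotypes
  at0 <- dplyr::filter(fe, f_res == 0)
  expect_equal(at0$delta_c_sto[at0$morphotype == "colony"], 6.74208,
               tolerance = 1e-9)
  expect_equal(at0$delta_c_sto[at0$morphotype == "trichome"], 9.9414,
               tolerance = 1e-9)
  pick <- function(m, fr) {
    fe$delta_c_sto[fe$morphotype == m & abs(fe$f_res - fr) < 1e-12]
  }
  expect_gt(pick("colony", 0.009), 0)
  expect_lt(pick("colony", 0.0095), 0)
  expect_gt(pick("trichome", 0.0135), 0)
  expect_lt(pick("trichome", 0.014), 0)
  # analytic break-evens sit inside the first losing grid cell
  bk <- breakeven_respiration(rates_tbl)
  expect_true(all(bk$value > c(0.009, 0.0135) & bk$value < c(0.0095, 0.014)))
})

test_that("theta sweep: ceiling, monotonicity, calibration, determinism", {
  th <- run_theta(seed = 1)
  expect_identical(th$success_proportion[th$theta == 1], 0)
  expect_true(all(diff(th$success_proportion) <= 0)) # non-increasing in theta
  expect_equal(max(th$theta[th$success_proportion > 0]), 0.77,
               tolerance = 1e-12)
  # empirical success tracks the analytic uniform-tail probability
  # (binomial 3-sigma at n = 500 is ~0.056)
  expect_true(all(
    abs(th$success_proportion - th$analytic_tail_prob) <= 0.06
  ))
  # same seed, bit-identical result; different seed, different draws
  expect_identical(tidy(run_theta(seed = 1)), tidy(th))
  th2 <- run_theta(seed = 2)
  expect_false(identical(th2$success_proportion, th$success_proportion))
  # a higher respiration limit raises the feasibility ceiling (0.8889)
  th4 <- run_theta(seed = 1, f_res_max = 0.04)
  expect_equal(max(th4$theta[th4$success_proportion > 0]), 0.88,
               tolerance = 1e-12)
  expect_error(run_theta(n_draws = 0), "n_draws")
})

test_that("r_p sweep brackets the crossover and the sustain limits", {
  rp <- run_rp()
  w <- wide_storage(rp, "r_p")
  expect_equal(min(w$r_p[w$colony > w$trichome]), 0.889, tolerance = 1e-9)
  expect_equal(max(w$r_p[w$colony <= w$trichome]), 0.888, tolerance = 1e-9)
  expect_equal(max(rp$r_p[rp$morphotype == "colony" & rp$delta_c_sto >= 0]),
               0.936, tolerance = 1e-9)
  expect_equal(max(rp$r_p[rp$morphotype == "trichome" & rp$delta_c_sto >= 0]),
               0.920, tolerance = 1e-9)
  # empirical crossover bracket contains the analytic value
  expect_true(rp_crossover(rates_tbl)$value > 0.888 &&
                rp_crossover(rates_tbl)$value < 0.889)
})

test_that("i_p sweep: no-cost dominance, crossover bracket, -1 annihilation", {
  ip <- run_ip()
  w0 <- wide_storage(dplyr::filter(ip, r_p == 0), "i_p")
  expect_true(all(w0$trichome > w0$colony | w0$i_p <= -1))
  w9 <- wide_storage(dplyr::filter(ip, r_p == 0.9), "i_p")
  winners_flip <- w9$i_p[w9$colony > w9$trichome]
  # colonies win below the crossover, trichomes above
  cross <- ip_crossover(rates_tbl, r_p = 0.9)$value
  expect_equal(max(winners_flip), snap_to_grid(cross, w9$i_p),
               tolerance = 1e-9)
  expect_true(all(w9$i_p[w9$colony <= w9$trichome] > cross))
  # i_p = -1 wipes the metabolic term: only respiration remains
  at_m1 <- dplyr::filter(ip, abs(i_p + 1) < 1e-12)
  expect_equal(
    at_m1$delta_c_sto,
    -720 * at_m1$r_p *
      ifelse(at_m1$morphotype == "colony", 0.010, 0.015),
    tolerance = 1e-9
  )
})

test_that("i_t sweep: winner invariant to i_t, set by respiration burden", {
  it <- run_it()
  for (rp in c(0, 0.3, 0.6)) {
    expect_true(all(it$difference[it$r_p == rp] < 0))
  }
  expect_true(all(it$difference[it$r_p == 0.9] > 0))
  # at i_t = 0 the pair matches a direct no-interaction integration
  at0 <- dplyr::filter(it, i_t == 0, r_p == 0.9)
  expect_equal(
    at0$c_sto_colony,
    closed_form_final(net_flux(0.010, 0.004, f_res = 0.9 * 0.010)),
    tolerance = 1e-9
  )
  # signed log magnitude inverts back to the raw difference
  s <- sign(it$difference)
  expect_true(all(!is.na(it$log10_difference) | it$difference == 0))
  expect_equal(s * 10^(s * it$log10_difference), it$difference,
               tolerance = 1e-9)
})

test_that("tau sweep: ratio bound, monotonicity, maxima", {
  tt <- run_tau()
  expect_identical(nrow(tt), 41L * 41L)
  expect_true(all(tt$success_proportion[tt$tau_ratio >= 1.5 - 1e-12] == 0))
  expect_equal(max(tt$success_proportion), 42 / 101, tolerance = 1e-12)
  expect_identical(
    tt$success_proportion[abs(tt$tau_colony - 5) < 1e-9 &
                            abs(tt$tau_trichome - 1) < 1e-9],
    max(tt$success_proportion)
  )
  # success at the ratios implied by the reported rates
  at_reported <- tt$success_proportion[abs(tt$tau_colony - 2.5) < 1e-9 &
                                         abs(tt$tau_trichome - 2) < 1e-9]
  expect_equal(at_reported, 12 / 101, tolerance = 1e-12)
  # monotone: more trichome tau never helps colonies; more colony tau never hurts
  by_col <- split(tt, tt$tau_colony)
  for (g in by_col) {
    expect_true(all(diff(g$success_proportion[order(g$tau_trichome)]) <= 0))
  }
  by_tri <- split(tt, tt$tau_trichome)
  for (g in by_tri) {
    expect_true(all(diff(g$success_proportion[order(g$tau_colony)]) >= 0))
  }
  expect_error(run_tau(tau_grid_colony = make_grid(0.5, 2, 0.5)), "below 1")
  sub <- run_tau(tau_grid_colony = c(0.5, 1), tau_grid_trichome = c(1),
                 allow_tau_below_one = TRUE)
  expect_identical(nrow(sub), 2L)
})

test_that("empirical tau crossover brackets its analytic threshold", {
  rp_grid <- make_grid(0, 1, 0.01)
  for (taus in list(c(2.5, 2), c(5, 1), c(3, 2.5), c(4, 3))) {
    tt <- run_tau(tau_grid_colony = taus[1], tau_grid_trichome = taus[2],
                  rp_grid = rp_grid)
    thr <- tau_win_threshold(rates_tbl, taus[1], taus[2])$value
    # fraction of the grid strictly above the analytic threshold
    expect_equal(tt$success_proportion, mean(rp_grid > thr))
  }
})

test_that("halving a grid step moves crossovers by at most one original cell", {
  fine <- run_fixed_equal(f_res_grid = make_grid(0, 0.02, 0.00025))
  coarse <- run_fixed_equal()
  for (m in c("colony", "trichome")) {
    last_c <- max(coarse$f_res[coarse$morphotype == m & coarse$delta_c_sto >= 0])
    last_f <- max(fine$f_res[fine$morphotype == m & fine$delta_c_sto >= 0])
    expect_lte(abs(last_f - last_c), 0.0005 + 1e-12)
  }
  rp_fine <- run_rp(rp_grid = make_grid(0.001, 1, 0.0005))
  wf <- wide_storage(rp_fine, "r_p")
  expect_lte(abs(min(wf$r_p[wf$colony > wf$trichome]) - 0.889), 0.001 + 1e-12)
})

test_that("colony success proportion counts strict wins", {
  expect_identical(
    colony_success_proportion(
      data.frame(c_sto_colony = c(1, 1), c_sto_trichome = c(1, 1))
    ),
    0
  )
  df <- data.frame(c_sto_colony = c(rep(2, 3), rep(0, 7)),
                   c_sto_trichome = rep(1, 10))
  expect_identical(colony_success_proportion(df), 0.3)
  # custom column names through tidy-eval
  df2 <- data.frame(a = 2, b = 1)
  expect_identical(colony_success_proportion(df2, a, b), 1)
  expect_error(colony_success_proportion(df[0, ]), "undefined")
})
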