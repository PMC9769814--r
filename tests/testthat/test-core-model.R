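test_that("nitrogen-fixation carbon cost matches hand arithmetic", {
  expect_identical(nfix_carbon_cost(0.004), 0.004 * 1 * 0.159)
  expect_identical(nfix_carbon_cost(0.0075), 0.0075 * 1 * 0.159)
  expect_identical(nfix_carbon_cost(0), 0)
  # quota and price scale the cost independently
  st <- stoichiometry(y_cn = 2, r_nc = 0.1)
  expect_equal(nfix_carbon_cost(0.004, st), 0.004 * 2 * 0.1)
  expect_error(nfix_carbon_cost(-1e-3), "n_fix")
})

test_that("net flux reduces to the core balance at i_p = 0", {
  expect_equal(net_flux(0.010, 0.004), NET0_COLONY, tolerance = 1e-15)
  expect_equal(net_flux(0.015, 0.0075), NET0_TRICHOME, tolerance = 1e-15)
  # i_p = -1 annihilates the metabolic term
  expect_identical(net_flux(0.015, 0.0075, f_res = 0, i_p = -1), 0)
  expect_identical(net_flux(0.010, 0.004, f_res = 0.003, i_p = -1), -0.003)
  # exact reduction for arbitrary inputs
  set.seed(11)
  for (i in 1:25) {
    cf <- runif(1, 0, 0.05); nf <- runif(1, 0, 0.02); fr <- runif(1, 0, 0.02)
    expect_identical(
      net_flux(cf, nf, f_res = fr, i_p = 0),
      (1 + 0) * (cf - nfix_carbon_cost(nf)) - fr
    )
  }
})

test_that("trajectory has the promised shape and bookkeeping", {
  traj <- integrate_storage(net = NET0_COLONY)
  expect_s3_class(traj, "storage_trajectory")
  expect_identical(nrow(traj), 721L)
  expect_identical(traj$time_h, as.double(0:720))
  expect_identical(
    attr(traj, "delta_c_sto"),
    traj$c_sto[721] - traj$c_sto[1]
  )
  expect_equal(attr(traj, "delta_c_sto"), 720 * NET0_COLONY,
               tolerance = 1e-12)
  # no flux, no change
  expect_identical(attr(integrate_storage(0), "delta_c_sto"), 0)
  # geometric growth under a pure biomass interaction
  traj_it <- integrate_storage(net = 0, i_t = 0.001)
  expect_equal(attr(traj_it, "delta_c_sto"), 100 * (1.001^720 - 1),
               tolerance = 1e-12)
  # storage may go negative; no floor is applied
  deep_loss <- integrate_storage(net = -0.2)
  expect_lt(min(deep_loss$c_sto), 0)
  expect_error(integrate_storage(NaN), "finite")
  expect_error(integrate_storage(0.01, i_t = Inf), "finite")
})

test_that("empty horizon returns the initial storage", {
  cfg0 <- sim_config(duration_hours = 0)
  expect_identical(closed_form_final(net = 0.42, config = cfg0), 100)
  traj <- integrate_storage(net = 0.42, config = cfg0)
  expect_identical(nrow(traj), 1L)
  expect_identical(attr(traj, "delta_c_sto"), 0)
})

test_that("Euler path agrees with the closed-form oracle to 1e-9 relative", {
  expect_equal(closed_form_final(NET0_TRICHOME), 100 + 720 * NET0_TRICHOME,
               tolerance = 1e-15)
  set.seed(42)
  nets <- runif(40, -0.02, 0.02)
  its <- runif(40, -0.002, 0.002)
  its[1:5] <- 0
  for (cfg in list(sim_config(), sim_config(duration_hours = 719, dt_hours = 1),
                   sim_config(c0 = 3, duration_hours = 48, dt_hours = 0.5))) {
    euler <- vapply(
      seq_along(nets),
      function(i) {
        tr <- integrate_storage(nets[i], its[i], cfg)
        tr$c_sto[nrow(tr)]
      },
      numeric(1)
    )
    cf <- closed_form_final(nets, its, cfg)
    expect_true(all(abs(euler - cf) <= 1e-9 * pmax(1, abs(cf))))
  }
})

test_that("storage change is linear in net flux and duration when i_t = 0", {
  # 720 accumulation steps against c0 = 100 leave ~1e-11 mol C of roundoff
  d1 <- attr(integrate_storage(0.004), "delta_c_sto")
  d3 <- attr(integrate_storage(3 * 0.004), "delta_c_sto")
  expect_equal(d3, 3 * d1, tolerance = 1e-9)
  half <- sim_config(duration_hours = 360)
  expect_equal(
    attr(integrate_storage(0.004, config = half), "delta_c_sto"),
    d1 / 2,
    tolerance = 1e-9
  )
})

test_that("storage change strictly decreases with respiration", {
  f_res <- seq(0, 0.02, by = 0.002)
  deltas <- vapply(
    f_res,
    function(fr) {
      attr(integrate_storage(net_flux(0.010, 0.004, f_res = fr)), "delta_c_sto")
    },
    numeric(1)
  )
  expect_true(all(diff(deltas) < 0))
})

test_that("the winner under a biomass interaction follows the net-flux sign", {
  # both morphotypes share c0 and i_t, so the Euler amplification factor is
  # common and positive: the end-of-run ordering is set by the net fluxes
  for (i_t in c(-0.002, -0.0007, 0, 0.0013, 0.002)) {
    for (rp in c(0, 0.45, 0.9)) {
      net_c <- net_flux(0.010, 0.004, f_res = rp * 0.010)
      net_t <- net_flux(0.015, 0.0075, f_res = rp * 0.015)
      fin <- closed_form_final(c(net_c, net_t), i_t)
      expect_identical(sign(fin[1] - fin[2]), sign(net_c - net_t))
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration_hours = 10, dt_hours = 3), "multiple")
  expect_error(sim_config(dt_hours = 0), "dt_hours")
  expect_error(metabolic_rates("colony", -0.01, 0.004), "non-negative")
  expect_error(metabolic_rates(c("a", "a"), c(1, 1), c(1, 1)), "unique")
  expect_error(stoichiometry(r_nc = 0), "r_nc")
  expect_error(fixation_ratio(metabolic_rates("x", 0.01, 0)), "undefined")
  expect_equal(fixation_ratio(rates_tbl)$tau, c(2.5, 2))
  modded <- set_fixation_ratio(rates_tbl, c(2.5, 2))
  expect_equal(modded$n_fix, rates_tbl$n_fix, tolerance = 1e-15)
})
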