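test_that("rate laws follow the kinetic model", {
  p <- kinetic_params(k1 = 1.03e-4)
  expect_equal(mn_rate(0, p), 0)
  expect_equal(mn_rate(3.458e-4, p), 1.03e-4 * 3.458e-4)
  expect_equal(mn_rate(1e-3, kinetic_params()), 0)
  expect_error(mn_rate(-1e-6, p), "negative")
  # autocatalytic term engages only through k2
  p2 <- kinetic_params(k1 = 1e-5, k2 = 2)
  expect_equal(mn_rate(1e-4, p2, c_mnox = 1e-3),
               1e-5 * 1e-4 + 2 * 1e-3 * 1e-4)

  q <- kinetic_params(km = 1e-3, kd = 4.49)
  expect_equal(zn_rate(2e-4, 4.49 * 2e-4, q), 0)        # at equilibrium
  expect_equal(zn_rate(2e-4, 0, q), 1e-3 * 2e-4)        # empty sorbent
  expect_lt(zn_rate(0, 1e-5, q), 0)                     # desorption
  expect_error(zn_rate(1e-4, 1e-5, kinetic_params(km = 1e-3, kd = 0)), "kd")
})

test_that("the reaction step reproduces closed-form decay and batch sorption", {
  cfg <- reactor_config(n_cells = 2, sorbent_growth = FALSE)
  # identity under all-zero kinetics
  st <- cell_state(cfg, c_mn = 1e-4, c_zn = 2e-4)
  st2 <- step_reaction(st, kinetic_params(), cfg, dt = 1e5)
  expect_equal(st2$c_mn, st$c_mn)
  expect_equal(st2$c_zn, st$c_zn)

  # pure Mn decay: 19 mg/L, k1 = 1.03e-4 /s, dt = 1e4 s -> 19 e^{-1.03}
  st <- cell_state(cfg, c_mn = mg_to_mol(19, "mn"))
  st2 <- step_reaction(st, kinetic_params(k1 = 1.03e-4), cfg, dt = 1e4)
  expect_equal(mol_to_mg(st2$c_mn[1], "mn"), 19 * exp(-1.03),
               tolerance = 1e-12)
  # oxidised Mn is banked as MnO2, one mole per mole
  expect_equal(st2$mnox[1], mg_to_mol(19, "mn") - st2$c_mn[1])

  # batch Zn equilibrium: c_eq = c0 / (1 + M kd) with fixed sorbent M = 1 g/L
  p <- kinetic_params(km = 1e-3, kd = 4.49)
  st <- cell_state(cfg, c_zn = mg_to_mol(8, "zn"))
  st2 <- step_reaction(st, p, cfg, dt = 1e6)  # >> 1/km: fully equilibrated
  expect_equal(mol_to_mg(st2$c_zn[1], "zn"), 8 / (1 + 1 * 4.49),
               tolerance = 1e-6)
  expect_equal(round(mol_to_mg(st2$c_zn[1], "zn"), 3), 1.457)
  # exchange conserved Zn per litre of pore water
  expect_equal(st2$c_zn[1] + st2$q_zn[1], mg_to_mol(8, "zn"))
})

test_that("zero-rate simulation is pure advection: outlet = delayed inlet", {
  cfg <- reactor_config()
  inlet <- data.frame(day = c(0, 2), mn = c(10, 20), zn = c(5, 3))
  sim <- simulate_reactor(cfg, kinetic_params(), inlet, hrt_days = 0.5,
                          duration_days = 4, warmup_flushes = 0)
  # after the first flush the outlet replays the inlet with a one-HRT delay
  late <- sim$times_days > 0.5 + 1e-9
  expected_mn <- ifelse(sim$times_days[late] - 0.5 < 2, 10, 20)
  expect_equal(sim$outlet_mn_mg_l[late], expected_mn, tolerance = 1e-12)
  expect_equal(mass_balance(sim), c(mn = 0, zn = 0), tolerance = 1e-12)
})

test_that("dispersion-free steady state matches the plug-flow oracle", {
  cfg <- reactor_config()
  for (k1 in c(2e-5, 1.03e-4, 3e-4)) {
    for (hrt in c(0.3, 0.5)) {
      sim <- simulate_reactor(cfg, kinetic_params(k1 = k1), c(mn = 19, zn = 0),
                              hrt_days = hrt, duration_days = 3 * hrt)
      expect_equal(tail(sim$outlet_mn_mg_l, 1), plugflow_outlet(19, k1, hrt),
                   tolerance = 1e-10)
    }
  }
  expect_equal(plugflow_outlet(25, 1.03e-4, log(2.5) / 1.03e-4 / 86400), 10)
  expect_equal(plugflow_outlet(7, 1.03e-4, 0), 7)
  expect_equal(plugflow_outlet(7, 0, 3), 7)
})

test_that("solute budgets close to machine precision under random kinetics", {
  set.seed(21)
  sch <- hrt_schedule(c(0, 5), c(5, 12), c(1, 0.4))
  for (i in 1:6) {
    p <- kinetic_params(k1 = 10^runif(1, -6, -3.5), km = 10^runif(1, -5, -2),
                        kd = 10^runif(1, -1, 1))
    cfg <- reactor_config(initial_sorbent_g_l = runif(1, 0.1, 3),
                          sorbent_growth = i %% 2 == 0,
                          dispersivity_m = sample(c(0, 0.05), 1))
    inlet <- data.frame(day = c(0, 6), mn = runif(2, 5, 25),
                        zn = runif(2, 2, 10))
    sim <- simulate_schedule(cfg, p, inlet, sch)
    bal <- mass_balance(sim)
    expect_lt(bal[["mn"]], 1e-8)
    expect_lt(bal[["zn"]], 1e-8)
    # positivity of every state variable
    expect_true(all(unlist(sim$state) >= 0))
    expect_true(all(sim$outlet_mn_mg_l >= 0) && all(sim$outlet_zn_mg_l >= 0))
  }
})

test_that("steady outlets are monotone in HRT, k1, kd and sorbent inventory", {
  cfg <- reactor_config()
  p <- pilot_params()
  out_hrt <- vapply(c(0.1, 0.3, 0.5, 1),
                    function(h) steady_outlet(cfg, p, 19, h, "mn")$outlet_mg_l,
                    numeric(1))
  expect_true(all(diff(out_hrt) <= 1e-12))
  out_k1 <- vapply(c(2e-5, 1e-4, 5e-4), function(k)
    steady_outlet(cfg, kinetic_params(k1 = k), 19, 0.3, "mn")$outlet_mg_l,
    numeric(1))
  expect_true(all(diff(out_k1) <= 1e-12))
  out_kd <- vapply(c(1, 4.49, 20), function(kd)
    steady_outlet(cfg, kinetic_params(k1 = p$k1, km = p$km, kd = kd),
                  8, 0.5, "zn", c_in_other = 19)$outlet_mg_l, numeric(1))
  expect_true(all(diff(out_kd) <= 1e-9))
  out_m <- vapply(c(0.5, 2), function(m0)
    steady_outlet(reactor_config(initial_sorbent_g_l = m0, sorbent_growth = FALSE),
                  kinetic_params(k1 = p$k1, km = p$km, kd = p$kd),
                  8, 0.5, "zn", c_in_other = 19, max_flushes = 200)$outlet_mg_l,
    numeric(1))
  expect_true(all(diff(out_m) <= 1e-9))
})

test_that("large km drives the sorbed phase to local equilibrium", {
  cfg <- reactor_config()
  p <- kinetic_params(k1 = 1.03e-4, km = 1, kd = 4.49)  # km >> 1/dt
  sim <- simulate_reactor(cfg, p, c(mn = 19, zn = 8), hrt_days = 0.5,
                          duration_days = 5)
  s <- sim$state
  s_zn <- s$q_zn / s$m_solid
  active <- s$c_zn > 1e-12
  expect_true(all(abs(s_zn[active] / p$kd - s$c_zn[active]) /
                    s$c_zn[active] < 1e-3))
})
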