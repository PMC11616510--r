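test_that("residuals are simulated-minus-observed and vanish at the truth", {
  cfg <- reactor_config()
  camp <- generate_campaign(campaign_spec(seed = 2, noise_cv = 0),
                            config = cfg)
  ds <- campaign_fit_dataset(camp)
  r <- residuals_kinetics(camp$truth$params, ds, cfg, "mn")
  expect_lt(max(abs(r)), 1e-10)
  r_zn <- residuals_kinetics(camp$truth$params, ds, cfg, "zn")
  expect_lt(max(abs(r_zn)), 1e-10)

  # inert column against decaying observations: simulation overshoots
  r0 <- residuals_kinetics(kinetic_params(), ds, cfg, "mn")
  expect_true(all(r0 > 0))

  # plain subtraction on a constructed inert dataset
  sch <- hrt_schedule(0, 10, 0.5)
  inlet <- data.frame(day = c(0, 10), mn = c(1, 1), zn = c(1, 1))
  obs <- data.frame(day = c(3, 5, 7), mn = c(0.8, 1.0, 1.2),
                    zn = c(0.8, 1.0, 1.2))
  ds2 <- fit_dataset(inlet, obs, sch)
  r2v <- residuals_kinetics(kinetic_params(), ds2, cfg, "mn")
  expect_equal(as.numeric(r2v), c(0.2, 0.0, -0.2), tolerance = 1e-10)
})

test_that("noiseless campaigns are recovered to solver precision", {
  cfg <- reactor_config()
  camp <- generate_campaign(campaign_spec(seed = 4, noise_cv = 0),
                            config = cfg)
  ds <- campaign_fit_dataset(camp)
  fmn <- fit_kinetics(kinetic_params(k1 = 1e-5, km = 1e-3, kd = 1), ds, cfg,
                      "mn")
  expect_lt(abs(fmn$params$k1 / camp$truth$params$k1 - 1), 1e-3)
  fzn <- fit_kinetics(fmn$params, ds, cfg, "zn")
  expect_lt(abs(fzn$params$kd / camp$truth$params$kd - 1), 1e-3)
})

test_that("noisy single-campaign recovery of k1 is within 10 %", {
  cfg <- reactor_config()
  camp <- generate_campaign(campaign_spec(seed = 7, noise_cv = 0.05),
                            config = cfg)
  fmn <- fit_kinetics(kinetic_params(k1 = 1e-5), campaign_fit_dataset(camp),
                      cfg, "mn")
  expect_lt(abs(fmn$params$k1 / 1.03e-4 - 1), 0.10)
  expect_true(fmn$converged)
})

test_that("the objective never exceeds its value at the initial guess", {
  cfg <- reactor_config()
  camp <- generate_campaign(campaign_spec(seed = 9), config = cfg)
  ds <- campaign_fit_dataset(camp)
  init <- kinetic_params(k1 = 3e-5, km = 1e-3, kd = 1)
  f <- fit_kinetics(init, ds, cfg, "mn")
  obj0 <- sum(residuals_kinetics(init, ds, cfg, "mn")^2)
  expect_lte(f$objective, obj0)
  # validation datasets are scored but do not move the fit
  ds_val <- campaign_fit_dataset(camp, role = "validation", label = "val")
  f2 <- fit_kinetics(init, list(ds, ds_val), cfg, "mn")
  expect_equal(f2$params$k1, f$params$k1, tolerance = 1e-12)
  expect_setequal(f2$metrics$role, c("calibration", "validation"))
})

test_that("fits are invariant to observation order and support weighting", {
  cfg <- reactor_config()
  camp <- generate_campaign(campaign_spec(seed = 12), config = cfg)
  ds <- campaign_fit_dataset(camp)
  perm <- sample(nrow(ds$observed))
  ds_shuf <- ds
  ds_shuf$observed <- ds$observed[perm, ]
  init <- kinetic_params(k1 = 1e-5)
  f1 <- fit_kinetics(init, ds, cfg, "mn")
  f2 <- fit_kinetics(init, ds_shuf, cfg, "mn")
  expect_equal(f1$params$k1, f2$params$k1, tolerance = 1e-10)
  fw <- fit_kinetics(init, ds, cfg, "mn", weights = "inverse_obs")
  expect_true(fw$converged)
})

test_that("fit datasets enforce their invariants", {
  sch <- hrt_schedule(0, 10, 0.5)
  inlet <- data.frame(day = c(0, 10), mn = c(1, 1), zn = c(1, 1))
  expect_error(fit_dataset(inlet, data.frame(day = c(1, 2), mn = 1:2,
                                             zn = 1:2), sch),
               ">= 3 observations")
  expect_error(fit_dataset(inlet, data.frame(day = c(1, 2, 40), mn = 1:3,
                                             zn = 1:3), sch),
               "outside")
})
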