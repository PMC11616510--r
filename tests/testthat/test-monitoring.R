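test_that("monitoring CSV parsing handles the documented schema", {
  f <- write_lines_tmp(c(monitoring_header,
                         "2022-07-01,A1,0.30,1.59,7.1,9.3,,,",
                         "2022-07-06,A0,19.2,8.1,6.9,7.7,1138,138,15"))
  rec <- read_monitoring_csv(f)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$mn[1], 0.30)
  expect_equal(rec$zn[1], 1.59)
  expect_true(is.na(rec$ec[1]))
  expect_equal(rec$ec[2], 1138)

  # empty data section -> empty record set
  expect_equal(nrow(read_monitoring_csv(write_lines_tmp(monitoring_header))), 0)

  # unknown station -> validation error naming the row
  f_bad <- write_lines_tmp(c(monitoring_header, "2022-07-01,B9,1,1,,,,,"))
  expect_error(read_monitoring_csv(f_bad), "B9")
  expect_error(read_monitoring_csv(f_bad), "row 1")

  # missing mandatory column -> schema error
  f_nocol <- write_lines_tmp(c("date,station,zn_mg_l", "2022-07-01,A1,1"))
  expect_error(read_monitoring_csv(f_nocol), "mn_mg_l")

  # unparseable numeric cell -> missing value, never a silent zero
  f_na <- write_lines_tmp(c(monitoring_header, "2022-07-01,A1,abc,1.0,,,,,"))
  expect_true(is.na(read_monitoring_csv(f_na)$mn[1]))

  # invariant violations are refused
  f_neg <- write_lines_tmp(c(monitoring_header, "2022-07-01,A1,-1,1,,,,,"))
  expect_error(read_monitoring_csv(f_neg), "negative")
  f_ph <- write_lines_tmp(c(monitoring_header, "2022-07-01,A1,1,1,15.2,,,,"))
  expect_error(read_monitoring_csv(f_ph), "pH")
})

test_that("HRT schedules validate ordering, overlap and half-open matching", {
  sch <- pilot_schedule()
  expect_equal(sch$label, c("hrt2d", "hrt0.5d", "hrt0.3d"))
  expect_error(hrt_schedule(c(0, 10), c(16, 20), c(1, 1)), "overlap")
  expect_error(hrt_schedule(0, 0, 1), "after start")
  expect_error(hrt_schedule(0, 16, -2))
  # boundary day belongs to the regime that starts there (half-open)
  expect_equal(assign_regime(c(0, 15.9, 16, 113, 151.9, 152), sch),
               c("hrt2d", "hrt2d", "hrt0.5d", "hrt0.3d", "hrt0.3d", NA))
})

test_that("removal efficiency matches the regime-mean definition", {
  sch <- hrt_schedule(0, 100, 0.5)
  days <- seq(5, 95, by = 5)
  inlet <- mk_series(days, mn = rep(19, length(days)), schedule = sch)
  outlet <- mk_series(days, mn = rep(0.5, length(days)), schedule = sch)
  expect_equal(removal_efficiency(inlet, outlet, "hrt0.5d", "mn"),
               100 * (19 - 0.5) / 19, tolerance = 1e-12)
  # identical series -> no removal; paired mode agrees
  expect_equal(removal_efficiency(inlet, inlet, "hrt0.5d", "mn"), 0)
  expect_equal(removal_efficiency(inlet, outlet, "hrt0.5d", "mn",
                                  method = "paired"),
               100 * (19 - 0.5) / 19, tolerance = 1e-12)
  # no data in regime -> insufficient-data error
  expect_error(removal_efficiency(inlet, outlet, "nonexistent", "mn"),
               "insufficient")
})

test_that("removal efficiency is scale-invariant and bounded above by 100", {
  sch <- hrt_schedule(0, 50, 1)
  set.seed(11)
  for (i in 1:5) {
    days <- sort(sample(1:49, 8))
    iv <- runif(8, 5, 25); ov <- runif(8, 0, 30)
    inlet <- mk_series(days, iv, schedule = sch)
    outlet <- mk_series(days, ov, schedule = sch)
    e <- removal_efficiency(inlet, outlet, "hrt1d", "mn")
    a <- runif(1, 0.1, 10)
    e_scaled <- removal_efficiency(mk_series(days, a * iv, schedule = sch),
                                   mk_series(days, a * ov, schedule = sch),
                                   "hrt1d", "mn")
    expect_equal(e, e_scaled, tolerance = 1e-10)
    expect_lte(e, 100)
  }
  zero_out <- mk_series(c(5, 10), c(0, 0), schedule = sch)
  some_in <- mk_series(c(5, 10), c(4, 6), schedule = sch)
  expect_equal(removal_efficiency(some_in, zero_out, "hrt1d", "mn"), 100)
})

test_that("molar ratio uses Mn 54.938 and Zn 65.38 g/mol", {
  expect_equal(molar_ratio(20, 9.5), (20 / 54.938) / (9.5 / 65.38))
  expect_equal(round(molar_ratio(20, 9.5), 2), 2.51)
  expect_equal(molar_ratio(0, 8), 0)
  expect_equal(molar_ratio(54.938, 65.38), 1.0)
  expect_equal(molar_ratio(3 * 20, 3 * 9.5), molar_ratio(20, 9.5))
  expect_error(molar_ratio(1, 0), "positive")
})

test_that("station summaries report regime means, extrema and missing counts", {
  sch <- hrt_schedule(0, 50, 1)
  s <- mk_series(c(5, 10, 15), mn = c(1, 2, 3), zn = c(2, NA, 4),
                 schedule = sch)
  out <- summarise_station(s)
  mn_row <- out[out$analyte == "mn", ]
  expect_equal(mn_row$mean, 2); expect_equal(mn_row$min, 1)
  expect_equal(mn_row$max, 3); expect_equal(mn_row$n, 3)
  zn_row <- out[out$analyte == "zn", ]
  expect_equal(zn_row$mean, 3); expect_equal(zn_row$n_missing, 1)
  single <- summarise_station(mk_series(5, 7.5, schedule = sch))
  expect_equal(single$mean[single$analyte == "mn"], 7.5)
  expect_error(summarise_station(mk_series(numeric(), numeric())), "empty")
})
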