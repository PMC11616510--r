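test_that("spectra validate their grid and interpolate linearly", {
  expect_error(xas_spectrum(c(1, 1, 2), c(0, 1, 2)), "strictly increasing")
  sp <- xas_spectrum(c(0, 1, 2), c(0, 2, 6), e0 = 1)
  same <- interpolate_to_grid(sp, c(0, 1, 2))
  expect_equal(same$absorbance, sp$absorbance)
  expect_equal(interpolate_to_grid(sp, 0.5)$absorbance, 1)  # segment midpoint
  expect_error(interpolate_to_grid(sp, c(1, 3)), "outside")
})

test_that("LCF recovers pure spectra and constructed mixtures exactly", {
  refs <- synth_refs()
  grid <- refs[[1]]$energy
  pure <- xas_spectrum(grid, refs[[2]]$absorbance, label = "pure", e0 = 6550)
  fit <- lcf_fit(pure, refs)
  expect_equal(unname(fit$weights), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(fit$r_factor, 1e-16)

  mix <- xas_spectrum(grid, 0.5 * refs[[1]]$absorbance +
                        0.5 * refs[[3]]$absorbance, e0 = 6550)
  fit2 <- lcf_fit(mix, refs)
  expect_equal(unname(fit2$weights), c(0.5, 0, 0.5), tolerance = 1e-9)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)
})

test_that("random convex mixtures are recovered across seeded trials", {
  refs <- synth_refs()
  grid <- refs[[1]]$energy
  A <- vapply(refs, function(r) r$absorbance, numeric(length(grid)))
  set.seed(31)
  for (i in 1:10) {
    w <- runif(3); w <- w / sum(w)
    mix <- xas_spectrum(grid, as.numeric(A %*% w), e0 = 6550)
    fit <- lcf_fit(mix, refs)
    expect_equal(unname(fit$weights), w, tolerance = 1e-6)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    # noisy recovery within 3 sigma of the propagated noise level
    sig <- 0.01
    noisy_mix <- xas_spectrum(grid, as.numeric(A %*% w) + rnorm(length(grid),
                                                                sd = sig),
                              e0 = 6550)
    fitn <- lcf_fit(noisy_mix, refs)
    expect_lt(max(abs(fitn$weights - w)), 3 * sig * 10)
  }
})

test_that("reference permutation permutes weights; duplicates warn", {
  refs <- synth_refs()
  grid <- refs[[1]]$energy
  mix <- xas_spectrum(grid, 0.2 * refs[[1]]$absorbance +
                        0.8 * refs[[2]]$absorbance, e0 = 6550)
  f1 <- lcf_fit(mix, refs)
  f2 <- lcf_fit(mix, refs[c(3, 1, 2)])
  expect_equal(unname(f2$weights), unname(f1$weights)[c(3, 1, 2)],
               tolerance = 1e-9)
  expect_warning(lcf_fit(mix, list(refs[[1]], refs[[1]], refs[[2]])),
                 "ill-conditioned")
  # free-sum mode reaches the same mixture here without the constraint
  f3 <- lcf_fit(mix, refs, sum_to_one = FALSE)
  expect_equal(sum(f3$weights), 1, tolerance = 1e-6)
})

test_that("spectrum files round-trip through the two-column reader", {
  refs <- synth_refs(seq(6530, 6590, by = 1))
  f <- tempfile(fileext = ".txt")
  writeLines(c("# synthetic reference",
               paste(refs[[1]]$energy, refs[[1]]$absorbance)), f)
  sp <- read_spectrum(f, e0 = 6550)
  expect_equal(sp$energy, refs[[1]]$energy)
  expect_equal(sp$absorbance, refs[[1]]$absorbance)
})
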