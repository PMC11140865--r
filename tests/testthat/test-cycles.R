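test_that("cycle sums reproduce the published derived rows", {
  reg <- pplfer_registry()
  dry <- derive_sum(reg$KOA, reg$KAW, "KOW_dry")
  expect_equal(dry$coef[["s"]], 0.69 + (-2.26))
  expect_equal(dry$coef[["v"]], 0.52 + 2.19)
  expect_equal(round2(dry$total_se), 0.23)
  expect_equal(round2(sqrt(0.17^2 + 0.16^2)), 0.23)

  so_dry <- derive_sum(reg$SW_liquid, dry, "SO_dry_liquid")
  expect_equal(so_dry$coef[["a"]], 2.80 + (-0.16))
  expect_equal(round2(so_dry$total_se), 0.64)
  # d term carries over from the solubility row untouched
  expect_equal(so_dry$coef[["d"]], -1.60)
  expect_equal(so_dry$se[["d"]], 0.27)
})

test_that("adding an all-zero parameter set is the identity", {
  kaw <- builtin_system_parameters("KAW")
  z <- zero_params("KOA")
  out <- derive_sum(kaw, z, "KAW")
  expect_equal(out$coef, kaw$coef)
  expect_equal(out$se, kaw$se)
  expect_equal(out$total_se, kaw$total_se)
})

test_that("cycle differences reproduce the wet/dry octanol row", {
  reg <- pplfer_registry()
  dry <- derive_sum(reg$KOA, reg$KAW, "KOW_dry")
  koo <- derive_difference(reg$KOW_wet, dry, "KOO")
  expect_equal(koo$coef[["b"]], -3.49 - (-4.05))
  expect_equal(koo$coef[["l"]], 0)
  expect_equal(koo$coef[["v"]], round(2.41 - 2.71, 10))
  # s.e. propagate in quadrature with the dry row kept unrounded
  expect_equal(round2(koo$total_se),
               round2(sqrt(0.15^2 + 0.17^2 + 0.16^2)))
  expect_equal(round2(koo$total_se), 0.28)

  self <- derive_difference(reg$KOW_wet, reg$KOW_wet, "KOO")
  expect_true(all(self$coef == 0))
})

test_that("derivations commute, associate, and differences invert sums", {
  reg <- pplfer_registry()
  ab <- derive_sum(reg$KOA, reg$KAW, "KOW_dry")
  ba <- derive_sum(reg$KAW, reg$KOA, "KOW_dry")
  expect_equal(ab$coef, ba$coef)
  expect_equal(ab$total_se, ba$total_se)

  s1 <- derive_sum(derive_sum(reg$SW_liquid, reg$KOA, "SW_liquid"),
                   reg$KAW, "SW_liquid")
  s2 <- derive_sum(reg$SW_liquid,
                   derive_sum(reg$KOA, reg$KAW, "KOW_dry"), "SW_liquid")
  expect_equal(s1$coef, s2$coef, tolerance = 1e-12)
  expect_equal(s1$total_se, s2$total_se, tolerance = 1e-12)

  back <- derive_difference(ab, reg$KAW, "KOA")
  expect_equal(back$coef, reg$KOA$coef, tolerance = 1e-12)
  # s.e. do not invert: quadrature accumulates either way
  expect_gt(back$total_se, reg$KOA$total_se)
})

test_that("unit algebra rejects combinations that do not yield the endpoint", {
  reg <- pplfer_registry()
  expect_error(derive_sum(reg$KOA, reg$KAW, "SW_liquid"),
               "endpoint mismatch")
  expect_error(derive_sum(reg$SW_liquid, reg$VP_liquid, "SW_liquid"),
               "endpoint mismatch")
})

test_that("cycle audit passes on the bundled registry and flags defects", {
  aud <- check_cycle_consistency(pplfer_registry())
  expect_true(attr(aud, "pass"))
  expect_true(all(aud$residual <= 0.005))
  # the wet-octanol solubility intercept closes exactly: 0.59 = 0.18 + 0.41
  c_row <- aud[aud$endpoint == "SO_wet_liquid" & aud$term == "c", ]
  expect_equal(c_row$residual, 0)

  broken <- pplfer_registry()
  broken$KOW_dry$coef[["s"]] <- broken$KOW_dry$coef[["s"]] + 0.1
  aud2 <- check_cycle_consistency(broken)
  expect_false(attr(aud2, "pass"))
  bad <- aud2[aud2$endpoint == "KOW_dry" & aud2$term == "s", ]
  expect_equal(bad$residual, 0.1)

  expect_error(check_cycle_consistency(pplfer_registry()[1:3]),
               "missing endpoints")
})

test_that("noise-free calibration interpolates the generating parameters", {
  for (ep in c("KAW", "SW_liquid")) {
    truth <- builtin_system_parameters(ep)
    dat <- generate_property_dataset(truth, n = 50, noise_sd = 0,
                                     seed = 3)
    fit <- suppressWarnings(calibrate_system_parameters(dat, ep))
    expect_equal(fit$coef, truth$coef, tolerance = 1e-8, label = ep)
    expect_lt(fit$total_se, 1e-8)
  }
})

test_that("noisy calibration recovers parameters within estimated error", {
  truth <- builtin_system_parameters("KAW")
  dat <- generate_property_dataset(truth, n = 500, noise_sd = 0.2,
                                   seed = 42)
  fit <- calibrate_system_parameters(dat, "KAW")
  used <- c("s", "a", "b", "v", "l", "c")
  z <- abs(fit$coef[used] - truth$coef[used]) / fit$se[used]
  expect_true(all(z <= 3))
  expect_gte(fit$total_se, 0.17)
  expect_lte(fit$total_se, 0.23)
})

test_that("degenerate calibration inputs raise informative errors", {
  dat <- generate_property_dataset(builtin_system_parameters("KAW"),
                                   n = 40, noise_sd = 0, seed = 5)
  dat$L <- dat$V  # two identical descriptor columns
  expect_error(calibrate_system_parameters(dat, "KAW"),
               "rank deficient")
  small <- generate_property_dataset(builtin_system_parameters("KAW"),
                                     n = 5, noise_sd = 0, seed = 5)
  expect_error(calibrate_system_parameters(small, "KAW"), "few rows")
  expect_error(calibrate_system_parameters(dat[0, ], "KAW"))
})
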