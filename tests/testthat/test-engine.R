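test_that("partition equation reproduces hand-computed values", {
  reg <- pplfer_registry()
  # interaction-free solute: the intercept
  expect_equal(evaluate_partition(reg$KOW_wet, zero_descriptors()), 0.41)
  # dry KOW intercept is the sum of the KOA and KAW intercepts
  expect_equal(evaluate_partition(reg$KOW_dry, zero_descriptors()),
               0.64 + (-0.26))
  # unit descriptors: plain sum of coefficients
  ones <- list(S = 1, A = 1, B = 1, V = 1, L = 1)
  expect_equal(evaluate_partition(reg$KOW_wet, ones),
               -1.36 - 0.13 - 3.49 + 2.41 + 0.41 + 0.41)
})

test_that("solubility equation includes the sqrt(A*B) term", {
  sw <- builtin_system_parameters("SW_liquid")
  expect_equal(evaluate_solubility(sw, zero_descriptors()), 0.18)
  expect_equal(evaluate_solubility(sw, list(S = 0, A = 1, B = 1,
                                            V = 0, L = 0)),
               2.80 + 4.15 - 1.60 + 0.18)
  # with A = 0 the d term contributes exactly nothing
  with_b <- list(S = 0.5, A = 0, B = 1.2, V = 1, L = 3)
  no_d <- sw
  no_d$coef[["d"]] <- 0
  expect_identical(evaluate_solubility(sw, with_b),
                   evaluate_solubility(no_d, with_b))
})

test_that("equation forms are enforced and bad descriptors named", {
  reg <- pplfer_registry()
  expect_error(evaluate_partition(reg$SW_liquid, zero_descriptors()),
               "partition endpoint")
  expect_error(evaluate_solubility(reg$KAW, zero_descriptors()),
               "solubility endpoint")
  expect_error(evaluate_partition(reg$KAW,
                                  list(S = 1, A = 1, B = NA, V = 1,
                                       L = 1)),
               "'B'")
  expect_error(evaluate_solubility(reg$SW_liquid,
                                   list(S = 1, A = -0.1, B = 1, V = 1,
                                        L = 1)),
               "sqrt")
})

test_that("partition equation is linear with slope equal to each coefficient", {
  kaw <- builtin_system_parameters("KAW")
  base <- list(S = 0.8, A = 0.2, B = 0.5, V = 1.4, L = 5.1)
  for (f in c("S", "A", "B", "V", "L")) {
    bumped <- base
    bumped[[f]] <- bumped[[f]] + 1
    slope <- evaluate_partition(kaw, bumped) -
      evaluate_partition(kaw, base)
    expect_equal(slope, kaw$coef[[tolower(substr(f, 1, 1))]],
                 tolerance = 1e-12, label = f)
  }
})

test_that("predictions close the thermodynamic cycles for any solute", {
  reg <- pplfer_registry()
  full <- derived_full_precision(reg)
  sols <- generate_solutes(25, seed = 11)
  for (i in seq_len(nrow(sols))) {
    sd_i <- as.list(sols[i, c("S", "A", "B", "V", "L")])
    expect_equal(evaluate_partition(reg$KOA, sd_i) +
                   evaluate_partition(reg$KAW, sd_i),
                 evaluate_partition(full$KOW_dry, sd_i),
                 tolerance = 1e-12)
    expect_equal(evaluate_solubility(reg$SW_liquid, sd_i) +
                   evaluate_partition(reg$KOW_wet, sd_i),
                 evaluate_solubility(full$SO_wet_liquid, sd_i),
                 tolerance = 1e-12)
  }
})

test_that("Raoult's-law vapor pressure route matches direct arithmetic", {
  expect_equal(vp_from_kkak(0, MV = 0.1), log10(8.314 * 298.15 / 1e-4),
               tolerance = 1e-9)
  expect_equal(round(vp_from_kkak(0, MV = 0.1), 3), 7.394)
  expect_equal(round(vp_from_kkak(3, MV = 0.1), 3), 4.394)
  # doubling the activity coefficient lowers log VP by log10(2)
  expect_equal(vp_from_kkak(1.2, MV = 0.2, gamma = 2),
               vp_from_kkak(1.2, MV = 0.2, gamma = 1) - log10(2))
  expect_error(vp_from_kkak(0, MV = -1), "MV")
  expect_error(vp_from_kkak(0, MV = 0.1, gamma = 0), "gamma")
  expect_error(vp_from_kkak(0, MV = 0.1, T = 0), "T")
  expect_warning(vp_from_kkak(0, MV = 0.1, state = "solid"),
                 "validated for liquids")
})

test_that("K_kAk evaluation is a plain linear form of the descriptors", {
  kp <- kkak_parameters(s = -1, a = -2, b = -1.5, v = 1, l = -0.8,
                        c = 7)
  sd1 <- list(S = 1, A = 0.5, B = 0.2, V = 2, L = 6)
  expect_equal(evaluate_kkak(kp, sd1),
               -1 * 1 - 2 * 0.5 - 1.5 * 0.2 + 1 * 2 - 0.8 * 6 + 7)
  expect_error(kkak_parameters(1, 2, NA, 4, 5, 6), "finite")
})

test_that("VP to solubility-in-air conversion is the ideal-gas affine map", {
  expect_equal(round(vp_to_sa(log10(101325)), 3), -1.389)
  # at VP = 1000 RT Pa one mole occupies one litre: log S_A = 0 exactly
  expect_identical(vp_to_sa(log10(1000 * 8.314 * 298.15)), 0)
  expect_equal(vp_to_sa(3.2) - vp_to_sa(2.2), 1)
  expect_error(vp_to_sa(1, T = -5), "T")
})
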