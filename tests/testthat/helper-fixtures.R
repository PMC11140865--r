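# shared helpers for the test suite; all fixtures are built in code

# a system-parameter set with every coefficient and s.e. equal to zero
zero_params <- function(endpoint = "KAW") {
  system_parameters(endpoint,
                    coef = c(s = 0, a = 0, b = 0, d = 0, v = 0, l = 0,
                             c = 0),
                    se = c(s = 0, a = 0, b = 0, d = 0, v = 0, l = 0,
                           c = 0),
                    total_se = 0)
}

# descriptor list with every descriptor zero (intercept-only solute)
zero_descriptors <- function() list(S = 0, A = 0, B = 0, V = 0, L = 0)

# full-precision cycle-derived rows, recomputed from calibrated rows
derived_full_precision <- function(reg = pplfer_registry()) {
  dry <- derive_sum(reg$KOA, reg$KAW, "KOW_dry")
  list(KOW_dry = dry,
       KOO = derive_difference(reg$KOW_wet, dry, "KOO"),
       SO_dry_liquid = derive_sum(reg$SW_liquid, dry, "SO_dry_liquid"),
       SO_wet_liquid = derive_sum(reg$SW_liquid, reg$KOW_wet,
                                  "SO_wet_liquid"))
}
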