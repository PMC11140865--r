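# pplferkit

Thermodynamically consistent prediction of physical–chemical
properties for neutral organic chemicals, with honest uncertainty.

Environmental fate, exposure and risk assessment need six core
properties per chemical — the octanol–water (wet and dry),
octanol–air and air–water partition ratios, vapor pressure, and
solubility in water and octanol — and they need them to be mutually
consistent: a chemical's K<sub>OW</sub>, K<sub>OA</sub> and
K<sub>AW</sub> are not independent numbers but ratios of its three
solubilities. `pplferkit` implements that workflow for modellers and
cheminformaticians who have Abraham solute descriptors (S, A, B, V,
L) for their chemicals, whether measured or predicted upstream.

## The model

Partition ratios follow the poly-parameter linear free energy
relationship (PPLFER / Abraham equation)

    log K = s·S + a·A + b·B + v·V + l·L + c

and pure-phase properties (vapor pressure, solubilities) the extended
form with a solute self-interaction term

    log S = s·S + a·A + b·B + d·(A·B)^0.5 + v·V + l·L + c.

System parameters for nine endpoints at 25 °C ship with the package.
Five rows are calibrated; four are *defined* by three-solubility
thermodynamic cycles (dry K_OW = K_OA + K_AW; K_OO = wet − dry K_OW;
S_O = S_W + K_OW), with standard errors propagated in quadrature.
Around the equations sits the full prediction pipeline:
physical-state classification, Van't Hoff solid ↔ supercooled-liquid
conversion, physical upper bounds on VP and solubility,
applicability-domain diagnostics (leverage, Tanimoto similarity,
negative-domain check) condensed into uncertainty levels 0–6, RMSEP
aggregation for meta-models, and calibrated 95 % prediction
intervals `M ± 1.96·RMSEP_adj`.

## Worked example

A naphthalene-like solute (S = 0.92, A = 0, B = 0.2, V = 1.0854,
L = 5.16, melting at 353.4 K):

```r
library(pplferkit)
tab <- data.frame(id = "naphthalene_like", S = 0.92, A = 0, B = 0.2,
                  V = 1.0854, L = 5.16, Tm_K = 353.4, Tb_K = 491.1,
                  dSm_J_molK = 54.4, MV_L_mol = 0.125)
predict_batch(tab)
```

```
       endpoint    value rmsep pi_low pi_high state
1           KAW -1.97897  0.17 -2.395  -1.562 solid
2           KOA  5.16161  0.16  4.770   5.554 solid
3       KOW_wet  3.19221  0.15  2.825   3.560 solid
4       KOW_dry  3.18263  0.23  2.619   3.746 solid
5           KOO  0.00958  0.28 -0.676   0.696 solid
6     VP_liquid  1.53538  0.59 -0.879   3.949 solid
7     SW_liquid -2.79565  0.60 -4.633  -0.958 solid
8 SO_dry_liquid  0.38699  0.64 -1.181   1.955 solid
9 SO_wet_liquid  0.39657  0.62 -1.122   1.916 solid
```

Reading the output: the wet octanol–water partition ratio is
10^3.19 with a 95 % prediction interval of about ±0.37 log units
(the 0.15 log-unit equation error times the global 1.25 adjustment
times 1.96). The solute is classified solid at 25 °C, so VP and the
solubilities are supercooled-liquid values — the fate-modelling
convention; pass `pplfer_config(solid_output = "solid")` for
Van't Hoff-corrected solid-state values. K_OO ≈ 0 says wet and dry
octanol behave almost identically for this weakly hydrogen-bonding
solute, exactly as the cycle requires (K_OW wet − dry = 0.01).

The thermodynamic consistency of the bundled parameters can be
audited directly:

```r
aud <- check_cycle_consistency(pplfer_registry())
attr(aud, "pass")        # TRUE
max(aud$residual)        # 0
```

A command-line wrapper with `predict`, `audit-cycle`, `calibrate`,
`evaluate` and `simulate` subcommands is installed at
`system.file("cli", "pplferkit.R", package = "pplferkit")`.

## Layout

- `R/` — registry and types, PPLFER engine, thermodynamic cycles,
  state corrections, AD/uncertainty, evaluation statistics,
  synthetic fixtures, batch prediction, CLI.
- `inst/extdata/system_parameters.yaml` — the bundled nine-endpoint
  registry (versioned YAML; `read_registry()`/`write_registry()`
  round-trip it exactly).
- `vignettes/pplfer-methods.Rmd` — model assumptions, parameter
  meanings, numerical choices and limitations.
- `tests/testthat/` — unit, property and end-to-end suites.
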