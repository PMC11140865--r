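---
title: "PPLFER property prediction: models, uncertainty and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PPLFER property prediction: models, uncertainty and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pplferkit)
```

## The model

Poly-parameter linear free energy relationships (PPLFERs, also known
as Abraham solvation equations) predict how a neutral organic solute
distributes between phases from five solute descriptors: `S`
(dipolarity/polarizability), `A` (hydrogen-bond donor capacity), `B`
(hydrogen-bond acceptor capacity), `V` (McGowan characteristic volume,
conventional units of cm^3/mol divided by 100) and `L` (log
hexadecane–air partition coefficient). For a partition ratio between
two phases,

$$\log K = s\,S + a\,A + b\,B + v\,V + l\,L + c,$$

where the lower-case system parameters are calibrated per two-phase
system by multiple linear regression against solutes with
experimentally determined descriptors. For properties of the pure
solute phase — vapor pressure and solubility in water or octanol —
the solute acts as its own solvent, and an extra term captures
hydrogen bonding between molecules of the chemical itself:

$$\log S_{[W,O,A]} = s\,S + a\,A + b\,B + d\,\sqrt{A B} + v\,V +
l\,L + c.$$

Both forms share one evaluation path in this package; partition
endpoints simply carry $d = 0$.

The nine bundled endpoints (`pplfer_endpoints()`) are air–water, wet
and dry octanol–water, octanol–air, the hypothetical wet/dry octanol
ratio, and liquid-state vapor pressure and water/octanol
solubilities, all at 25 °C. Nothing in the package models temperature
dependence of the system parameters.

## Thermodynamic consistency: the three-solubility cycles

Interpreting $K_{OW}$, $K_{AW}$ and $K_{OA}$ as ratios of the
solubilities in octanol, water and air links the endpoints into
property cycles. Four system-parameter rows are *defined* by those
cycles rather than calibrated:

* dry $K_{OW}$ = $K_{OA}$ + $K_{AW}$ (coefficient-wise),
* $K_{OO}$ (wet/dry octanol) = wet $K_{OW}$ − dry $K_{OW}$,
* dry-octanol solubility = water solubility + dry $K_{OW}$,
* wet-octanol solubility = water solubility + wet $K_{OW}$.

Wet octanol (water-saturated, as in a shake-flask $K_{OW}$
measurement) and dry octanol (as in most $K_{OA}$ measurements) have
genuinely different solvent properties, which is why both rows exist
and why $K_{OO}$ is needed to move between them.

Standard errors propagate in quadrature for sums *and* differences
(independent errors accumulate identically in both), e.g. the dry
$K_{OW}$ total s.e. is $\sqrt{0.17^2 + 0.16^2} = 0.23$. Covariances
between calibrated equations are ignored; the registry stores values
at the printed 2-decimal precision, and `check_cycle_consistency()`
recomputes the derived rows at full float precision before comparing
half-even-rounded values, passing at residuals ≤ 0.005.

```{r cycles}
aud <- check_cycle_consistency(pplfer_registry())
attr(aud, "pass")
max(aud$residual)
```

One numerical subtlety is deliberate: the per-coefficient s.e. of the
$l$ coefficient of dry $K_{OW}$ propagates to 0.028, which rounds to
0.03; the registry stores the published 0.02. The audit therefore
compares coefficients and total s.e. values, which all close exactly,
and not per-coefficient standard errors.

## Vapor pressure routes and unit conversions

The direct route evaluates the calibrated VP equation. An indirect
route is also provided: per-solute system parameters for the
"air/own liquid phase" system (`kkak_parameters()`, coefficients
supplied by the caller from published empirical regressions — they
are inputs here, not refit) give $\log K_{kAk}$, which Raoult's law
converts to vapor pressure,

$$\log VP = \log_{10}\frac{RT}{\gamma\,K_{kAk}\,MV},$$

with the pure-phase activity coefficient $\gamma = 1$ by default and
the molar volume accepted in L/mol (converted internally; solubility
caps work in mol/L). The indirect route is only trustworthy for
liquids, so calling it with a (maybe-)solid state attaches a warning.
`vp_to_sa()` converts to solubility in air by the ideal gas law,
$\log S_A = \log VP - \log_{10}(1000\,RT)$. No identity is asserted
between the VP and $S_W$ intercepts via $S_A$: both equations were
calibrated on experimental data independently and differ by a small
constant that is not recoverable from the printed coefficients.

## Physical state and the Van't Hoff correction

Fate and transport models treat all chemicals as (supercooled)
liquids, while measurements for solids are made on the solid. The
package classifies state at system temperature with a transparent
threshold rule: gas if $T_B \le T$; solid if $T_M \ge T + m$;
`maybe_solid` if $|T_M - T| < m$; liquid if $T_M \le T - m$ and
$T_B > T$; `unknown` whenever the needed inputs are missing. The
band half-width $m$ defaults to 10 K and is configuration
(`state_margin_K`), reflecting that melting-point inputs are
themselves often predicted; the rule deliberately stands in for an
opaque trained classifier, trading a little accuracy for total
auditability. Solid-state adjustment factors key on both `solid` and
`maybe_solid`.

Solid and supercooled-liquid values are related by the Van't Hoff
(Walden) approximation,

$$\log_{10} X_{solid} - \log_{10} X_{liquid} =
  -\frac{\Delta S_M (T_M - T)}{\ln(10)\,R\,T}, \qquad T_M > T,$$

an exact inverse pair in both directions. When the entropy of fusion
is unavailable, Walden's rule (56.5 J mol⁻¹ K⁻¹) is substituted and
the prediction flagged `default_dS_M`. The default batch output mode
is `supercooled`, the modelling convention; `solid` output applies
the correction for solutes classified (maybe) solid.

Two physical upper bounds are enforced after prediction: solubility
cannot exceed the concentration of the pure liquid solute,
$\log_{10}(1/MV)$, and vapor pressure cannot exceed atmospheric
pressure ($\log_{10} 101325 \approx 5.006$). Capped predictions keep
the RMSEP of their pre-cap uncertainty level, move to UL 6 and are
flagged. When no molar volume is supplied, an optional fallback
$MV \approx 0.127\,V$ L/mol (organic liquids run about 1.27× the
McGowan characteristic volume) can be enabled; it is always flagged.

## Applicability domain and uncertainty levels

Three complementary AD diagnostics feed an ordinal uncertainty level:

| UL | meaning |
|----|---------|
| 0 | in domain, no warnings |
| 1 | in domain, borderline leverage/similarity warning |
| 2 | out of domain, leverage/similarity warning |
| 3 | out of domain, egregious extrapolation by leverage |
| 4 | intercept-only prediction (all fragment counts zero) |
| 5 | uncalibrated atom/bond types present |
| 6 | boundary-cap violation (assigned by `apply_caps()`, never by `assign_ul()`) |

Leverage is the classic hat-matrix extrapolation measure
$h = x^\top (X^\top X)^{-1} x$ (pseudo-inverse fallback for singular
designs). The chemical similarity score is the mean Tanimoto
similarity of the $k$ nearest training count-vectors (cosine
selectable). The cut-offs — 1.5, 3 and 10 times the mean training
leverage $p/n$, and similarity 0.5 / 0.25 — live in `ad_context()`
as configuration: the UL scheme itself is principled, but these
particular numbers are documented defaults, not fitted quantities,
and users with a real training design should tune them.

Property models are meta-models: their inputs (predicted descriptors,
calibrated system parameters) each carry uncertainty.
`aggregate_meta()` combines RMSEPs by propagation of uncertainty
(root-sum-of-squares) and takes the maximum component UL; whether a
UL 4 component counts as in-domain depends on what the intercept
means for the endpoint, so it is remappable per call (`ul4_as`,
default: kept at 4).

## Prediction intervals and their calibration

The 95 % prediction interval is $M \pm 1.96 \cdot RMSEP_{adj}$.
Because validation sets under-represent truly novel chemicals, the
estimated RMSEP is widened by an empirical adjustment ladder before
the interval is formed: ×1.25 globally; a further ×1.67 (VP) or
×1.25 ($S_W$) for solutes classified (maybe) solid; and a further
×1.25 for VP at UL 2, 3 or 5. All factors are configuration
(`pi_adjustments()`) and only ever widen.

`calibrate_adjustments()` recovers such factors from data: per
stratum it walks the geometric ladder $1, 1.25, 1.25^2, \dots$ until
the closed-interval coverage reaches the target (95 % by default).
Closed intervals — the boundary counts as inside — is a fixed,
documented choice; ties are measure-zero on real data but the rule
must be deterministic. The package's own calibration check constructs
a stratum whose true spread is exactly 1.25× the estimated RMSEP
using plug-in normal quantiles rather than random draws: the
construction is then deterministic, the recovered factor is exactly
1.25, and post-adjustment coverage is exactly 95.0 %.

Validation statistics use the divide-by-$n$ RMSEP (not $n-p$), and
UL 6 records are evaluated with the RMSEP of their pre-cap UL.
Records of strong acids (pKa < 4) and strong bases (pKa > 10) are
removed before evaluation — their measured values are distribution
ratios of an ion mixture, not the neutral-species property; both
inequalities are strict, so pKa exactly 4 or 10 is kept.

## Synthetic data: what it does and does not emulate

All tests run on generated fixtures. `generate_solutes()` draws
descriptor populations spanning typical neutral organics:
$V \sim U(0.3, 4.0)$ (the upper end covering very large, complex
chemicals), $L = 3.5V + N(0, 0.8)$ (the strong size–dispersion
correlation of real solutes), $S \sim U(0, 2.5)$, and truncated
exponentials for $A$ (mean 0.25, cap 1.5) and $B$ (mean 0.45, cap
2.5) — most organics donate few hydrogen bonds, fewer accept many.
Boiling points rise with volume, melting points sit 80–250 K below
them, entropies of fusion scatter around Walden's rule, and molar
volumes follow $0.127\,V$ with 10 % noise. All generators are pure
functions of their parameters and seed, and restore the caller's RNG
state.

What the fixtures do *not* emulate: the discrete functional-group
structure of real chemical space, correlated descriptor errors from
upstream structure-based predictions, measurement error heterogeneity
across laboratories, and polymorphism of solids. Passing tests
therefore demonstrate that the machinery is correct — equations,
cycles, error propagation, coverage logic — not that any particular
empirical RMSEP will be achieved on real data; empirical validation
requires real property datasets, which are intentionally outside this
package.

Calibration recovery runs at $n = 500$ solutes with 0.2 log-unit
noise per endpoint, and coverage checks at $n = 2000$ records per
stratum — sizes at which sampling error in the recovered
coefficients (a few hundredths of a log unit) and in coverage
(±0.5 %) is small relative to the decision thresholds, while the
whole suite runs in seconds.

## Degenerate inputs and numerical choices

* Rank-deficient calibration designs error naming the collinear
  columns; so do tables with fewer rows than coefficients.
* `classify_state()` is total: no combination of present/missing
  inputs raises; the answer degrades to `unknown`.
* Descriptor validation at the constructors enforces $V > 0$; the
  evaluator itself only needs finiteness and $A, B \ge 0$ (so the
  interaction-free $V = 0$ limit can be probed).
* Tanimoto similarity of two all-zero count vectors is defined as 1
  (identical), and 0 against any non-zero vector.
* Cycle comparisons round half-even (base `round`) to 2 decimals,
  matching how the registry values are printed.
* An RMSEP of exactly 0 yields a degenerate zero-width interval
  rather than an error.

## Known limitations

Solute descriptors are inputs: the package does not predict them from
structure (SMILES strings pass through as opaque text). The ~100
published solvent systems beyond these nine endpoints, ionic-species
partitioning, temperature dependence, and PPLFER-extrapolation
interval terms are out of scope. The state classifier is a
threshold rule, not a trained model; with predicted melting points
its `maybe_solid` band should be widened.
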