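# pbrgrowth

Batch growth-kinetics analysis for lab-scale bubble-column photobioreactors
(PBRs) run under atmospheric CO2 — the regime where microalgal cultures such
as *Chlorella vulgaris* grow **linearly** from inoculation (carbon/light
limitation) and then saturate, instead of showing the exponential start that
classical sigmoid models assume. The package is aimed at bioprocess
scientists who want to compare growth-model families on OD-derived biomass
curves and quantify how aeration intensity and temperature shape early
growth.

## What it computes

**Preprocessing.** Optical density is converted to biomass concentration by
the empirical calibration `X = OD750 · k_cal · n` (default `k_cal = 0.4`
g/L per OD unit, dilution factor `n`, linear range 0.3–0.6), and measured
concentrations are corrected for evaporation/top-ups by a volume ledger:
`X_corr(t) = X_meas(t) · V(t) / V_nom`.

**Six growth formulations** (all returning g/L, rates in h⁻¹, time in h):

- logistic: `X(t) = K / (1 + ((K − X₀)/X₀) e^(−μt))`
- logistic with lag: same, clock shifted by `t_lag`, `X = X₀` before it
- modified Gompertz (Zwietering):
  `X(t) = X_max · exp(−exp((μ_max e / X_max)(λ − t) + 1))`
- Baranyi–Roberts: adjustment function `A(t)` with asymptote `C` of
  `ln(X/X₀)`, returned as concentration `X₀·e^y` (log-sum-exp stable)
- **hybrid two-phase**: `X = X₀ + a·t` for `t < t_s`, then a logistic branch
  continuous at the stitch time `t_s`
- **Monod × Gauss** rate surface:
  `μ(T, B) = μ_max · B/(K_B + B) · exp(−(T − T_opt)²/(2σ²))`
  with aeration `B` in vvm (= L/min air ÷ L culture)

**Estimation.** Bounded multi-start nonlinear least squares
(L-BFGS-B + a projected Levenberg–Marquardt polish), goodness of fit by
R² and RMSE, and a per-reactor model-comparison table. A change-point
procedure locates `t_s`: OLS on the first 92 h, extrapolation, and the
first sample whose absolute deviation exceeds the within-window
mean + 2 SD. The aeration–temperature analysis regresses early-phase
slopes (OLS over 0–100 h) on `(T, B)` with the Monod × Gauss surface.

**Synthetic campaigns.** A seeded generator emulates an 8-reactor,
700 h campaign (aeration ladder 0.25–3.25 vvm, inoculum 0.33 g/L, no lag,
capacity plateau above ~1.3 vvm, 24.5–28.5 °C, evaporation + top-ups,
multiplicative 2% observation noise), so the entire pipeline is testable
without any external data and every truth parameter is recoverable.

## Worked example

```r
library(pbrgrowth)
sc     <- campaign_scenario()                  # stated 8-reactor world
series <- generate_campaign(sc, seed = 42)
s5     <- apply_volume_correction(series[["PBR5"]],
                                  evaporation_rate_mL_per_h = 1.2)
fit_model(s5, "hybrid_two_phase")
#> <growth_fit> hybrid_two_phase on 'PBR5' (n = 15)
#>       estimate  unit
#> X0  3.3006e-01   g/L
#> a   7.7993e-03 g/L/h
#> t_s 1.5803e+02     h
#> K   3.8698e+00   g/L
#> r   6.9620e-03   1/h
#> R2 = 0.9981, RMSE = 0.05355 g/L, Xmax = 3.87 g/L

pts <- surface_points(series, sc$reactors)     # (T, B, slope) per reactor
fit_surface(pts)
#> <surface_fit> Monod x Gauss on 8 points
#>        estimate std_error  unit flag
#> mumax  0.013837  0.000967 g/L/h
#> KB     0.469600  0.051000   vvm
#> Topt  24.851000  1.490000  degC
#> sigma  4.843400  1.820000  degC
#> R2 = 0.9895, RMSE = 0.0002197 g/L/h
#> Warning: estimated sigma (4.84 degC) exceeds the observed temperature
#> span (2.88 degC); thermal parameters are weakly identified
```

Reading the output: the reactor at 1.38 vvm grew linearly at
~0.0078 g/L/h until ~160 h and saturated near 3.9 g/L with R² = 0.998;
across reactors the aeration half-saturation is ~0.47 vvm (rates plateau
above ~1.3 vvm), while the thermal optimum and window are *weakly
identified* from a 2.9 °C span — the warning is the designed behaviour,
not an error.

The full pipeline (volume correction → transition detection → five-model
comparison → surface fit, with CSV/JSON artifacts and a run log):

```r
res <- run_pipeline(run_config(out_dir = "pbr_out", seed = 1))
read.csv(res$paths$comparison)
```

A command-line front-end with `simulate`, `detect`, `fit`, `compare`,
`surface` and `run-all` subcommands lives at
`inst/cli/pbr-pipeline.R` (after install:
`Rscript $(Rscript -e 'cat(system.file("cli/pbr-pipeline.R", package="pbrgrowth"))') run-all --seed 1`).

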