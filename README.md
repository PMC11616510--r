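# mdtreat

Reactive-transport modelling, inverse calibration and retention-time
optimisation for passive treatment of Mn- and Zn-rich mine drainage in a
limestone bioreactor.

Passive treatment columns remove dissolved Mn²⁺ through bacterially catalysed
oxidation to birnessite (MnO₂) at circumneutral pH, and dissolved Zn²⁺ by
sorption onto that growing birnessite coating. `mdtreat` is aimed at
environmental engineers and geochemists who monitor such systems: it turns
routine inlet/outlet concentration series into kinetic parameters and design
numbers (the minimum hydraulic retention time, HRT, that meets effluent
limits) without bench sorption experiments.

## The model

A 1D cells-in-series column (default: 1.6 m path, 16 cells, porosity 0.48,
pure advection with opt-in dispersivity) with two kinetic processes:

* Mn(II) oxidation, pseudo-first-order:
  `R_Mn = −d[Mn²⁺]/dt = k₁[Mn²⁺]` (an autocatalytic term `k₂[MnOx][Mn²⁺]`
  exists but is off by default);
* Zn(II) linear-driving-force sorption on the birnessite inventory:
  `R_Zn = k_m (c_Zn − s_Zn/K_d)`, with the sorbent mass per litre of pore
  water growing by one mole of MnO₂ (86.94 g/mol) per mole of Mn oxidised.

The three parameters (k₁, k_m, K_d) are estimated by Levenberg–Marquardt
weighted least squares in log₁₀ space against observed outlet series;
goodness of fit is scored with MAE, RMSE, range-normalised NRMSE and the
Nash–Sutcliffe coefficient of efficiency R². A synthetic campaign generator
with known ground truth, a steady-state HRT optimiser and an XANES
linear-combination fitter (non-negative, sum-to-one least squares) round out
the toolkit. See `vignette("passive-treatment-model")` for the science and
the numerical scheme.

## Worked example

```r
library(mdtreat)

cfg  <- reactor_config()                       # the pilot column
camp <- generate_campaign(campaign_spec(seed = 1))  # 152-day synthetic season
ds   <- campaign_fit_dataset(camp)

fit_mn <- fit_kinetics(kinetic_params(k1 = 1e-5), ds, cfg, "mn")
fit_zn <- fit_kinetics(fit_mn$params, ds, cfg, "zn")
fit_mn$params$k1
#> [1] 0.0001025125
fit_zn$params$kd
#> [1] 4.409975

a0 <- campaign_station(camp, "A0"); a1 <- campaign_station(camp, "A1")
removal_efficiency(a0, a1, "hrt0.5d", "mn")
#> [1] 98.84112

min_hrt_for_limit(cfg, fit_mn$params, c_in = 25, limit = 10, "mn")
#> [1] 0.1034595
```

Read: from a noisy synthetic season generated with k₁ = 1.03e-4 s⁻¹ and
K_d = 4.49 L/g, the inverse model recovers k₁ within ~0.5 % and K_d within
~2 %; Mn removal across the column in the 0.5-day-HRT regime is ~99 %; and
holding the Mn effluent limit of 10 mg/L at a 25 mg/L feed requires an HRT of
at least ~0.103 days (the plug-flow value ln(2.5)/k₁; dispersivity of 0.2 m
raises it to ~0.114 days).

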