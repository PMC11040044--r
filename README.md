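# maizecast

Process-based simulation and per-window regression forecasting of Brazilian
off-season (safrinha) maize yield.

The off-season crop — sown January–April after soybean — supplies about 80%
of Brazil's maize, and a skillful in-season forecast of the national yield
matters to anyone exposed to that supply chain.  `maizecast` implements a
desk-scale version of the operational approach used for this problem:

1. **A daily crop growth simulator.**  Phenology is a continuous
   development index (DVI: −1 sowing, 0 emergence, 1 start of reproduction,
   2 maturity/harvest) driven by thermal time with a trapezoidal
   temperature response (T_b, T_o, T_m) and a photoperiod multiplier
   RPE = 1 − (P − P_crit)/P_sens.  Canopy carbon gain
   (RUE × intercepted PAR × stress) is partitioned among leaf, stem,
   grain and root pools by a softmax of DVI,
   p_i = exp(α_i + β_i·DVI) / Σ_j exp(α_j + β_j·DVI),
   with stem-reserve remobilization into grain, threshold leaf senescence
   μ(DVI − DVI_sen)^ν, allometric SLA/LAI and height, and a layered
   tipping-bucket soil water balance supplying the stress factor FSMC and
   root-zone water content SWC.  Runs at potential (Yp) and water-limited
   (Yw) production levels.
2. **10-day forecasting-window indicators.**  Model outputs (LDM, SDM,
   GDM, CH, LAI; FSMC and SWC for Yw) read on each window day, and
   agrometeorological indicators accumulated from sowing: mean temperature
   TMED, accumulated rainfall RAIN, and mean diffuse radiation DIFF_RAD
   (two-band visible/NIR potential-radiation partitioning).
3. **Area-weighted aggregation** of per-soil and per-zone values to a
   national series.
4. **A forecasting engine**: OLS detrending of the yield series, then per
   window a bidirectional stepwise regression (α = 0.05 entry/removal,
   VIF ≤ 5), Durbin–Watson screening against tabulated 5% bounds,
   leave-one-out cross-validation, and R², Willmott's d, Nash–Sutcliffe EF
   and SDEP on the cross-validated predictions.

A synthetic multi-zone study generator with known ground truth
(`generate_study()`) makes every stage testable with no external data.

## Worked example

Simulate one water-limited season on the bundled synthetic weather:

```r
library(maizecast)
wx <- read_weather(system.file("extdata", "weather_synthetic_2003.csv",
                               package = "maizecast"))
params <- read_crop_params(system.file("extdata", "maize_default.yaml",
                                       package = "maizecast"))
season <- run_season(wx, as.Date("2003-02-01"), params, soil_profile(),
                     mode = "water_limited")
season
#> Maize season simulation (water_limited mode)
#>   sowing 2003-02-01, 100 simulated day(s)
#>   maturity (DVI = 2) at 100 days after sowing
#>   grain dry mass at harvest: 6.81 Mg ha-1
#>   peak LAI 3.49, final height 1.74 m, final FSMC 0.65
```

The crop matures (DVI = 2) 100 days after sowing with a water-limited grain
yield of 6.8 Mg ha⁻¹; the end-of-season stress factor of 0.65 reflects the
characteristic off-season dry-down.

Generate a full synthetic study (4 zones × 14 years) and fit the
per-window forecasting models:

```r
study <- generate_study(seed = 1)
fit <- yield_forecast(study$indicators, study$yields)
summary(fit)
#>  window n_selected    r2     d     ef vif_max    dw dw_decision p_value  sdep     regressors
#>      10          0 1.000 0.000 -0.160      NA    NA        <NA>      NA 1.194
#>      20          1 0.172 0.579  0.144   1.000 2.575    accepted   0.040 1.026           TMED
#>      30          0 1.000 0.000 -0.160      NA    NA        <NA>      NA 1.194
#>      40          0 1.000 0.000 -0.160      NA    NA        <NA>      NA 1.194
#>      50          0 1.000 0.000 -0.160      NA    NA        <NA>      NA 1.194
#>      60          1 0.210 0.610  0.183   1.000 2.237    accepted   0.027 1.003           RAIN
#>      70          1 0.198 0.609  0.169   1.000 2.017    accepted   0.027 1.011           RAIN
#>      80          2 0.580 0.864  0.562   1.041 2.033    accepted   0.000 0.734 GDM_Yw+FSMC_Yw
#>      90          1 0.587 0.864  0.581   1.000 1.756    accepted   0.000 0.718         GDM_Yw
#>     100          1 0.737 0.921  0.737   1.000 2.323    accepted   0.000 0.569         GDM_Yw
#>     110          2 0.861 0.963  0.853   2.028 2.632    accepted   0.000 0.425  GDM_Yw+SWC_Yw
#>     120          2 0.879 0.968  0.878   1.023 2.245    accepted   0.000 0.387    GDM_Yw+TMED
```

Forecast skill is flat and poor through the vegetative windows, then rises
steeply once grain filling starts: the cross-validated Nash–Sutcliffe
efficiency climbs from ≈0.14 (day 20) to 0.88 at maturation while the
prediction error (SDEP) falls from 1.19 to 0.39 Mg ha⁻¹, with rainfall
selected in mid-season windows and water-limited grain dry mass dominating
from day 80 — the qualitative signature the synthetic ground truth is
built to produce.  Every selected model keeps VIF well under 5 and a
Durbin–Watson decision of "accepted" (no residual autocorrelation).

`predict(fit, window = 120)` returns the re-trended yield forecasts;
`plot(fit, "selection")` draws the window × regressor selection heatmap;
and

```r
cg <- compare_groups(study$indicators, study$yields)
round(tapply(cg$sdep, cg$config, mean), 2)
#>       agromet     potential water_limited    wl_agromet
#>          1.03          1.09          0.93          0.89
```

shows that combining water-limited model outputs with agrometeorological
indicators gives the lowest mean prediction error of the four regressor
groups.

A thin command-line wrapper is installed at
`system.file("cli", "maizecast", package = "maizecast")` with subcommands
`synth`, `simulate`, `forecast`, `evaluate` and `show-config`.

See `vignettes/maizecast-methods.Rmd` for the model equations, parameter
meanings, numerical choices and the design of the synthetic experiments.

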