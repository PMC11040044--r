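---
title: "Methods: the maizecast growth simulator and forecasting engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the maizecast growth simulator and forecasting engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizecast)
```

maizecast forecasts the national yield of the Brazilian off-season
(safrinha) maize crop from two ingredients: a desk-scale process-based
growth simulator run at potential and water-limited production levels, and
per-window multiple regressions that relate simulated model outputs plus
agrometeorological indicators to the detrended official yield series.  This
vignette is the package's own account of the model, the choices that were
genuinely open, and what the bundled synthetic experiments do and do not
demonstrate.

## The crop growth model

### Development index and thermal time

Crop phenology is tracked by a continuous development index (DVI): -2
before sowing, -1 at sowing, 0 at emergence, 1 at the start of the
reproductive stage and 2 at physiological maturity, which triggers harvest.
Development advances with the daily effective temperature
(`effective_temperature()`), a trapezoidal response with cardinal
temperatures $T_b < T_o < T_m$:

$$T_{eff}(T)=\begin{cases}0 & T<T_b\\ T-T_b & T_b\le T\le T_o\\
(T_o-T_b)\left(1-\frac{T-T_o}{T_m-T_o}\right) & T_o<T<T_m\\ 0 & T\ge T_m
\end{cases}$$

The daily DVI rate divides $T_{eff}$ by the phase thermal-time requirement
(`TTemr`, `TTveg`, `TTrep`); during the vegetative phase it is additionally
multiplied by the relative photoperiod effect
$RPE = 1-(P-P_{crit})/P_{sens}$, clamped to $[0,1]$.  The clamping, and the
application of RPE to the vegetative branch only, are deliberate: the
printed linear form can exceed 1 or go negative for photoperiods on the
other side of the critical value, and the sign convention for a short-day
crop is ambiguous in the source literature; we take the linear form
literally and bound it.  With the default `Psens = 100` h the off-season
penalty at tropical latitudes is negligible (&lt; 0.5%), which is the
intended behaviour for the cultivars emulated here.

**Numerical choice.**  The DVI is integrated with a phase-boundary-aware
daily step (`advance_dvi()`): when one day's thermal time would cross a
stage boundary, the remainder of the day is consumed at the next phase's
rate.  Each phase therefore consumes exactly its thermal-time requirement
-- a constant-temperature season with requirements of 10, 50 and 50
day-equivalents matures on day 110 exactly -- instead of overshooting each
boundary by up to one daily Euler step.  DVI = 2 is absorbing.

### Carbon partitioning, senescence and allometry

Daily canopy carbon gain is allocated among leaf, stem, harvest (grain) and
root pools by a softmax of DVI,

$$p_i = \frac{e^{\alpha_i+\beta_i\,DVI}}{\sum_j e^{\alpha_j+\beta_j\,DVI}},$$

computed with max-subtraction so extreme constants cannot overflow; the
fractions sum to 1 to machine precision by construction.  The stem share is
split between structure and a remobilizable reserve (`reserve_frac`,
default 0.2); from DVI = 1 the reserve drains into the harvest pool at
`remob_rate` (default 0.05 d$^{-1}$).  The source material states that stem
remobilization to reproductive structures occurs but not its rate; both
knobs are exposed as parameters.  At emergence (DVI crossing 0) the pools
are seeded with `initial_carbon` split by the partition fractions at
DVI = 0.

Leaf senescence starts above the threshold `DVIsen` (default 0.4) as
$\mu(DVI-DVIsen)^{\nu}$ per day, capped at 1, and is treated as a litter
loss (not re-allocated).  Specific leaf area follows
$SLA=\gamma(DVI+0.06)^{\delta}$; green leaf area index is
$LAI = (C_{leaf}/f_{c,leaf})\,SLA$; crop height is
$h = k_h (C_{stem}/f_{c,stem})^{\lambda_h}$ with the stem pool taken as
structure plus reserve (the carbon fraction of stem dry mass is defined
including the reserve, so the height allometry uses the same aggregate).
Dry masses are reported as $\mathrm{Mg\,ha^{-1}} = 10\,C/f_c$.

### Canopy carbon gain

The daily carbon source is a radiation-use-efficiency canopy model:

$$NPP = rue \cdot 0.5\,S \cdot (1-e^{-k\,LAI}) \cdot s,$$

with $S$ the daily global shortwave (half of it PAR), Beer-law interception
with extinction coefficient $k$, and $s$ the soil-moisture stress factor in
water-limited mode ($s = 1$ in potential mode).  This compact source model
is monotone in the same drivers as a full leaf-level photosynthesis scheme
and keeps the simulator self-contained; the default
`rue` = 1.3 g C MJ$^{-1}$ PAR (about 2.9 g dry mass MJ$^{-1}$ at 45%
carbon) produces realistic off-season canopies and yields under the default
climate: peak LAI 3-4 and water-limited grain dry mass of 6-8 Mg ha$^{-1}$.  Potential-mode production consequently dominates
water-limited production for identical forcing, a property the tests check.

### Soil water

The soil is a stack of 10-cm tipping-bucket layers over the 60-cm effective
maize root zone.  Rain fills layers to their critical ("no stress")
moisture from the top, the excess cascades downward and leaves the bottom
as drainage.  The stress factor FSMC is the root-zone depth-weighted mean
of the per-layer linear ramp $(\theta-\theta_{wilt})/(\theta_{fc}-
\theta_{wilt})$ clamped to $[0,1]$; a linear ramp is used because only the
endpoints (0 = extreme drought, 1 = no stress) are specified by the
indicator definitions.  Crop uptake is an unstressed radiation-driven
demand scaled by FSMC and extracted in proportion to layer availability,
never below wilting.  SWC is the depth-weighted mean water content of the
top 60 cm with residual moisture taken as zero.  The daily water ledger
(rain - drainage - uptake = storage change) closes exactly by construction
and is asserted to 10$^{-9}$ mm in the tests, as is the carbon ledger
(gain + emergence seeding - senescence = pool change) to 10$^{-9}$
kg C m$^{-2}$.

The update order within a day is: soil water (demand from yesterday's
canopy), thermal time, photoperiod, DVI, emergence initialization, carbon
gain, allocation, remobilization, senescence, allometry.

## Forecasting-window indicators

Every 10 days after sowing up to day 120 the package assembles, per
production level:

* model outputs read as point-in-time state on the window day: leaf, stalk
  and grain dry mass, crop height and LAI (both levels), plus FSMC and SWC
  (water-limited level only, where they are informative);
* agrometeorological indicators accumulated from sowing to the window day
  (inclusive; day 1 is the day after sowing): mean daily temperature TMED,
  accumulated rainfall RAIN, and mean daily diffuse radiation DIFF_RAD.

Diffuse radiation is computed by the classic two-band potential-radiation
method: clear-sky direct and diffuse components of the visible and
near-infrared bands are integrated over the day from solar geometry and
pressure-corrected air mass, and the measured-to-potential ratio drives an
empirical cloudiness reduction of each band's direct share.  DIFF_RAD is
reported as mean diffuse *energy* (MJ m$^{-2}$ d$^{-1}$), matching the
indicator's stated units, rather than as a mean diffuse fraction.  Pressure
defaults to the standard atmosphere at 500 m elevation when no measurement
is available.

Seasons that mature before day 120 carry their harvest-day state forward
unchanged so late windows stay defined; this mirrors operational practice
where a harvested crop's final state is what a forecaster would use.

## Aggregation

Two weighted means lift county/zone simulations to the national scale:
within a zone, per-soil-class runs are weighted by the areal share of each
dominant soil class (shares renormalized); across zones, annual values are
weighted by the zone's cultivated off-season area in that year.  The
national value is therefore convex in the zone values and invariant to
rescaling all areas, both asserted as properties.  When each zone is
represented by one county the county-to-zone step collapses to the
identity, but the two-step API is kept for generality.

## The statistical engine

* **Detrending.**  Technological trend is removed by OLS of yield on
  calendar year; the detrended series is residual + mean, and forecasts are
  re-trended by adding the fitted trend at the target year.  The linear
  form is isolated behind one operation (`detrend_yields()`) so an
  alternative detrender can be swapped in.  Note that only the yields are
  detrended: a chance correlation between an indicator and the year axis
  then shifts the estimated coefficients by a few percent even in the
  noiseless limit, which the tests document explicitly.
* **Stepwise selection.**  Bidirectional, with entry and removal thresholds
  of 0.05 on classical partial t-tests (equivalent to partial F), matching
  the 5% significance language of the application this package supports.  A
  candidate may enter only if every variance inflation factor of the
  resulting model stays at or below 5.  Ties on p-value break by larger
  absolute partial correlation, then lexicographic name, making the
  procedure invariant to candidate column order.  Entry requires a strict
  SSE reduction and a cycling guard caps the loop, so termination is
  guaranteed.  If nothing clears the entry threshold an intercept-only
  model is returned and flagged.
* **Collinearity.**  $VIF_i = 1/(1-R^2_i)$ with $R^2_i$ from regressing
  column $i$ on the remaining columns with intercept; exact collinearity
  reports `Inf` with the offending columns named.
* **Autocorrelation.**  The Durbin-Watson statistic
  $\sum_{t\ge2}(e_t-e_{t-1})^2/\sum_t e_t^2$ on the in-sample residuals in
  year order, compared against embedded 5% lower/upper critical bounds
  ($n$ 6-30, $k$ 1-5): accepted above $d_U$, rejected below $d_L$,
  inconclusive between.  Uncovered $(n,k)$ pairs raise an explicit error
  rather than extrapolating.
* **Cross-validation.**  Leave-one-out with the selected regressor set held
  fixed across folds (per-fold re-selection is available behind a flag;
  the fixed-set default matches the single per-window selection narrative
  of the workflow this package operationalizes).  SDEP is the root mean
  square of the LOO prediction errors with denominator $n$.
* **Goodness of fit.**  $R^2$ (squared Pearson correlation), Willmott's
  original bounded index of agreement $d$, and Nash-Sutcliffe efficiency
  EF, all evaluated on the cross-validated predictions.  The bounded 1981
  form of $d$ was chosen over the 2012 refined index because the bounded
  form is what the reported diagnostic patterns in comparable forecasting
  studies reflect; the identity
  $EF_{loo} = 1 - n\,SDEP^2/\sum(o-\bar o)^2$ holds exactly and is tested.
  The per-window "model p-value" is the overall-F p-value of the selected
  model, the standard single-number summary (the worst partial t-test is
  retained per regressor in the fitted object, so either reading is
  available).  For an intercept-only window the LOO predictions are fold
  means; their $R^2$ against the observations is a degenerate quantity
  (fold means anti-correlate perfectly with the held-out values), so EF
  and SDEP are the meaningful columns there.

`yield_forecast()` ties these together: detrend once, then per window
select, cross-validate, score and screen; the result carries a diagnostics
table (window by EF/d/R$^2$/VIF/DW/p/SDEP), a binary window-by-regressor
selection map, and per-window model objects, with `print`, `summary`,
`coef`, `predict`, `residuals` and `plot` methods.  `compare_groups()`
refits under different regressor-group configurations (water-limited,
agromet, potential, water-limited + agromet) and collects the SDEP and EF
curves.

## The synthetic study generator

`generate_study()` makes the whole pipeline testable offline.  Its defaults
describe the study conditions the package is designed around: 14 years, 12
forecasting windows (day 10 to 120), and 4 climate zones spread over
latitudes -12 to -23 (4 rather than 16 zones keeps a full study generation
near 10 s on one CPU without changing any statistical property of the
national series).  Per zone-year, weather is drawn as a seasonal
temperature sinusoid plus AR(1) noise plus a year-level anomaly
(s.d. 0.6 degC, an ENSO-like warm/cool year effect), Bernoulli-gamma
rainfall whose wet-day probability decays exponentially after day 60
(the characteristic off-season dry-down toward the reproductive stage),
and shortwave radiation as a cloud-reduced fraction of the
extraterrestrial total.  The simulator is run once per zone-year in
potential mode and once per dominant soil class (clayey/sandy, shares
0.65/0.35) in water-limited mode.

Synthetic "official" yields are
$$y_t = 5.5 + 0.05\,(t-t_0) + 0.009\,(RAIN_{120,t}-\overline{RAIN}) +
1.2\,(GDM^{Yw}_{120,t}-\overline{GDM}) + \varepsilon_t,\qquad
\varepsilon_t\sim N(0, 0.4^2).$$

The truth deliberately spans both indicator families -- accumulated
rainfall (the dominant agrometeorological driver of off-season maize) and
water-limited grain dry mass (a model output that integrates rain timing,
temperature and radiation) -- so that the qualitative structure of the
application holds *by construction*: forecast skill must rise toward
maturation (early-window indicators are only partial proxies of their
final values), and adding water-limited outputs to the agromet group must
reduce SDEP.  The coefficients were calibrated once against the default
climate so the true model explains roughly 80% of inter-annual yield
variance (signal s.d. about 0.8 Mg ha$^{-1}$ against noise 0.4), the
signal-to-noise regime the package's recovery experiments are specified
at, and then frozen.

**Replicate design.**  The recovery, cross-validation calibration and
structure experiments hold one generated study's weather and indicators
fixed and redraw the yield noise per replicate (`draw_yields()`).  The
statistical questions concern selection and prediction given the noise, so
conditioning on one realized climate is the appropriate (and fast) design;
regenerating hundreds of multi-zone climates would only add Monte-Carlo
variance to the quantity under test.

**What the generator does not emulate** -- and hence what passing tests do
not show: no spatial correlation of weather across zones, no reanalysis
data statistics, no cultivar differences between zones, no pest/management
shocks, and no reproduction of official yield statistics, which would
require external data.  Passing the synthetic experiments demonstrates
that the machinery is correct and that the workflow's qualitative findings
follow from its stated mechanism, not that the bundled defaults are
calibrated to any particular real region.

## Degenerate inputs and edge policies

Constant indicator columns (e.g. grain dry mass before grain filling) are
dropped from a window's candidate set and recorded.  Singular LOO folds are
excluded and counted.  All-zero residual vectors make the DW statistic
undefined and raise an error, as do constant observations in the
goodness-of-fit suite and all-zero soil shares.  Seasons that fail to reach
DVI = 2 within the horizon are flagged incomplete with `harvest_day = NA`
and report the final-day grain mass.  Polar latitudes are rejected by the
solar geometry.  Early-harvest triggers (excessive LAI, cold soil, etc.)
are intentionally not implemented.

## Known limitations

The carbon source is a one-parameter RUE model, not a leaf-level
photosynthesis scheme; no energy balance, no CO$_2$ response, no hourly
radiation transfer.  The soil bucket has no upward flow or water table.
The embedded Durbin-Watson bounds cover $n$ 6-30 and $k$ 1-5 at the 5%
level only.  Detrending is linear in year.  National aggregation assumes
one representative simulation per zone-soil combination.  These boundaries
match the operational forecasting use the package targets.
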