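# Synthetic multi-zone study generator with known ground truth.

# run code under a seeded, restored RNG stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Climate specification for the weather generator
#'
#' Describes one climate zone of a tropical off-season: a mild seasonal
#' temperature cycle with AR(1) day-to-day noise, Bernoulli-gamma rainfall
#' whose wet-day probability decays exponentially after the onset of the
#' dry-down (emulating rainfall declining toward the reproductive stage),
#' and shortwave radiation anticorrelated with rain occurrence.
#'
#' @param latitude Zone latitude [decimal degrees].
#' @param t_mean Annual-mean air temperature [degC].
#' @param t_amp Seasonal temperature amplitude [degC].
#' @param t_ar,t_sd AR(1) coefficient and innovation s.d. of the daily
#'   temperature noise.
#' @param year_t_sd S.d. of the year-level temperature anomaly [degC]
#'   (warm/cool years).
#' @param wet_prob Wet-day probability during the wet season.
#' @param rain_mm Mean wet-day rainfall [mm d-1] (gamma distributed).
#' @param rain_shape Gamma shape of wet-day rainfall.
#' @param decay Exponential decay rate of the wet-day probability [d-1]
#'   after `decay_start`.
#' @param decay_start Day of the season after which rainfall declines.
#' @param clear_frac Clear-sky transmission of the atmosphere (fraction of
#'   extraterrestrial radiation reaching the surface on dry days).
#' @param cloud_loss Fractional radiation reduction on wet days.
#' @return A list of class `climate_spec`.
#' @export
climate_spec <- function(latitude = -15, t_mean = 25.5, t_amp = 1.5,
                         t_ar = 0.7, t_sd = 1.1, year_t_sd = 0.6,
                         wet_prob = 0.55, rain_mm = 11, rain_shape = 0.9,
                         decay = 0.02, decay_start = 60,
                         clear_frac = 0.70, cloud_loss = 0.30) {
  stopifnot(rain_mm >= 0, wet_prob >= 0, wet_prob <= 1, decay >= 0,
            rain_shape > 0, abs(latitude) < 66.5)
  structure(list(latitude = latitude, t_mean = t_mean, t_amp = t_amp,
                 t_ar = t_ar, t_sd = t_sd, year_t_sd = year_t_sd,
                 wet_prob = wet_prob, rain_mm = rain_mm,
                 rain_shape = rain_shape, decay = decay,
                 decay_start = decay_start, clear_frac = clear_frac,
                 cloud_loss = cloud_loss),
            class = "climate_spec")
}

#' Generate one season of synthetic daily weather
#'
#' Temperature is a seasonal sinusoid plus AR(1) noise plus an optional
#' year-level anomaly; rainfall is Bernoulli-gamma with a wet-day
#' probability that decays exponentially after `decay_start`; radiation is a
#' fraction of the extraterrestrial total, reduced on wet days.  The same
#' seed always reproduces the same series.
#'
#' @param spec A [climate_spec()].
#' @param n_days Number of days (>= 150).
#' @param seed Integer seed.
#' @param start_date First day of the series.
#' @param year_anomaly Year-level temperature anomaly [degC]; default drawn
#'   from `N(0, year_t_sd)`.
#' @return A daily weather `data.frame` (see [read_weather()]).
#' @export
generate_weather <- function(spec, n_days = 170, seed = 1,
                             start_date = as.Date("2003-01-15"),
                             year_anomaly = NULL) {
  stopifnot(inherits(spec, "climate_spec"), n_days >= 150)
  with_seed(seed, {
    dates <- start_date + seq_len(n_days) - 1
    doy <- as.integer(format(dates, "%j"))
    t_season <- spec$t_mean + spec$t_amp * cos(2 * pi * (doy - 32) / 365)
    ar <- stats::filter(stats::rnorm(n_days, 0, spec$t_sd), spec$t_ar,
                        method = "recursive")
    if (is.null(year_anomaly)) year_anomaly <- stats::rnorm(1, 0, spec$year_t_sd)
    tmean <- t_season + as.numeric(ar) + year_anomaly
    half_range <- pmax(3 + stats::rnorm(n_days, 0, 0.8), 1)
    day <- seq_len(n_days)
    p_wet <- spec$wet_prob * exp(-spec$decay * pmax(day - spec$decay_start, 0))
    wet <- stats::rbinom(n_days, 1, p_wet)
    rain <- wet * stats::rgamma(n_days, shape = spec$rain_shape,
                                scale = spec$rain_mm / spec$rain_shape)
    ra <- extraterrestrial_radiation(spec$latitude, doy)
    trans <- spec$clear_frac - spec$cloud_loss * wet +
      stats::rnorm(n_days, 0, 0.04)
    srad <- ra * pmin(pmax(trans, 0.10), 0.78)
    data.frame(date = dates, tmean = tmean,
               tmin = tmean - half_range, tmax = tmean + half_range,
               rain = rain, srad = srad)
  })
}

#' Ground-truth specification for synthetic yields
#'
#' Defines how the synthetic "official" yields are built from the national
#' indicator matrix: a base level plus a linear technological trend plus
#' known coefficients on a chosen subset of indicators (read at a reference
#' window, centered on their across-year means) plus Gaussian noise.
#'
#' The defaults put signal on accumulated rainfall (the agrometeorological
#' driver) and on water-limited grain dry mass (a model-output driver), with
#' noise s.d. 0.4 Mg ha-1 -- calibrated so the true model explains roughly
#' 80% of the inter-annual yield variance under the default climate.
#'
#' @param regressors `data.frame` with columns `name`, `level`, `beta`
#'   (response units per indicator unit).
#' @param base Mean yield level [Mg ha-1].
#' @param trend_slope Technological trend [Mg ha-1 yr-1].
#' @param noise_sd Yield noise s.d. [Mg ha-1], positive.
#' @param ref_window Window (days after sowing) whose indicator values
#'   drive the yields.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(regressors = data.frame(
                         name = c("RAIN", "GDM"),
                         level = c("agromet", "water_limited"),
                         beta = c(0.009, 1.2)),
                       base = 5.5, trend_slope = 0.05, noise_sd = 0.4,
                       ref_window = 120) {
  stopifnot(nrow(regressors) >= 1, noise_sd > 0,
            all(c("name", "level", "beta") %in% names(regressors)))
  structure(list(regressors = regressors, base = base,
                 trend_slope = trend_slope, noise_sd = noise_sd,
                 ref_window = ref_window),
            class = "truth_spec")
}

#' Generate a complete synthetic multi-zone study
#'
#' Emulates a 14-year, multi-zone off-season: per zone-year weather is
#' generated, the crop simulator is run at both production levels (the
#' water-limited level once per dominant soil class, then soil-share
#' weighted), window indicators are computed, zones are aggregated to a
#' national indicator matrix by cultivated area, and synthetic official
#' yields are drawn from the ground truth.
#'
#' @param n_zones Number of climate zones (>= 1).
#' @param n_years Number of years (>= 10).
#' @param truth A [truth_spec()].
#' @param params A [crop_params()] object.
#' @param climates Optional list of `n_zones` [climate_spec()]s; default
#'   zones spread over latitudes -12 to -23 with slightly different
#'   temperature and rainfall levels.
#' @param seed Integer seed; drives every random draw.
#' @param windows Forecasting windows (days after sowing).
#' @param start_year First calendar year.
#' @return A list of class `synthetic_study`: `indicators` (national long
#'   table with `year`), `zone_indicators`, `yields` (`year`, `yield`),
#'   `areas`, `zones` (zone description table), `truth` (the ground-truth
#'   specification), `params`, `seed`.
#' @export
generate_study <- function(n_zones = 4, n_years = 14, truth = truth_spec(),
                           params = crop_params(), climates = NULL,
                           seed = 1, windows = seq(10, 120, by = 10),
                           start_year = 2003) {
  stopifnot(n_zones >= 1, n_years >= 10, inherits(truth, "truth_spec"))
  if (is.null(climates)) {
    lats <- seq(-12, -23, length.out = max(n_zones, 2))[seq_len(n_zones)]
    climates <- lapply(seq_len(n_zones), function(z)
      climate_spec(latitude = lats[z],
                   t_mean = 26.5 + 0.12 * lats[z],   # warmer toward the equator
                   rain_mm = 11 + z %% 2,
                   wet_prob = 0.55 - 0.02 * (z - 1)))
  }
  stopifnot(length(climates) == n_zones)
  soil_classes <- c("clayey", "sandy")
  soil_shares <- c(0.65, 0.35)
  years <- start_year + seq_len(n_years) - 1

  zone_rows <- list()
  area_rows <- list()
  zone_meta <- list()
  base_area <- with_seed(seed, stats::runif(n_zones, 5e4, 4e5))
  for (z in seq_len(n_zones)) {
    cs <- climates[[z]]
    for (iy in seq_along(years)) {
      yr <- years[iy]
      wseed <- (seed * 997L + z * 131L + iy * 7L) %% .Machine$integer.max
      sowing <- as.Date(sprintf("%d-02-01", yr))
      wx <- generate_weather(cs, n_days = 170, seed = wseed,
                             start_date = sowing - 10)
      pot <- run_season(wx, sowing, params, soil_class_profile("clayey"),
                        mode = "potential", latitude = cs$latitude,
                        horizon = max(windows))
      wl <- lapply(soil_classes, function(sc)
        run_season(wx, sowing, params, soil_class_profile(sc),
                   mode = "water_limited", latitude = cs$latitude,
                   horizon = max(windows)))
      # soil-share weighted water-limited trajectories
      wl_mix <- wl[[1]]
      for (col in c("dvi", "ldm", "sdm", "gdm", "lai", "height", "swc", "fsmc"))
        wl_mix[[col]] <- soil_weighted_cols(wl, col, soil_shares)
      ind <- window_indicators(wx, list(potential = pot, water_limited = wl_mix),
                               sowing, windows, latitude = cs$latitude)
      ind$zone <- z
      ind$year <- yr
      zone_rows[[length(zone_rows) + 1L]] <- ind
      area_rows[[length(area_rows) + 1L]] <- data.frame(
        zone = z, year = yr,
        area_ha = base_area[z] * (1 + 0.01 * (iy - 1)))
    }
    zone_meta[[z]] <- data.frame(zone = z, latitude = cs$latitude,
                                 sowing_date = "02-01",
                                 soil_class = soil_classes,
                                 share = soil_shares)
  }
  zone_ind <- do.call(rbind, zone_rows)
  areas <- do.call(rbind, area_rows)
  national <- aggregate_indicators(zone_ind, areas)

  study <- structure(list(indicators = national, zone_indicators = zone_ind,
                          areas = areas, zones = do.call(rbind, zone_meta),
                          params = params, seed = seed, windows = windows,
                          years = years),
                     class = "synthetic_study")
  study$truth <- truth
  study$yields <- draw_yields(study, truth, seed = seed + 1L)
  study
}

# extract column `col` at every day from a list of season results and
# soil-share weight them
soil_weighted_cols <- function(seasons, col, shares) {
  vals <- vapply(seasons, function(s) s[[col]], numeric(nrow(seasons[[1]])))
  apply(vals, 1, soil_weighted, shares = shares)
}

#' Draw synthetic official yields from a study's ground truth
#'
#' Builds the yield series `base + trend + sum(beta * centered indicator) +
#' noise` from the study's national indicator matrix.  Redrawing with new
#' seeds gives independent noise replicates over the same weather --
#' the replicate design used by the recovery and calibration experiments.
#'
#' @param study A [generate_study()] result.
#' @param truth A [truth_spec()]; default the study's own.
#' @param seed Integer seed for the noise draw.
#' @return `data.frame` with columns `year`, `yield`; the noise-free signal
#'   and the noise draws are attached as attributes `signal` and `noise`.
#' @export
draw_yields <- function(study, truth = study$truth, seed = 1) {
  ind <- study$indicators
  years <- sort(unique(ind$year))
  signal <- rep(0, length(years))
  for (i in seq_len(nrow(truth$regressors))) {
    tr <- truth$regressors[i, ]
    v <- ind$value[ind$window == truth$ref_window & ind$level == tr$level &
                     ind$name == tr$name]
    if (length(v) != length(years))
      stop("draw_yields(): truth regressor ", tr$name, "/", tr$level,
           " not present at window ", truth$ref_window)
    signal <- signal + tr$beta * (v - mean(v))
  }
  noise <- with_seed(seed, stats::rnorm(length(years), 0, truth$noise_sd))
  data.frame(year = years,
             yield = truth$base + truth$trend_slope * (years - years[1]) +
               signal + noise) |>
    structure(signal = signal, noise = noise)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic off-season maize study\n")
  cat(sprintf("  %d zones x %d years (%d-%d), windows %s\n",
              max(x$zone_indicators$zone), length(x$years),
              min(x$years), max(x$years),
              paste(range(x$windows), collapse = "-")))
  tr <- x$truth$regressors
  cat("  ground truth: yield =", x$truth$base, "+",
      sprintf("%+.3g yr", x$truth$trend_slope), "+",
      paste(sprintf("%+.3g x %s", tr$beta,
                    regressor_label(tr$name, tr$level)), collapse = " "),
      sprintf("+ N(0, %.2g)\n", x$truth$noise_sd))
  cat(sprintf("  mean yield %.2f Mg ha-1\n", mean(x$yields$yield)))
  invisible(x)
}
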