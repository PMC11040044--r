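# Solar geometry and daily radiation partitioning.

solar_declination <- function(doy) {
  23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
}

#' Geometric day length
#'
#' Photoperiod from standard solar declination / sunset hour-angle geometry
#' (no twilight allowance).
#'
#' @param latitude Latitude in decimal degrees, positive north; polar
#'   latitudes (`abs(latitude) >= 66.5`) are rejected.
#' @param doy Day of year (1-366).
#' @return Day length in hours; 12 h at the equinoxes for any latitude.
#' @export
day_length <- function(latitude, doy) {
  if (any(abs(latitude) >= 66.5))
    stop("day_length(): polar latitudes (|lat| >= 66.5) not supported")
  decl <- solar_declination(doy)
  x <- -tan(latitude * pi / 180) * tan(decl)
  ws <- acos(pmin(pmax(x, -1), 1))
  24 * ws / pi
}

#' Daily extraterrestrial solar radiation
#'
#' Top-of-atmosphere daily shortwave total from the standard closed-form
#' integral of the solar constant over the day arc.
#'
#' @inheritParams day_length
#' @return Radiation in MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  lat <- latitude * pi / 180
  decl <- solar_declination(doy)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  x <- pmin(pmax(-tan(lat) * tan(decl), -1), 1)
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(lat) * sin(decl) + cos(lat) * cos(decl) * sin(ws))
}

#' Surface pressure of the standard atmosphere
#'
#' @param elevation Site elevation [m]; default 500 m, a typical altitude of
#'   the Brazilian cerrado maize belt.
#' @return Pressure in kPa.
#' @export
standard_pressure <- function(elevation = 500) {
  101.325 * ((293 - 0.0065 * elevation) / 293)^5.26
}

# Clear-sky potential direct/diffuse radiation in the visible and
# near-infrared bands, integrated over the day in hour-angle steps.
# Band model: potential spectral irradiances of 600 (visible) and
# 720 (NIR) W m-2, beam extinction exp(-0.185 p m) and exp(-0.06 p m)
# with pressure-corrected air mass m, NIR water absorption
# w = 1320 * 10^(-1.1950 + 0.4459 log10 m - 0.0345 (log10 m)^2),
# and sky-scattered shares 0.4 / 0.6 of the depleted beam.
clearsky_bands <- function(latitude, doy, pressure, n_steps = 48) {
  lat <- latitude * pi / 180
  decl <- solar_declination(doy)
  x <- pmin(pmax(-tan(lat) * tan(decl), -1), 1)
  ws <- acos(x)
  if (ws <= 0) return(list(RDV = 0, RdV = 0, RDN = 0, RdN = 0))
  # midpoints of n_steps equal hour-angle intervals across the day arc
  edges <- seq(-ws, ws, length.out = n_steps + 1)
  h <- (edges[-1] + edges[-(n_steps + 1)]) / 2
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h)
  keep <- cosz > 1e-3
  if (!any(keep)) return(list(RDV = 0, RdV = 0, RDN = 0, RdN = 0))
  cosz <- cosz[keep]
  m <- pmin(1 / cosz, 30)
  pr <- pressure / 101.325
  rdv <- 600 * exp(-0.185 * pr * m) * cosz
  rdv_dif <- 0.4 * (600 * cosz - rdv)
  lm10 <- log10(m)
  w <- 1320 * 10^(-1.1950 + 0.4459 * lm10 - 0.0345 * lm10^2)
  rdn <- pmax(720 * exp(-0.06 * pr * m) - w, 0) * cosz
  rdn_dif <- pmax(0.6 * (720 - rdn / cosz - w) * cosz, 0)
  # step width in seconds: full day arc 2 ws rad = 24 h
  dt <- (2 * ws / n_steps) * (24 / (2 * pi)) * 3600
  tomj <- dt / 1e6
  list(RDV = sum(rdv) * tomj, RdV = sum(rdv_dif) * tomj,
       RDN = sum(rdn) * tomj, RdN = sum(rdn_dif) * tomj)
}

#' Daily diffuse radiation by two-band partitioning
#'
#' Splits a measured daily global shortwave total into direct and diffuse
#' components using the classic two-band (visible / near-infrared) potential
#' radiation method: clear-sky direct and diffuse components of both bands
#' are computed from solar geometry and pressure-corrected air mass and
#' integrated over the day; the ratio of measured to potential total then
#' drives an empirical cloudiness reduction of the direct fraction in each
#' band (coefficients A = 0.9, B = 0.7 visible; A = 0.88, B = 0.68 NIR).
#'
#' @param srad Measured daily global shortwave radiation [MJ m-2 d-1].
#' @inheritParams day_length
#' @param pressure Surface pressure [kPa]; defaults to the standard
#'   atmosphere at 500 m elevation.
#' @return Diffuse radiation [MJ m-2 d-1], in `[0, srad]`.  The diffuse
#'   fraction is 1 at and below the method's overcast ratio (0.2) and falls
#'   monotonically to its clear-sky minimum as the measured/potential ratio
#'   approaches 1.
#' @export
diffuse_fraction <- function(srad, latitude, doy, pressure = standard_pressure()) {
  if (length(srad) > 1L) {
    return(mapply(diffuse_fraction, srad, latitude, doy,
                  MoreArgs = list(pressure = pressure)))
  }
  if (!is.finite(srad) || srad < 0) stop("diffuse_fraction(): srad must be >= 0")
  if (srad == 0) return(0)
  b <- clearsky_bands(latitude, doy, pressure)
  rt <- b$RDV + b$RdV + b$RDN + b$RdN
  if (rt <= 0) return(0)  # sun below horizon all day
  ratio <- srad / rt
  corr_v <- if (ratio >= 0.9) 1 else max(0, 1 - ((0.9 - ratio) / 0.7)^(2 / 3))
  corr_n <- if (ratio >= 0.88) 1 else max(0, 1 - ((0.88 - ratio) / 0.68)^(2 / 3))
  fv <- (b$RDV + b$RdV) / rt
  fbeam_v <- if (b$RDV + b$RdV > 0) b$RDV / (b$RDV + b$RdV) * corr_v else 0
  fbeam_n <- if (b$RDN + b$RdN > 0) b$RDN / (b$RDN + b$RdN) * corr_n else 0
  beam <- srad * (fv * fbeam_v + (1 - fv) * fbeam_n)
  min(max(srad - beam, 0), srad)
}
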