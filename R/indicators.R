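# Forecasting-window indicators: model outputs and agrometeorological terms.

# canonical indicator names by production level
MODEL_OUTPUTS_BOTH <- c("LDM", "SDM", "GDM", "CH", "LAI")
MODEL_OUTPUTS_WL <- c("FSMC", "SWC")
AGROMET <- c("TMED", "RAIN", "DIFF_RAD")

#' Candidate regressor label
#'
#' Model outputs are suffixed by production level (`_Yp` potential, `_Yw`
#' water-limited); agrometeorological indicators keep their bare name.
#'
#' @param name Indicator name (e.g. `"GDM"`, `"RAIN"`).
#' @param level `"potential"`, `"water_limited"` or `"agromet"`.
#' @return Character label, e.g. `"GDM_Yw"`.
#' @export
regressor_label <- function(name, level) {
  suffix <- c(potential = "_Yp", water_limited = "_Yw", agromet = "")[level]
  paste0(name, suffix)
}

#' Window indicators for one simulated season
#'
#' For each forecasting window (days after sowing, every 10 days up to 120
#' by default) computes the agrometeorological indicators from the driving
#' weather -- TMED (mean daily temperature from sowing to the window day),
#' RAIN (accumulated rainfall) and DIFF_RAD (mean daily diffuse radiation by
#' [diffuse_fraction()]) -- and reads the model-output indicators (LDM, SDM,
#' GDM, CH, LAI per production level; FSMC and SWC from the water-limited
#' level only) as the simulated state on the window day.
#'
#' "From sowing to the date" is inclusive of the window day; day 1 is the
#' day after sowing.
#'
#' @param weather Daily weather table covering the season.
#' @param seasons Named list of [run_season()] results; names are production
#'   levels (`potential`, `water_limited`).  Each must cover the last window.
#' @param sowing Sowing date.
#' @param windows Integer vector of window days after sowing, strictly
#'   increasing; default `seq(10, 120, by = 10)`.
#' @param latitude Latitude for the diffuse-radiation geometry.
#' @param pressure Surface pressure [kPa]; defaults to the standard
#'   atmosphere at 500 m.
#' @return A long-format `data.frame` with columns `window`, `level`,
#'   `name`, `value` -- one row per (window, indicator) cell.
#' @export
window_indicators <- function(weather, seasons, sowing,
                              windows = seq(10, 120, by = 10),
                              latitude = -15, pressure = standard_pressure()) {
  stopifnot(is.list(seasons), length(seasons) >= 1,
            all(names(seasons) %in% c("potential", "water_limited")))
  if (any(diff(windows) <= 0) || any(windows < 1))
    stop("window_indicators(): windows must be positive and strictly increasing")
  validate_weather(weather)
  sowing <- as.Date(sowing)
  i0 <- match(sowing, weather$date)
  if (is.na(i0)) stop("window_indicators(): sowing date not in weather table")
  wmax <- max(windows)
  if (nrow(weather) - i0 < wmax)
    stop("window_indicators(): weather too short for window ", wmax)
  for (lv in names(seasons))
    if (nrow(seasons[[lv]]) < wmax)
      stop("window_indicators(): ", lv, " season trajectory too short for window ",
           wmax)

  days <- seq_len(wmax)
  wx <- weather[i0 + days, , drop = FALSE]
  doy <- as.integer(format(wx$date, "%j"))
  diff_rad <- diffuse_fraction(wx$srad, latitude, doy, pressure = pressure)

  rows <- list()
  for (d in windows) {
    rows[[length(rows) + 1L]] <- data.frame(
      window = d, level = "agromet", name = AGROMET,
      value = c(mean(wx$tmean[1:d]), sum(wx$rain[1:d]), mean(diff_rad[1:d])))
    for (lv in names(seasons)) {
      s <- seasons[[lv]]
      vals <- c(s$ldm[d], s$sdm[d], s$gdm[d], s$height[d], s$lai[d])
      nms <- MODEL_OUTPUTS_BOTH
      if (lv == "water_limited") {
        vals <- c(vals, s$fsmc[d], s$swc[d])
        nms <- c(nms, MODEL_OUTPUTS_WL)
      }
      rows[[length(rows) + 1L]] <- data.frame(window = d, level = lv,
                                              name = nms, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write an indicator table
#'
#' Long-format delimited text with columns `year,window,level,name,value`
#' (the `year` column is present once indicators from several seasons are
#' stacked).
#'
#' @param ind Indicator `data.frame`.
#' @param path File path.
#' @return `read_indicators()` returns the `data.frame`;
#'   `write_indicators()` returns `path` invisibly.
#' @export
write_indicators <- function(ind, path) {
  utils::write.csv(ind, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  ind <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window", "level", "name", "value")
  missing <- setdiff(need, names(ind))
  if (length(missing))
    stop("indicator file '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  ind
}
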