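# Daily weather tables: delimited text with a fixed header.

#' Read or write a daily weather table
#'
#' The on-disk format is comma-delimited text with header
#' `date,tmean,tmin,tmax,rain,srad[,pressure]`; dates ISO-8601, temperatures
#' in degC, rain in mm d-1, global shortwave in MJ m-2 d-1, optional surface
#' pressure in kPa.
#'
#' @param path File path.
#' @return `read_weather()` returns a validated `data.frame` with `date` as
#'   `Date`; `write_weather()` returns `path` invisibly.
#' @export
read_weather <- function(path) {
  wx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmean", "tmin", "tmax", "rain", "srad")
  missing <- setdiff(need, names(wx))
  if (length(missing))
    stop("weather file '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  wx$date <- as.Date(wx$date)
  validate_weather(wx)
  wx
}

#' @rdname read_weather
#' @param wx A daily weather `data.frame`.
#' @export
write_weather <- function(wx, path) {
  validate_weather(wx)
  utils::write.csv(wx, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_weather
#' @export
validate_weather <- function(wx) {
  need <- c("date", "tmean", "tmin", "tmax", "rain", "srad")
  stopifnot(all(need %in% names(wx)))
  if (any(is.na(wx$date))) stop("weather: unparseable dates")
  if (any(diff(as.integer(wx$date)) != 1L))
    stop("weather: dates must be consecutive days")
  num <- wx[setdiff(need, "date")]
  bad <- which(!stats::complete.cases(num))
  if (length(bad)) stop("weather: missing values at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(wx$tmin > wx$tmean + 1e-9) || any(wx$tmean > wx$tmax + 1e-9))
    stop("weather: need tmin <= tmean <= tmax")
  if (any(wx$rain < 0) || any(wx$srad < 0))
    stop("weather: rain and srad must be >= 0")
  invisible(wx)
}
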