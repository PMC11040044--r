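# Two-step spatial aggregation: soil classes -> climate zone -> nation.

#' Soil-share weighted zone value
#'
#' Weights per-soil-class simulation results by the areal share of each soil
#' class within a climate zone; shares are renormalized so they need not sum
#' to 1.
#'
#' @param values Numeric vector, one value per soil class.
#' @param shares Non-negative weights of the same length, not all zero.
#' @return The weighted mean `sum(values * shares) / sum(shares)`.
#' @export
soil_weighted <- function(values, shares) {
  stopifnot(length(values) == length(shares), length(values) >= 1)
  if (any(shares < 0) || all(shares == 0))
    stop("soil_weighted(): shares must be non-negative and not all zero")
  sum(values * shares) / sum(shares)
}

#' Area-weighted national series
#'
#' Collapses per-zone annual values to a national series, weighting each
#' zone by its cultivated area in that year.  Applied identically to
#' simulated outputs and agrometeorological indicators.
#'
#' @param zone_values `data.frame` with columns `zone`, `year`, `value`.
#' @param areas `data.frame` with columns `zone`, `year`, `area_ha`
#'   (positive).  Every (zone, year) pair present in `zone_values` must be
#'   covered; missing pairs are an error naming them.
#' @return `data.frame` with columns `year`, `value`, one row per year.
#'   The national value always lies within the range of the zone values of
#'   that year, and is invariant to rescaling all areas by a constant.
#' @export
area_weighted_national <- function(zone_values, areas) {
  stopifnot(all(c("zone", "year", "value") %in% names(zone_values)),
            all(c("zone", "year", "area_ha") %in% names(areas)))
  if (any(areas$area_ha <= 0)) stop("area_weighted_national(): areas must be > 0")
  m <- merge(zone_values, areas, by = c("zone", "year"), all.x = TRUE)
  if (any(is.na(m$area_ha))) {
    bad <- m[is.na(m$area_ha), c("zone", "year")]
    stop("area_weighted_national(): no area for ",
         paste(sprintf("%s/%s", bad$zone, bad$year), collapse = ", "))
  }
  agg <- by(m, m$year, function(g) {
    data.frame(year = g$year[1], value = sum(g$value * g$area_ha) / sum(g$area_ha))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$year), , drop = FALSE]
}

#' Aggregate a zone-level indicator table to the national scale
#'
#' Applies [area_weighted_national()] separately to every (window, level,
#' name) indicator cell of a stacked zone-level indicator table.
#'
#' @param zone_ind Long indicator `data.frame` with columns `zone`, `year`,
#'   `window`, `level`, `name`, `value`.
#' @param areas As in [area_weighted_national()].
#' @return National long indicator `data.frame` (`year`, `window`, `level`,
#'   `name`, `value`).
#' @export
aggregate_indicators <- function(zone_ind, areas) {
  need <- c("zone", "year", "window", "level", "name", "value")
  stopifnot(all(need %in% names(zone_ind)))
  key <- interaction(zone_ind$window, zone_ind$level, zone_ind$name, drop = TRUE)
  parts <- lapply(split(zone_ind, key), function(g) {
    nat <- area_weighted_national(g[c("zone", "year", "value")], areas)
    data.frame(year = nat$year, window = g$window[1], level = g$level[1],
               name = g$name[1], value = nat$value)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$year, out$window, out$level, out$name), , drop = FALSE]
}

#' Read region description tables
#'
#' Two delimited files describe the study regions: a zone table
#' (`zone,latitude,sowing_date,soil_class,share` -- one row per zone x soil
#' class) and an area table (`zone,year,area_ha`).
#'
#' @param zones_path,areas_path File paths.
#' @return A list with elements `zones` and `areas` (`data.frame`s).
#' @export
read_region_table <- function(zones_path, areas_path) {
  zones <- utils::read.csv(zones_path, stringsAsFactors = FALSE)
  need <- c("zone", "latitude", "sowing_date", "soil_class", "share")
  missing <- setdiff(need, names(zones))
  if (length(missing))
    stop("zone table '", zones_path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  areas <- utils::read.csv(areas_path, stringsAsFactors = FALSE)
  missing <- setdiff(c("zone", "year", "area_ha"), names(areas))
  if (length(missing))
    stop("area table '", areas_path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  list(zones = zones, areas = areas)
}
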