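# Whole-season simulation and its result container.

#' Simulate one maize season
#'
#' Runs the daily state update from the day after sowing until the
#' development index reaches 2 (physiological maturity, the harvest
#' trigger), or until `horizon` days after sowing when given.  With a
#' horizon beyond maturity the post-harvest state is carried forward
#' unchanged (soil water keeps cycling) so that forecasting windows after
#' harvest remain defined.  Early-harvest triggers are deliberately not
#' implemented.
#'
#' @param weather Daily weather `data.frame` (see [read_weather()]) covering
#'   the season; must include the sowing date.
#' @param sowing Sowing date (`Date` or ISO-8601 string).  DVI is -1 at
#'   sowing; simulated day 1 is the day after sowing.
#' @param params A [crop_params()] object.
#' @param soil A [soil_profile()] giving the initial soil state.
#' @param mode `"water_limited"` or `"potential"`.
#' @param latitude Site latitude [decimal degrees].
#' @param horizon Days after sowing to simulate (default `NULL`: stop at
#'   harvest or at 200 days, whichever comes first).
#' @return An object of class `season_result`: a `data.frame` with one row
#'   per simulated day and columns `das` (days after sowing), `dvi`, `ldm`,
#'   `sdm`, `gdm` (leaf/stalk/grain dry mass, Mg ha-1), `lai`, `height`,
#'   `swc`, `fsmc`; attributes `yield` (grain dry mass at harvest, Mg ha-1),
#'   `harvest_day` (`NA` if maturity was not reached), `complete`, `mode`,
#'   and the season's closing carbon and water ledgers.
#' @export
run_season <- function(weather, sowing, params, soil = soil_profile(),
                       mode = c("water_limited", "potential"),
                       latitude = -15, horizon = NULL) {
  mode <- match.arg(mode)
  validate_weather(weather)
  validate_crop_params(params)
  sowing <- as.Date(sowing)
  i0 <- match(sowing, weather$date)
  if (is.na(i0)) stop("run_season(): sowing date not covered by the weather table")
  max_days <- if (is.null(horizon)) 200L else as.integer(horizon)
  avail <- nrow(weather) - i0
  if (avail < 1) stop("run_season(): no weather after the sowing date")

  state <- new_crop_state(soil)
  n <- min(max_days, avail)
  out <- data.frame(das = seq_len(n), dvi = NA_real_, ldm = NA_real_,
                    sdm = NA_real_, gdm = NA_real_, lai = NA_real_,
                    height = NA_real_, swc = NA_real_, fsmc = NA_real_)
  cum <- list(npp = 0, sen = 0, seed = 0, rain = 0, drain = 0, et = 0)
  harvest_day <- NA_integer_
  last <- n
  for (d in seq_len(n)) {
    state <- step_day(state, weather[i0 + d, , drop = FALSE], params, mode,
                      latitude = latitude)
    fx <- state$flux
    cum$npp <- cum$npp + fx$npp;   cum$sen <- cum$sen + fx$sen_loss
    cum$seed <- cum$seed + fx$seed; cum$rain <- cum$rain + fx$rain
    cum$drain <- cum$drain + fx$drainage; cum$et <- cum$et + fx$et_actual
    out$dvi[d] <- state$dvi
    out$ldm[d] <- state$c_leaf / params$fc_leaf * 10
    out$sdm[d] <- (state$c_stem + state$c_reserve) / params$fc_stem * 10
    out$gdm[d] <- state$c_harvest / params$fc_grain * 10
    out$lai[d] <- state$lai
    out$height[d] <- state$height
    out$swc[d] <- state$swc
    out$fsmc[d] <- state$fsmc
    if (is.na(harvest_day) && state$dvi >= 2) {
      harvest_day <- d
      if (is.null(horizon)) { last <- d; break }
    }
  }
  out <- out[seq_len(last), , drop = FALSE]

  pools <- with(state, c_leaf + c_stem + c_reserve + c_root + c_harvest)
  structure(out,
            yield = if (!is.na(harvest_day)) out$gdm[harvest_day] else out$gdm[last],
            harvest_day = harvest_day,
            complete = !is.na(harvest_day),
            mode = mode, sowing = sowing, latitude = latitude,
            carbon_ledger = c(cum_npp = cum$npp, cum_seed = cum$seed,
                              cum_senescence = cum$sen, final_pools = pools),
            water_ledger = c(rain = cum$rain, drainage = cum$drain,
                             et = cum$et,
                             storage_change =
                               sum((state$profile$theta - soil$theta) *
                                     (soil$depth_bottom - soil$depth_top) * 1000)),
            class = c("season_result", "data.frame"))
}

#' @export
print.season_result <- function(x, ...) {
  hd <- attr(x, "harvest_day")
  cat(sprintf("Maize season simulation (%s mode)\n", attr(x, "mode")))
  cat(sprintf("  sowing %s, %d simulated day(s)\n",
              format(attr(x, "sowing")), nrow(x)))
  if (attr(x, "complete"))
    cat(sprintf("  maturity (DVI = 2) at %d days after sowing\n", hd))
  else
    cat("  maturity not reached within the simulated horizon\n")
  cat(sprintf("  grain dry mass at harvest: %.2f Mg ha-1\n", attr(x, "yield")))
  cat(sprintf("  peak LAI %.2f, final height %.2f m, final FSMC %.2f\n",
              max(x$lai), x$height[nrow(x)], x$fsmc[nrow(x)]))
  invisible(x)
}

#' @export
plot.season_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$das, x$dvi, type = "l", xlab = "days after sowing",
                 ylab = "DVI", main = "Development index", ...)
  graphics::abline(h = c(0, 1, 2), lty = 3, col = "grey60")
  graphics::matplot(x$das, cbind(x$ldm, x$sdm, x$gdm), type = "l", lty = 1,
                    col = c("forestgreen", "tan4", "goldenrod"),
                    xlab = "days after sowing", ylab = "dry mass (Mg/ha)",
                    main = "Organ dry mass")
  graphics::legend("topleft", c("leaf", "stalk", "grain"), lty = 1, bty = "n",
                   col = c("forestgreen", "tan4", "goldenrod"))
  graphics::plot(x$das, x$lai, type = "l", col = "forestgreen",
                 xlab = "days after sowing", ylab = "LAI", main = "Leaf area index")
  graphics::plot(x$das, x$fsmc, type = "l", ylim = c(0, 1), col = "steelblue",
                 xlab = "days after sowing", ylab = "FSMC",
                 main = "Soil moisture stress")
  invisible(x)
}

#' Read or write a simulated season table
#'
#' Delimited text, one row per day after sowing, columns
#' `das,dvi,ldm,sdm,gdm,lai,height,swc,fsmc`.
#'
#' @param x A `season_result` (or compatible `data.frame`).
#' @param path File path.
#' @return `read_season()` returns a `data.frame`; `write_season()` returns
#'   `path` invisibly.
#' @export
write_season <- function(x, path) {
  cols <- c("das", "dvi", "ldm", "sdm", "gdm", "lai", "height", "swc", "fsmc")
  utils::write.csv(as.data.frame(x)[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_season
#' @export
read_season <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("das", "dvi", "ldm", "sdm", "gdm", "lai", "height", "swc", "fsmc")
  missing <- setdiff(need, names(s))
  if (length(missing))
    stop("season file '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  s
}
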