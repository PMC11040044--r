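# Daily carbon gain, allocation and the assembled daily state update.

#' Daily canopy carbon gain
#'
#' Radiation-use-efficiency canopy model: intercepted photosynthetically
#' active radiation (half the global shortwave, Beer-law interception by the
#' canopy) times the radiation-use efficiency, scaled by the soil-moisture
#' stress factor in water-limited mode.
#'
#' @param srad Daily global shortwave radiation [MJ m-2 d-1].
#' @param lai Leaf area index [m2 m-2].
#' @param fsmc Soil-moisture stress factor in `[0, 1]`.
#' @param params A [crop_params()] object (uses `rue` [g C MJ-1 PAR] and
#'   `k_ext`).
#' @param mode `"potential"` (no water stress) or `"water_limited"`.
#' @return Net carbon gain [kg C m-2 d-1], zero at `lai = 0`; potential-mode
#'   gain is always >= the water-limited gain for the same state.
#' @export
npp_daily <- function(srad, lai, fsmc, params,
                      mode = c("water_limited", "potential")) {
  mode <- match.arg(mode)
  stopifnot(srad >= 0, lai >= 0, fsmc >= 0, fsmc <= 1)
  s <- if (mode == "water_limited") fsmc else 1
  params$rue * (0.5 * srad) * (1 - exp(-params$k_ext * lai)) * s / 1000
}

# Integrate the development index through one day's thermal time,
# splitting the day across phase boundaries so that each phase consumes
# exactly its thermal-time requirement (phases land on the stage boundaries
# 0, 1, 2 exactly instead of overshooting by one daily Euler step).
advance_dvi <- function(dvi, teff, rpe, params) {
  rem <- teff
  for (guard in 1:6) {
    if (rem <= 0 || dvi >= 2) break
    r <- if (dvi < 0) 1 / params$TTemr
         else if (dvi < 1) rpe / params$TTveg
         else 1 / params$TTrep
    if (r <= 0) break
    bnext <- if (dvi < 0) 0 else if (dvi < 1) 1 else 2
    need <- (bnext - dvi) / r
    if (need <= rem * (1 + 1e-12)) {
      dvi <- bnext
      rem <- rem - min(need, rem)
    } else {
      dvi <- dvi + rem * r
      rem <- 0
    }
  }
  min(dvi, 2)
}

# Unstressed daily crop water demand [mm]: radiation-equivalent evaporation
# (latent heat 2.45 MJ kg-1) scaled by a bulk coefficient and canopy cover,
# with a bare-soil floor before canopy closure.
et_demand_daily <- function(srad, lai, params) {
  cover <- 1 - exp(-params$k_ext * lai)
  (srad / 2.45) * 0.55 * (0.25 + 0.75 * cover)
}

#' Initial crop state at sowing
#'
#' @param prof A [soil_profile()] giving the initial soil moisture state.
#' @return A list of class `crop_state`: development index -1 (sowing),
#'   empty carbon pools, zero canopy.
#' @export
new_crop_state <- function(prof) {
  validate_soil_profile(prof)
  structure(list(dvi = -1, c_leaf = 0, c_stem = 0, c_reserve = 0,
                 c_root = 0, c_harvest = 0, lai = 0, height = 0,
                 profile = prof, swc = NA_real_, fsmc = 1,
                 emerged = FALSE),
            class = "crop_state")
}

#' Advance the crop state by one day
#'
#' Update order: soil water balance (demand from yesterday's canopy), then
#' thermal time from the daily mean temperature, photoperiod effect,
#' development-index increment (capped at 2, the harvest trigger), pool
#' initialization at emergence, canopy carbon gain, softmax allocation (the
#' stem share split between structure and remobilizable reserve), reserve
#' remobilization to the harvest pool during the reproductive phase, leaf
#' senescence, and finally the canopy (SLA, LAI) and height allometries.
#'
#' The carbon ledger closes exactly each day:
#' change in total pools = carbon gain + emergence seeding - senescence loss.
#'
#' @param state A `crop_state` from [new_crop_state()] or a previous step.
#' @param wx One-row `data.frame` of daily weather (columns `date`, `tmean`,
#'   `tmin`, `tmax`, `rain`, `srad`).
#' @inheritParams npp_daily
#' @param latitude Site latitude [decimal degrees] for the photoperiod.
#' @return The updated `crop_state`, with a `flux` element recording the
#'   day's npp, senescence loss, emergence seeding, drainage and actual ET.
#' @export
step_day <- function(state, wx, params, mode = c("water_limited", "potential"),
                     latitude = -15) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "crop_state"))
  need <- c("date", "tmean", "tmin", "tmax", "rain", "srad")
  if (!all(need %in% names(wx)) || nrow(wx) != 1L ||
      any(!is.finite(unlist(wx[needs_num <- setdiff(need, "date")]))))
    stop("step_day(): weather gap or malformed daily record")

  # 1. soil water
  demand <- et_demand_daily(wx$srad, state$lai, params)
  sw <- soil_water_step(state$profile, wx$rain, demand)
  state$profile <- sw$profile
  state$swc <- sw$swc
  state$fsmc <- sw$fsmc

  # 2. development
  teff <- effective_temperature(wx$tmean, params)
  doy <- as.integer(format(as.Date(wx$date), "%j"))
  rpe <- relative_photoperiod_effect(day_length(latitude, doy), params)
  old_dvi <- state$dvi
  if (old_dvi < 2) {
    state$dvi <- advance_dvi(old_dvi, teff, rpe, params)
  }

  # 3. emergence: seed the pools when DVI crosses 0
  seed <- 0
  if (!state$emerged && state$dvi >= 0) {
    fr <- partition_fractions(0, params)
    state$c_leaf <- params$initial_carbon * fr[["leaf"]]
    state$c_stem <- params$initial_carbon * fr[["stem"]]
    state$c_harvest <- params$initial_carbon * fr[["harvest"]]
    state$c_root <- params$initial_carbon * fr[["root"]]
    state$emerged <- TRUE
    seed <- params$initial_carbon
  }

  # 4. carbon gain and allocation (growing crop only)
  npp <- 0
  if (state$emerged && old_dvi < 2) {
    npp <- npp_daily(wx$srad, state$lai, state$fsmc, params, mode)
    fr <- partition_fractions(state$dvi, params)
    state$c_leaf <- state$c_leaf + fr[["leaf"]] * npp
    stem_alloc <- fr[["stem"]] * npp
    state$c_reserve <- state$c_reserve + params$reserve_frac * stem_alloc
    state$c_stem <- state$c_stem + (1 - params$reserve_frac) * stem_alloc
    state$c_harvest <- state$c_harvest + fr[["harvest"]] * npp
    state$c_root <- state$c_root + fr[["root"]] * npp
  }

  # 5. reserve remobilization into the harvest pool
  if (state$emerged && state$dvi >= 1 && old_dvi < 2) {
    moved <- params$remob_rate * state$c_reserve
    state$c_reserve <- state$c_reserve - moved
    state$c_harvest <- state$c_harvest + moved
  }

  # 6. senescence (a litter loss, not re-allocated)
  sen_loss <- 0
  if (state$emerged && old_dvi < 2) {
    sf <- senescence_fraction(state$dvi, params)
    sen_loss <- sf * state$c_leaf
    state$c_leaf <- state$c_leaf - sen_loss
  }

  # 7. canopy and height allometry
  if (state$emerged) {
    sla <- specific_leaf_area(state$dvi, params)
    state$lai <- leaf_area_index(state$c_leaf, params, sla)
    state$height <- crop_height(state$c_stem + state$c_reserve, params)
  }

  state$flux <- list(npp = npp, sen_loss = sen_loss, seed = seed,
                     drainage = sw$drainage, et_actual = sw$et_actual,
                     et_demand = demand, rain = wx$rain)
  state
}
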