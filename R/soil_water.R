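# Layered tipping-bucket soil water balance.

#' Construct a layered soil profile
#'
#' A stack of equal-thickness layers with shared (or per-layer) hydraulic
#' limits.  The default is six 10-cm layers spanning the 60-cm effective
#' maize root zone, initialized at the critical (field-capacity) moisture.
#'
#' @param n_layers Number of layers.
#' @param thickness Layer thickness [m].
#' @param theta_sat Saturated volumetric water content [m3 m-3].
#' @param theta_fc Critical ("no stress") volumetric water content.
#' @param theta_wilt Wilting-point volumetric water content.
#' @param theta Initial water content; recycled over layers.  Defaults to
#'   `theta_fc` (profile refilled by the preceding wet season).
#' @return A `data.frame` of class `soil_profile` with columns `depth_top`,
#'   `depth_bottom`, `theta`, `theta_sat`, `theta_fc`, `theta_wilt`.
#' @export
soil_profile <- function(n_layers = 6, thickness = 0.1,
                         theta_sat = 0.45, theta_fc = 0.32, theta_wilt = 0.15,
                         theta = theta_fc) {
  tops <- (seq_len(n_layers) - 1) * thickness
  prof <- data.frame(depth_top = tops, depth_bottom = tops + thickness,
                     theta = rep_len(theta, n_layers),
                     theta_sat = rep_len(theta_sat, n_layers),
                     theta_fc = rep_len(theta_fc, n_layers),
                     theta_wilt = rep_len(theta_wilt, n_layers))
  class(prof) <- c("soil_profile", "data.frame")
  validate_soil_profile(prof)
  prof
}

validate_soil_profile <- function(prof) {
  stopifnot(is.data.frame(prof), nrow(prof) >= 1)
  with(prof, {
    if (any(theta_wilt < 0) || any(theta_wilt >= theta_fc) || any(theta_fc > theta_sat))
      stop("soil_profile: need 0 <= theta_wilt < theta_fc <= theta_sat")
    if (any(theta < 0) || any(theta > theta_sat + 1e-12))
      stop("soil_profile: theta must lie in [0, theta_sat]")
    if (any(diff(depth_top) <= 0) || any(depth_bottom <= depth_top))
      stop("soil_profile: layers must be ordered and non-degenerate")
  })
  invisible(prof)
}

# depth overlap [m] of each layer with [0, depth]
layer_overlap <- function(prof, depth) {
  pmax(pmin(prof$depth_bottom, depth) - pmin(prof$depth_top, depth), 0)
}

#' One daily step of the soil water balance
#'
#' Tipping-bucket scheme: rain infiltrates from the top, each layer storing
#' water up to its critical moisture and cascading the excess downward;
#' water leaving the bottom layer is drainage.  Crop water uptake is the
#' demand scaled by the stress factor and extracted from the root zone in
#' proportion to layer availability, never below the wilting point.
#'
#' The stress factor FSMC is the root-zone depth-weighted mean of the
#' per-layer linear ramp `(theta - theta_wilt) / (theta_fc - theta_wilt)`
#' clamped to `[0, 1]` (0 = extreme drought, 1 = no stress).  SWC is the
#' depth-weighted mean water content over the top 60 cm, with residual
#' moisture taken as zero.
#'
#' @param prof A [soil_profile()].
#' @param rain Daily rainfall [mm], non-negative.
#' @param et_demand Unstressed crop water demand [mm d-1], non-negative.
#' @param root_depth Effective rooting depth [m]; default 0.6.
#' @return A list with elements `profile` (updated), `swc` [m3 m-3],
#'   `fsmc` [0-1], `drainage` [mm], `et_actual` [mm].  The water ledger
#'   closes exactly: change in storage = rain - drainage - et_actual.
#' @export
soil_water_step <- function(prof, rain, et_demand, root_depth = 0.6) {
  validate_soil_profile(prof)
  if (!is.finite(rain) || rain < 0) stop("soil_water_step(): rain must be >= 0")
  if (!is.finite(et_demand) || et_demand < 0)
    stop("soil_water_step(): et_demand must be >= 0")
  if (max(prof$depth_bottom) < root_depth - 1e-9)
    stop("soil_water_step(): profile shallower than root_depth")
  thick_mm <- (prof$depth_bottom - prof$depth_top) * 1000

  # infiltration, cascading excess over the critical moisture
  water <- rain
  for (i in seq_len(nrow(prof))) {
    cap <- max(prof$theta_fc[i] - prof$theta[i], 0) * thick_mm[i]
    take <- min(water, cap)
    prof$theta[i] <- prof$theta[i] + take / thick_mm[i]
    water <- water - take
  }
  drainage <- water

  # stress factor over the root zone (post-infiltration state)
  w <- layer_overlap(prof, root_depth)
  ramp <- pmin(pmax((prof$theta - prof$theta_wilt) /
                      (prof$theta_fc - prof$theta_wilt), 0), 1)
  fsmc <- sum(w * ramp) / sum(w)

  # uptake: demand scaled by stress, split over layers by available water
  target <- et_demand * fsmc
  avail <- pmax(prof$theta - prof$theta_wilt, 0) * thick_mm * (w > 0)
  et_actual <- 0
  if (target > 0 && sum(avail) > 0) {
    share <- avail / sum(avail)
    takes <- pmin(target * share, avail)
    prof$theta <- prof$theta - takes / thick_mm
    et_actual <- sum(takes)
  }

  swc_w <- layer_overlap(prof, 0.6)
  swc <- sum(swc_w * prof$theta) / sum(swc_w)
  list(profile = prof, swc = swc, fsmc = fsmc,
       drainage = drainage, et_actual = et_actual)
}

#' Reference soil hydraulic classes
#'
#' Two-parameter-set library used by the synthetic study generator to stand
#' in for the dominant soil classes of a climate zone: a clayey
#' Ferralsol-like profile with high water storage and a sandy Arenosol-like
#' profile with low storage.
#'
#' @param class One of `"clayey"`, `"sandy"`, `"loamy"`.
#' @param ... Passed on to [soil_profile()] (e.g. `theta` to change the
#'   initial moisture).
#' @return A [soil_profile()].
#' @export
soil_class_profile <- function(class = c("clayey", "sandy", "loamy"), ...) {
  class <- match.arg(class)
  h <- switch(class,
              clayey = list(theta_sat = 0.48, theta_fc = 0.34, theta_wilt = 0.17),
              sandy  = list(theta_sat = 0.40, theta_fc = 0.24, theta_wilt = 0.09),
              loamy  = list(theta_sat = 0.45, theta_fc = 0.30, theta_wilt = 0.13))
  do.call(soil_profile, c(h, list(...)))
}
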