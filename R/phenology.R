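# Phenology and allometry: the per-day building blocks of the simulator.

#' Effective temperature (daily thermal-time increment)
#'
#' Trapezoidal temperature response of crop development: zero below the base
#' temperature `Tb`, linear up to the optimum `To`, declining linearly to
#' zero at the maximum `Tm`, zero above.
#'
#' @param t Air temperature [degC]; vectorized.
#' @param params A [crop_params()] object.
#' @return Thermal-time increment [degC day], in `[0, To - Tb]`.
#' @export
effective_temperature <- function(t, params) {
  ifelse(t < params$Tb | t >= params$Tm, 0,
         ifelse(t <= params$To, t - params$Tb,
                (params$To - params$Tb) *
                  (1 - (t - params$To) / (params$Tm - params$To))))
}

#' Relative photoperiod effect on vegetative development
#'
#' `RPE = 1 - (P - Pcrit) / Psens`, clamped to `[0, 1]`.  Multiplies the
#' vegetative development rate only.
#'
#' @param p Photoperiod [h]; vectorized.
#' @inheritParams effective_temperature
#' @return RPE in `[0, 1]`.
#' @export
relative_photoperiod_effect <- function(p, params) {
  if (params$Psens == 0) stop("relative_photoperiod_effect(): Psens must be nonzero")
  pmin(pmax(1 - (p - params$Pcrit) / params$Psens, 0), 1)
}

#' Daily development-index rate
#'
#' Piecewise by phase: `Teff/TTemr` during sowing-emergence (DVI in
#' `[-1,0)`), `(Teff/TTveg) * RPE` during emergence-flowering (`[0,1)`),
#' `Teff/TTrep` during flowering-maturity (`[1,2)`); zero at and beyond
#' maturity (DVI >= 2 is absorbing).
#'
#' @param teff Thermal-time increment [degC day].
#' @param dvi Current development index; values below -1 (pre-sowing) are
#'   rejected.
#' @param rpe Relative photoperiod effect in `[0, 1]`.
#' @inheritParams effective_temperature
#' @return dDVI/dt [d-1], non-negative.
#' @export
dvi_rate <- function(teff, dvi, rpe, params) {
  if (dvi < -1) stop("dvi_rate(): pre-sowing state (dvi < -1) does not advance")
  if (dvi < 0) teff / params$TTemr
  else if (dvi < 1) (teff / params$TTveg) * rpe
  else if (dvi < 2) teff / params$TTrep
  else 0
}

#' Carbon partition fractions
#'
#' Softmax allocation over the four organ pools:
#' `p_i = exp(alpha_i + beta_i * DVI) / sum_j exp(alpha_j + beta_j * DVI)`.
#' Computed with max-subtraction so extreme constants cannot overflow.
#'
#' @inheritParams dvi_rate
#' @return Named numeric vector (`leaf`, `stem`, `harvest`, `root`) summing
#'   to 1 to machine precision, each element in (0,1).
#' @export
partition_fractions <- function(dvi, params) {
  z <- params$alpha + params$beta * dvi
  if (any(!is.finite(z))) stop("partition_fractions(): non-finite alpha/beta")
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Daily leaf senescence fraction
#'
#' Zero up to the senescence threshold `DVIsen`, then the allometric loss
#' `mu * (DVI - DVIsen)^nu`, capped at 1.
#'
#' @inheritParams dvi_rate
#' @return Fraction of the leaf carbon pool lost per day, in `[0, 1]`.
#' @export
senescence_fraction <- function(dvi, params) {
  if (dvi <= params$DVIsen) return(0)
  min(params$mu * (dvi - params$DVIsen)^params$nu, 1)
}

#' Specific leaf area as a development-index function
#'
#' `SLA = gamma * (DVI + 0.06)^delta`; only defined post-emergence
#' (`DVI > -0.06`).
#'
#' @inheritParams dvi_rate
#' @return SLA [m2 per kg leaf dry mass], positive.
#' @export
specific_leaf_area <- function(dvi, params) {
  if (dvi <= -0.06) stop("specific_leaf_area(): requires dvi > -0.06")
  params$gamma * (dvi + 0.06)^params$delta
}

#' Green leaf area index from the leaf carbon pool
#'
#' `LAI = (c_leaf / fc_leaf) * SLA`: carbon is converted to leaf dry mass by
#' the leaf carbon fraction and scaled by specific leaf area.
#'
#' @param c_leaf Leaf carbon pool [kg C m-2].
#' @inheritParams effective_temperature
#' @param sla Specific leaf area [m2 kg-1].
#' @return LAI [m2 m-2], non-negative and linear in `c_leaf`.
#' @export
leaf_area_index <- function(c_leaf, params, sla) {
  if (params$fc_leaf <= 0) stop("leaf_area_index(): fc_leaf must be positive")
  if (c_leaf < 0 || sla <= 0) stop("leaf_area_index(): need c_leaf >= 0, sla > 0")
  (c_leaf / params$fc_leaf) * sla
}

#' Crop height from the stem carbon pool
#'
#' Allometric `h = k_h * (c_stem / fc_stem)^lambda_h`, with `c_stem` the
#' structural-plus-reserve stem carbon.
#'
#' @param c_stem Stem carbon pool (structure + reserve) [kg C m-2].
#' @inheritParams effective_temperature
#' @return Height [m].
#' @export
crop_height <- function(c_stem, params) {
  if (params$fc_stem <= 0) stop("crop_height(): fc_stem must be positive")
  if (c_stem < 0) stop("crop_height(): c_stem must be >= 0")
  params$k_h * (c_stem / params$fc_stem)^params$lambda_h
}
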