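#' Crop parameter set for the maize growth simulator
#'
#' Bundles every cultivar/crop constant used by the daily simulator: the
#' cardinal temperatures of the thermal-time response, phase thermal-time
#' requirements, photoperiod response, softmax carbon-partition constants,
#' senescence and specific-leaf-area allometry, height allometry, carbon
#' fractions of organ dry mass, and the canopy radiation-use-efficiency
#' parameters of the carbon-gain model.
#'
#' Defaults describe a DKB390-like tropical maize hybrid grown in the
#' Brazilian off-season (sown February, ~110-day cycle at 25-26 degC).
#'
#' @param Tb,To,Tm Base, optimum and maximum temperature of development
#'   [degC]; development rate is a trapezoid between them (`Tb < To < Tm`).
#' @param TTemr,TTveg,TTrep Thermal time of the sowing-emergence,
#'   emergence-flowering and flowering-maturity phases [degC day].
#' @param Pcrit Critical photoperiod [h].
#' @param Psens Photoperiod sensitivity [h]; large values make the
#'   photoperiod effect negligible.
#' @param alpha,beta Named numeric vectors (names `leaf`, `stem`, `harvest`,
#'   `root`) of the softmax carbon-partition constants [dimensionless].
#' @param DVIsen Development-index threshold above which leaf senescence
#'   starts [DVI units, in (0,1)].
#' @param mu,nu Senescence allometry: daily leaf-loss fraction is
#'   `mu * (DVI - DVIsen)^nu`, capped at 1.
#' @param gamma,delta Specific-leaf-area allometry: `SLA = gamma *
#'   (DVI + 0.06)^delta` [m2 kg-1 dry mass and dimensionless].
#' @param k_h,lambda_h Height allometry: `h = k_h * (stem dry mass)^lambda_h`
#'   with stem dry mass in kg m-2.
#' @param fc_leaf,fc_stem,fc_grain Carbon fraction of leaf, stem (including
#'   reserve) and grain dry mass [0-1].
#' @param initial_carbon Carbon seeded into the pools at emergence
#'   [kg C m-2], split by the partition fractions at DVI = 0.
#' @param reserve_frac Fraction of the stem allocation routed to the
#'   remobilizable reserve pool [0-1].
#' @param remob_rate Daily fraction of the stem reserve remobilized to the
#'   harvest pool during the reproductive phase (DVI >= 1) [d-1].
#' @param rue Radiation-use efficiency of the canopy carbon-gain model
#'   [g C MJ-1 intercepted PAR].
#' @param k_ext Canopy extinction coefficient of the Beer-law interception
#'   term [dimensionless].
#' @return An object of class `crop_params` (a validated named list).
#' @seealso [read_crop_params()], [run_season()]
#' @export
crop_params <- function(Tb = 8, To = 30, Tm = 42,
                        TTemr = 90, TTveg = 1000, TTrep = 900,
                        Pcrit = 12.5, Psens = 100,
                        alpha = c(leaf = 0.8, stem = 0.5, harvest = -3.0, root = 1.0),
                        beta  = c(leaf = -1.2, stem = -0.6, harvest = 2.8, root = -2.0),
                        DVIsen = 0.4, mu = 0.015, nu = 2,
                        gamma = 14, delta = -0.2,
                        k_h = 2.8, lambda_h = 0.4,
                        fc_leaf = 0.40, fc_stem = 0.45, fc_grain = 0.45,
                        initial_carbon = 0.008,
                        reserve_frac = 0.2, remob_rate = 0.05,
                        rue = 1.3, k_ext = 0.6) {
  p <- list(Tb = Tb, To = To, Tm = Tm,
            TTemr = TTemr, TTveg = TTveg, TTrep = TTrep,
            Pcrit = Pcrit, Psens = Psens,
            alpha = alpha[ORGANS], beta = beta[ORGANS],
            DVIsen = DVIsen, mu = mu, nu = nu,
            gamma = gamma, delta = delta,
            k_h = k_h, lambda_h = lambda_h,
            fc_leaf = fc_leaf, fc_stem = fc_stem, fc_grain = fc_grain,
            initial_carbon = initial_carbon,
            reserve_frac = reserve_frac, remob_rate = remob_rate,
            rue = rue, k_ext = k_ext)
  class(p) <- "crop_params"
  validate_crop_params(p)
  p
}

ORGANS <- c("leaf", "stem", "harvest", "root")

validate_crop_params <- function(p) {
  stopifnot(inherits(p, "crop_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("Tb", "To", "Tm", "TTemr", "TTveg", "TTrep", "Pcrit", "Psens",
              "DVIsen", "mu", "nu", "gamma", "delta", "k_h", "lambda_h",
              "fc_leaf", "fc_stem", "fc_grain", "initial_carbon",
              "reserve_frac", "remob_rate", "rue", "k_ext"))
    if (!num1(p[[f]])) stop("crop_params: field '", f, "' must be a finite number")
  if (!(p$Tb < p$To && p$To < p$Tm))
    stop("crop_params: need Tb < To < Tm")
  if (any(c(p$TTemr, p$TTveg, p$TTrep) <= 0))
    stop("crop_params: thermal-time requirements must be positive")
  if (p$Psens == 0) stop("crop_params: Psens must be nonzero")
  for (f in c("fc_leaf", "fc_stem", "fc_grain"))
    if (p[[f]] <= 0 || p[[f]] > 1) stop("crop_params: ", f, " must lie in (0,1]")
  if (p$DVIsen <= 0 || p$DVIsen >= 1)
    stop("crop_params: DVIsen must lie in (0,1)")
  if (p$rue <= 0 || p$k_ext <= 0)
    stop("crop_params: rue and k_ext must be positive")
  if (p$reserve_frac < 0 || p$reserve_frac > 1 ||
      p$remob_rate < 0 || p$remob_rate > 1)
    stop("crop_params: reserve_frac and remob_rate must lie in [0,1]")
  for (f in c("alpha", "beta")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 4L || !all(is.finite(v)) ||
        !identical(names(v), ORGANS))
      stop("crop_params: '", f, "' must be finite and named ",
           paste(ORGANS, collapse = ", "))
  }
  invisible(p)
}

#' @export
print.crop_params <- function(x, ...) {
  cat("Maize crop parameter set\n")
  cat(sprintf("  cardinal temperatures: Tb=%g To=%g Tm=%g degC\n", x$Tb, x$To, x$Tm))
  cat(sprintf("  thermal time: emergence %g, vegetative %g, reproductive %g degC day\n",
              x$TTemr, x$TTveg, x$TTrep))
  cat(sprintf("  photoperiod: Pcrit=%g h, Psens=%g h\n", x$Pcrit, x$Psens))
  cat("  partition constants (alpha; beta):\n")
  for (o in ORGANS)
    cat(sprintf("    %-8s %6.2f; %6.2f\n", o, x$alpha[[o]], x$beta[[o]]))
  cat(sprintf("  senescence: DVIsen=%g mu=%g nu=%g\n", x$DVIsen, x$mu, x$nu))
  cat(sprintf("  canopy: gamma=%g delta=%g  rue=%g gC/MJ  k_ext=%g\n",
              x$gamma, x$delta, x$rue, x$k_ext))
  invisible(x)
}

#' Read or write a crop parameter file
#'
#' Parameter files are flat key-value YAML; the vector-valued partition
#' constants are stored as `alpha_leaf`, `beta_root`, etc.  A default file
#' is shipped under `system.file("extdata", "maize_default.yaml",
#' package = "maizecast")`.
#'
#' @param path File path.
#' @return `read_crop_params()` returns a [crop_params()] object;
#'   `write_crop_params()` returns `path` invisibly.
#' @export
read_crop_params <- function(path) {
  kv <- yaml::read_yaml(path)
  args <- kv[!grepl("^(alpha|beta)_", names(kv))]
  args$alpha <- vapply(ORGANS, function(o) as.numeric(kv[[paste0("alpha_", o)]]), 0)
  args$beta  <- vapply(ORGANS, function(o) as.numeric(kv[[paste0("beta_", o)]]), 0)
  do.call(crop_params, args)
}

#' @rdname read_crop_params
#' @param params A [crop_params()] object.
#' @export
write_crop_params <- function(params, path) {
  validate_crop_params(params)
  kv <- unclass(params)
  for (o in ORGANS) {
    kv[[paste0("alpha_", o)]] <- unname(params$alpha[[o]])
    kv[[paste0("beta_", o)]] <- unname(params$beta[[o]])
  }
  kv$alpha <- NULL
  kv$beta <- NULL
  yaml::write_yaml(kv, path)
  invisible(path)
}
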