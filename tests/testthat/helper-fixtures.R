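# Shared fixtures: tiny parameter sets and deterministic weather builders.

# parameters with round numbers for hand-checkable arithmetic
toy_params <- function(...) {
  crop_params(Tb = 8, To = 30, Tm = 42,
              TTemr = 220, TTveg = 1100, TTrep = 1100,
              Pcrit = 24, Psens = 100,   # RPE clamps to 1 for any real day
              ...)
}

# constant-weather season: tmean fixed, no rain unless asked
constant_weather <- function(n_days = 200, tmean = 30, rain = 0, srad = 18,
                             start = as.Date("2003-02-01")) {
  data.frame(date = start + seq_len(n_days) - 1,
             tmean = tmean, tmin = tmean - 5, tmax = tmean + 5,
             rain = rain, srad = srad)
}

# one shared synthetic study per test run (generation is the slow part)
.study_cache <- new.env(parent = emptyenv())
cached_study <- function(seed = 3) {
  key <- as.character(seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- generate_study(seed = seed)
  .study_cache[[key]]
}

random_params <- function() {
  crop_params(Tb = runif(1, 5, 10), To = runif(1, 25, 32), Tm = runif(1, 38, 45),
              TTemr = runif(1, 50, 150), TTveg = runif(1, 600, 1200),
              TTrep = runif(1, 500, 1100),
              Pcrit = runif(1, 11, 14), Psens = runif(1, 20, 200),
              alpha = setNames(runif(4, -2, 2), c("leaf", "stem", "harvest", "root")),
              beta = setNames(runif(4, -3, 3), c("leaf", "stem", "harvest", "root")),
              DVIsen = runif(1, 0.2, 0.8), mu = runif(1, 0.005, 0.1),
              nu = runif(1, 0.5, 3),
              gamma = runif(1, 10, 25), delta = runif(1, -0.5, 0.2),
              k_h = runif(1, 1, 4), lambda_h = runif(1, 0.2, 1),
              fc_leaf = runif(1, 0.3, 0.5), fc_stem = runif(1, 0.3, 0.5),
              fc_grain = runif(1, 0.3, 0.5))
}
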