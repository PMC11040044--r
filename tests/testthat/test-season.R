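# Daily step assembly and whole-season behaviour.

test_that("no thermal time means no development", {
  p <- toy_params()
  wx <- constant_weather(160, tmean = p$Tb)     # zero effective temperature
  s <- run_season(wx, wx$date[1] + 5, p, soil_profile())
  expect_false(attr(s, "complete"))
  expect_true(all(s$dvi == -1))
  expect_true(all(s$gdm == 0))
})

test_that("harvest day follows thermal-time bookkeeping exactly", {
  # constant tmean = To gives Teff = To - Tb = 22 each day; with phase
  # requirements of 10u / 50u / 50u (u = 22) the phases take 10, 50 and 50
  # whole days: maturity on day 110
  p <- toy_params()   # TTemr 220, TTveg 1100, TTrep 1100; RPE clamped to 1
  wx <- constant_weather(160, tmean = 30, rain = 4)
  s <- run_season(wx, wx$date[1] + 5, p, soil_profile())
  expect_equal(attr(s, "harvest_day"), 110)
  expect_equal(s$dvi[10], 0)     # emergence
  expect_equal(s$dvi[60], 1)     # flowering
  expect_equal(s$dvi[110], 2)    # maturity
})

test_that("simulation is deterministic and DVI is monotone with absorbing harvest", {
  p <- crop_params()
  wx <- generate_weather(climate_spec(), n_days = 170, seed = 5,
                         start_date = as.Date("2004-01-20"))
  s1 <- run_season(wx, as.Date("2004-02-01"), p, soil_profile(), horizon = 120)
  s2 <- run_season(wx, as.Date("2004-02-01"), p, soil_profile(), horizon = 120)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$dvi) >= 0))
  expect_lte(max(s1$dvi), 2)
  hd <- attr(s1, "harvest_day")
  expect_true(all(s1$dvi[hd:nrow(s1)] == 2))   # absorbing after harvest
  expect_true(all(s1$fsmc >= 0 & s1$fsmc <= 1))
  expect_true(all(s1$ldm >= 0 & s1$gdm >= 0 & s1$lai >= 0))
})

test_that("carbon and water ledgers close over a full season", {
  p <- crop_params()
  for (seed in c(2, 9)) {
    wx <- generate_weather(climate_spec(), n_days = 170, seed = seed,
                           start_date = as.Date("2005-01-20"))
    for (mode in c("water_limited", "potential")) {
      s <- run_season(wx, as.Date("2005-02-01"), p, soil_profile(), mode = mode,
                      horizon = 120)
      led <- attr(s, "carbon_ledger")
      expect_lt(abs(led[["cum_npp"]] + led[["cum_seed"]] -
                      led[["cum_senescence"]] - led[["final_pools"]]), 1e-9)
      wl <- attr(s, "water_ledger")
      expect_lt(abs(wl[["rain"]] - wl[["drainage"]] - wl[["et"]] -
                      wl[["storage_change"]]), 1e-9)
    }
  }
})

test_that("potential production dominates water-limited production", {
  p <- crop_params()
  # dry season: rainfall collapses after day 30
  spec <- climate_spec(wet_prob = 0.5, decay = 0.05, decay_start = 30)
  wx <- generate_weather(spec, n_days = 170, seed = 21,
                         start_date = as.Date("2006-01-20"))
  s_wl <- run_season(wx, as.Date("2006-02-01"), p, soil_profile(), "water_limited",
                     horizon = 120)
  s_p <- run_season(wx, as.Date("2006-02-01"), p, soil_profile(), "potential",
                    horizon = 120)
  expect_true(all(s_p$gdm >= s_wl$gdm - 1e-12))
  expect_gt(attr(s_p, "yield"), attr(s_wl, "yield"))
  expect_lt(min(s_wl$fsmc), 0.5)   # the drought actually bites
})

test_that("zero carbon gain freezes the pools until senescence", {
  p <- crop_params(rue = 1e-12)    # effectively no photosynthesis
  wx <- constant_weather(160, tmean = 28, rain = 4)
  s <- run_season(wx, wx$date[1] + 5, p, soil_profile())
  hd <- which(s$dvi >= p$DVIsen)[1]
  pre <- s[s$dvi >= 0 & seq_len(nrow(s)) < hd, ]
  expect_lt(diff(range(pre$sdm)), 1e-9)        # stem frozen before senescence
  expect_lt(max(s$gdm), 0.2)                   # only remobilized seed carbon
})

test_that("season I/O round-trips and malformed files are rejected", {
  p <- crop_params()
  wx <- generate_weather(climate_spec(), n_days = 170, seed = 3,
                         start_date = as.Date("2007-01-20"))
  s <- run_season(wx, as.Date("2007-02-01"), p, soil_profile(), horizon = 120)
  f <- withr::local_tempfile(fileext = ".csv")
  write_season(s, f)
  s2 <- read_season(f)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$gdm, s$gdm, tolerance = 1e-6)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("das,dvi,ldm", bad)
  expect_error(read_season(bad), "missing column")
  expect_error(run_season(wx, as.Date("1999-01-01"), p, soil_profile()),
               "sowing date")
})
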