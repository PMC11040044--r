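# Phenology and allometry building blocks against hand-computed oracles.

test_that("effective temperature follows the trapezoidal response", {
  p <- crop_params(Tb = 8, To = 30, Tm = 42)
  expect_equal(effective_temperature(8, p), 0)            # base boundary
  expect_equal(effective_temperature(30, p), 22)          # optimum plateau edge
  expect_equal(effective_temperature(36, p), 11)          # 22 * (1 - 6/12)
  expect_equal(effective_temperature(5, p), 0)
  expect_equal(effective_temperature(42, p), 0)
  expect_equal(effective_temperature(50, p), 0)
  # continuity at the three break points on a 0.01 degC grid
  for (brk in c(p$Tb, p$To, p$Tm)) {
    grid <- seq(brk - 0.05, brk + 0.05, by = 0.01)
    vals <- effective_temperature(grid, p)
    expect_lt(max(abs(diff(vals))), 0.011 * 2)
  }
  # range invariant over random draws
  set.seed(1)
  for (i in 1:50) {
    pp <- random_params()
    t <- runif(1, -5, 55)
    te <- effective_temperature(t, pp)
    expect_gte(te, 0)
    expect_lte(te, pp$To - pp$Tb + 1e-12)
  }
})

test_that("relative photoperiod effect is the clamped linear penalty", {
  p <- crop_params(Pcrit = 12.5, Psens = 100)
  expect_equal(relative_photoperiod_effect(12.5, p), 1)
  expect_equal(relative_photoperiod_effect(12.5 + 100, p), 0)
  expect_equal(relative_photoperiod_effect(13.0, p), 0.995)
  expect_equal(relative_photoperiod_effect(10, p), 1)      # clamp above
  p2 <- crop_params(Pcrit = 12, Psens = 0.1)
  expect_equal(relative_photoperiod_effect(14, p2), 0)     # clamp below
})

test_that("development rate branches by phase and rejects pre-sowing state", {
  p <- crop_params(TTemr = 100, TTveg = 900, TTrep = 800)
  expect_equal(dvi_rate(100, -0.5, 1, p), 1)     # whole emergence phase in a day
  expect_equal(dvi_rate(0, 0.5, 1, p), 0)
  expect_equal(dvi_rate(18, 0.3, 0.9, p), 0.018) # (18/900) * 0.9
  expect_equal(dvi_rate(16, 1.5, 0.2, p), 16 / 800)  # RPE only vegetative
  expect_equal(dvi_rate(20, 2, 1, p), 0)         # maturity is absorbing
  expect_error(dvi_rate(10, -1.5, 1, p), "pre-sowing")
})

test_that("partition fractions are a normalized softmax", {
  p0 <- crop_params()
  p0$alpha[] <- 0; p0$beta[] <- 0
  expect_equal(unname(partition_fractions(0.7, p0)), rep(0.25, 4))
  p1 <- crop_params()
  p1$alpha[] <- c(1, 0, 0, 0); p1$beta[] <- 0
  fr <- partition_fractions(0, p1)
  expect_equal(unname(fr),
               c(exp(1), 1, 1, 1) / (exp(1) + 3))
  # normalization to machine precision over many random draws
  set.seed(42)
  for (i in 1:2000) {
    pp <- crop_params()
    pp$alpha[] <- runif(4, -3, 3); pp$beta[] <- runif(4, -3, 3)
    fr <- partition_fractions(runif(1, -1, 2), pp)
    expect_lt(abs(sum(fr) - 1), 1e-12)
    expect_true(all(fr > 0 & fr < 1))
  }
  # overflow safety with extreme constants
  pe <- crop_params()
  pe$alpha[] <- c(500, 0, 0, 0); pe$beta[] <- c(200, 0, 0, 0)
  fr <- partition_fractions(2, pe)
  expect_true(all(is.finite(fr)))
  expect_equal(sum(fr), 1)
})

test_that("senescence fraction starts at the threshold and is capped", {
  expect_equal(senescence_fraction(0.3, crop_params(DVIsen = 0.4)), 0)
  expect_equal(senescence_fraction(0.4, crop_params(DVIsen = 0.4)), 0)
  expect_equal(senescence_fraction(1.4, crop_params(DVIsen = 0.4, mu = 1, nu = 1)), 1)
  expect_equal(senescence_fraction(0.9, crop_params(DVIsen = 0.4, mu = 0.05, nu = 2)),
               0.0125)
})

test_that("specific leaf area, LAI and height follow their allometries", {
  expect_equal(specific_leaf_area(1.5, crop_params(gamma = 20, delta = 0)), 20)
  expect_equal(specific_leaf_area(0.94, crop_params(gamma = 20, delta = -0.2)), 20)
  expect_equal(specific_leaf_area(1.94, crop_params(gamma = 18, delta = -0.1)),
               18 * 2^(-0.1))
  expect_error(specific_leaf_area(-0.2, crop_params()), "dvi")

  p <- crop_params(fc_leaf = 0.4)
  expect_equal(leaf_area_index(0, p, 18), 0)
  expect_equal(leaf_area_index(0.05, p, 18), 2.25)
  expect_equal(leaf_area_index(0.10, p, 18), 2 * leaf_area_index(0.05, p, 18))

  expect_equal(crop_height(0, crop_params(k_h = 2, lambda_h = 0.4)), 0)
  expect_equal(crop_height(0.2, crop_params(k_h = 1, lambda_h = 1, fc_stem = 0.5)),
               0.4)
  expect_equal(crop_height(0.45, crop_params(k_h = 3.5, lambda_h = 0.4,
                                             fc_stem = 0.45)), 3.5)
})

test_that("parameter validation catches inconsistent sets", {
  expect_error(crop_params(Tb = 30, To = 20), "Tb < To < Tm")
  expect_error(crop_params(fc_leaf = 0), "fc_leaf")
  expect_error(crop_params(DVIsen = 1.2), "DVIsen")
  expect_error(crop_params(Psens = 0), "Psens")
  expect_error(crop_params(TTveg = -5), "thermal-time")
})

test_that("parameter files round-trip through the key-value format", {
  p <- crop_params(Tb = 9.5, rue = 1.4)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_crop_params(p, f)
  q <- read_crop_params(f)
  expect_equal(unclass(q), unclass(p))
})
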