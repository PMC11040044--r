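# The per-window forecasting model object and its methods.

test_that("the fitted object carries coherent diagnostics", {
  st <- cached_study()
  fit <- yield_forecast(st$indicators, st$yields)
  d <- fit$diagnostics
  expect_equal(d$window, seq(10, 120, 10))
  expect_true(all(is.finite(d$sdep) & d$sdep > 0))
  expect_true(all(d$ef <= 1))
  expect_true(all(d$vif_max[!is.na(d$vif_max)] <= 5))
  expect_true(all(d$dw[!is.na(d$dw)] >= 0 & d$dw[!is.na(d$dw)] <= 4))
  expect_true(all(is.na(d$dw_decision) |
                    d$dw_decision %in% c("accepted", "rejected", "inconclusive")))
  # selection map is binary and consistent with the window models
  expect_true(all(fit$selection %in% 0:1))
  for (w in c("80", "120"))
    expect_setequal(colnames(fit$selection)[fit$selection[w, ] == 1],
                    fit$window_models[[w]]$selected)
  # every selected regressor comes from the allowed groups
  wl_agro <- c(paste0(c("LDM", "SDM", "GDM", "CH", "LAI", "FSMC", "SWC"), "_Yw"),
               "TMED", "RAIN", "DIFF_RAD")
  expect_true(all(colnames(fit$selection) %in% wl_agro))
})

test_that("refitting with identical inputs is deterministic", {
  st <- cached_study()
  f1 <- yield_forecast(st$indicators, st$yields)
  f2 <- yield_forecast(st$indicators, st$yields)
  expect_equal(f1$diagnostics, f2$diagnostics)
  expect_equal(coef(f1), coef(f2))
})

test_that("two windows with identical candidate columns give identical models", {
  st <- cached_study()
  ind <- st$indicators
  dup <- ind[ind$window == 120, ]
  dup$window <- 130
  ind2 <- rbind(ind, dup)
  fit <- yield_forecast(ind2, st$yields, windows = c(120, 130))
  m1 <- fit$window_models[["120"]]; m2 <- fit$window_models[["130"]]
  expect_equal(m1$selected, m2$selected)
  expect_equal(m1$coef, m2$coef)
  expect_equal(m1$cv$sdep, m2$cv$sdep)
})

test_that("predictions re-trend onto the original yield scale", {
  st <- cached_study()
  fit <- yield_forecast(st$indicators, st$yields)
  pr <- predict(fit, window = 120)
  expect_equal(pr$year, st$yields$year)
  # re-trended LOO predictions approximate the observed yields
  expect_lt(sqrt(mean((pr$forecast - st$yields$yield)^2)), 0.7)
  # predicting the training indicators through newdata reproduces the
  # in-sample linear predictor plus trend
  m <- fit$window_models[["120"]]
  pr2 <- predict(fit, newdata = st$indicators, window = 120)
  M <- indicator_design(st$indicators, 120, fit$groups)
  lin <- drop(cbind(1, M[, m$selected, drop = FALSE]) %*% m$coef)
  retr <- lin + fit$trend$intercept + fit$trend$slope * st$yields$year -
    fit$trend$mean
  expect_equal(pr2$forecast, unname(retr))
})

test_that("residuals and summary expose the per-window fits", {
  st <- cached_study()
  fit <- yield_forecast(st$indicators, st$yields)
  r_ols <- residuals(fit, window = 120, type = "ols")
  expect_lt(abs(mean(r_ols)), 1e-10)       # OLS residuals sum to zero
  s <- summary(fit)
  expect_true(all(c("window", "ef", "sdep", "regressors") %in% names(s)))
  expect_output(print(s), "window")
  expect_output(print(fit), "best window")
})

test_that("group restriction changes the candidate set", {
  st <- cached_study()
  fit_a <- yield_forecast(st$indicators, st$yields, groups = "agromet")
  expect_true(all(colnames(fit_a$selection) %in% c("TMED", "RAIN", "DIFF_RAD")))
  fit_p <- yield_forecast(st$indicators, st$yields, groups = "potential")
  expect_true(all(grepl("_Yp$", colnames(fit_p$selection))))
  cg <- compare_groups(st$indicators, st$yields,
                       group_sets = list(agromet = "agromet",
                                         wl = "water_limited"))
  expect_setequal(unique(cg$config), c("agromet", "wl"))
  expect_equal(nrow(cg), 2 * 12)
})

test_that("per-fold re-selection is available and never beats the fixed set unfairly", {
  st <- cached_study()
  fit <- yield_forecast(st$indicators, st$yields, windows = 120,
                        reselect_folds = TRUE)
  expect_true(is.finite(fit$diagnostics$sdep))
})

test_that("misaligned year axes are rejected", {
  st <- cached_study()
  y <- st$yields
  y$year <- y$year + 100
  expect_error(yield_forecast(st$indicators, y), "year axis")
  expect_error(yield_forecast(st$indicators, st$yields[1:5, ]), "8 years")
})
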