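# Detrending, VIF, Durbin-Watson and the goodness-of-fit suite.

test_that("detrending removes a linear technological trend", {
  # palindromic series: exactly zero OLS slope, so detrending is the identity
  flat <- data.frame(year = 2003:2012,
                     yield = c(5.2, 4.8, 5.1, 4.9, 5, 5, 4.9, 5.1, 4.8, 5.2))
  d <- detrend_yields(flat)
  expect_equal(d$detrended, flat$yield, tolerance = 1e-10)
  # perfect line becomes constant at the mean
  line <- data.frame(year = 2003:2016, yield = 2 + 0.1 * (2003:2016 - 2003))
  d <- detrend_yields(line)
  expect_equal(d$detrended, rep(mean(line$yield), 14))
  expect_equal(attr(d, "slope"), 0.1)
  # 5-point toy series against the normal-equations oracle
  toy <- data.frame(year = 1:5, yield = c(1, 2, 2, 4, 6))
  slope <- sum((1:5 - 3) * (toy$yield - 3)) / sum((1:5 - 3)^2)   # 12/10
  icpt <- 3 - slope * 3
  d <- detrend_yields(toy)
  expect_equal(attr(d, "slope"), slope)
  expect_equal(d$detrended, toy$yield - (icpt + slope * (1:5)) + 3)
  # re-fit on detrended values has zero slope
  refit <- detrend_yields(data.frame(year = 1:5, yield = d$detrended))
  expect_lt(abs(attr(refit, "slope")), 1e-10)
  expect_error(detrend_yields(toy[1:3, ]), "5 years")
})

test_that("VIF matches per-column regression and flags collinearity", {
  # orthogonal centered columns (orthogonal basis including the intercept
  # direction): all VIF exactly 1
  set.seed(14)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(14 * 3), 14, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_lt(max(abs(colMeans(X))), 1e-12)          # centered
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)
  # duplicated column is infinite and named
  Xd <- cbind(X[, 1:2], d = X[, 1])
  v <- vif(Xd)
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["d"]]))
  expect_setequal(attr(v, "collinear"), c("a", "d"))
  # random designs against an independent lm-based oracle
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:20, 1); p <- sample(2:5, 1)
    M <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, letters[1:p]))
    v <- vif(M)
    for (j in seq_len(p)) {
      r2 <- summary(lm(M[, j] ~ M[, -j]))$r.squared
      expect_equal(v[[j]], 1 / (1 - r2), tolerance = 1e-8)
    }
    expect_true(all(v >= 1 - 1e-12))
  }
  # cross-check against car's implementation on one design
  M <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- rnorm(15)
  vc <- car::vif(lm(y ~ M[, 1] + M[, 2] + M[, 3]))
  expect_equal(unname(vif(M)), unname(vc), tolerance = 1e-8)
})

test_that("Durbin-Watson statistic and tabulated decision behave", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)       # 12/4 by hand
  expect_equal(durbin_watson(rep(2, 6)), 0)             # no successive change
  expect_error(durbin_watson(rep(0, 5)), "all-zero")
  expect_error(durbin_watson(c(1, 2)), "at least 3")
  set.seed(99)
  expect_lt(abs(durbin_watson(rnorm(1e4)) - 2), 0.05)   # white-noise limit
  # against lmtest on a real regression fit
  set.seed(12)
  x <- rnorm(14); y <- 1 + 0.5 * x + rnorm(14)
  fit <- lm(y ~ x)
  expect_equal(durbin_watson(residuals(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
  # decision rules
  expect_equal(as.character(dw_decision(3.9, 14, 2)), "accepted")
  expect_equal(as.character(dw_decision(0.05, 14, 2)), "rejected")
  mid <- mean(c(attr(dw_decision(1, 14, 2), "dL"), attr(dw_decision(1, 14, 2), "dU")))
  expect_equal(as.character(dw_decision(mid, 14, 2)), "inconclusive")
  expect_error(dw_decision(1.5, 40, 2), "outside the tabulated range")
  expect_error(dw_decision(1.5, 14, 6), "outside the tabulated range")
  expect_error(dw_decision(1.5, 14, 2, alpha = 0.01), "5%")
})

test_that("goodness-of-fit suite matches hand evaluation", {
  obs <- c(1, 2, 3, 4)
  g <- goodness_of_fit(obs, obs)
  expect_equal(c(g$r2, g$d, g$ef), c(1, 1, 1))
  g0 <- goodness_of_fit(rep(mean(obs), 4), obs)
  expect_equal(g0$ef, 0)                                # the null model
  pred <- c(1.1, 1.9, 3.2, 3.8)
  g <- goodness_of_fit(pred, obs)
  sse <- 0.01 + 0.01 + 0.04 + 0.04
  expect_equal(g$ef, 1 - sse / 5)
  expect_equal(g$d, 1 - sse / (2.9^2 + 1.1^2 + 1.2^2 + 2.8^2))
  sxy <- sum((pred - mean(pred)) * (obs - mean(obs)))
  expect_equal(g$r2, sxy^2 / (sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2)))
  expect_equal(g$rmse, sqrt(sse / 4))
  expect_error(goodness_of_fit(pred, rep(1, 4)), "constant")
  # EF <= R2 for OLS fitted values; d bounded in [0,1]
  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(12); y <- 1 + x + rnorm(12)
    f <- fitted(lm(y ~ x))
    g <- goodness_of_fit(f, y)
    expect_lte(g$ef, g$r2 + 1e-12)
    expect_gte(g$d, 0); expect_lte(g$d, 1)
    expect_lte(g$ef, 1)
  }
})
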