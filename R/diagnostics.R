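# Regression diagnostics: detrending, VIF, Durbin-Watson, goodness of fit.

#' Detrend an annual yield series
#'
#' Removes the technological trend by ordinary least squares of yield on
#' calendar year; the detrended series is residual + series mean, so it
#' keeps the original scale.  Forecasts on the detrended scale are
#' re-trended by adding the fitted trend at the target year and subtracting
#' the mean (see [predict.yield_forecast()]).
#'
#' @param yields `data.frame` with columns `year` (integer) and `yield`
#'   [Mg ha-1]; at least 5 distinct years.
#' @return The input `data.frame` with an added `detrended` column and
#'   attributes `slope` [Mg ha-1 yr-1], `intercept` and `mean`.
#' @export
detrend_yields <- function(yields) {
  stopifnot(all(c("year", "yield") %in% names(yields)))
  if (nrow(yields) < 5) stop("detrend_yields(): need at least 5 years")
  if (length(unique(yields$year)) < 2) stop("detrend_yields(): constant years")
  yields <- yields[order(yields$year), , drop = FALSE]
  fit <- stats::lm(yield ~ year, data = yields)
  yields$detrended <- stats::residuals(fit) + mean(yields$yield)
  structure(yields,
            slope = unname(stats::coef(fit)[2]),
            intercept = unname(stats::coef(fit)[1]),
            mean = mean(yields$yield))
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R2_i)` where `R2_i` comes from regressing column `i`
#' on all remaining columns (with intercept).  A single column has VIF 1 by
#' convention; exact collinearity is reported as `Inf` with the offending
#' columns named in the `collinear` attribute.
#'
#' @param X Numeric design matrix (no intercept column); columns must be
#'   non-constant and `nrow(X) > ncol(X) + 1`.
#' @return Named numeric vector of VIFs, each >= 1 (up to rounding).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (any(apply(X, 2, stats::sd) == 0)) stop("vif(): constant column in design")
  if (p == 1) return(stats::setNames(1, colnames(X)))
  if (nrow(X) <= p + 1) stop("vif(): need n > p + 1")
  out <- stats::setNames(numeric(p), colnames(X))
  for (i in seq_len(p)) {
    yi <- X[, i]
    Zi <- cbind(1, X[, -i, drop = FALSE])
    fit <- stats::lm.fit(Zi, yi)
    rss <- sum(fit$residuals^2)
    tss <- sum((yi - mean(yi))^2)
    r2 <- 1 - rss / tss
    out[i] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out)))
    attr(out, "collinear") <- names(out)[!is.finite(out)]
  out
}

#' Durbin-Watson statistic
#'
#' `DW = sum_{t=2..n} (e_t - e_{t-1})^2 / sum_t e_t^2` on residuals ordered
#' by year; ranges over `[0, 4]`, with 2 indicating no first-order
#' autocorrelation.
#'
#' @param residuals Numeric residual vector in time order, length >= 3, not
#'   all zero.
#' @return The DW statistic.
#' @export
durbin_watson <- function(residuals) {
  n <- length(residuals)
  if (n < 3) stop("durbin_watson(): need at least 3 residuals")
  if (all(residuals == 0)) stop("durbin_watson(): undefined for all-zero residuals")
  sum(diff(residuals)^2) / sum(residuals^2)
}

# 5% lower (dL) and upper (dU) Durbin-Watson critical bounds for n = 6..30
# observations and k = 1..5 regressors (excluding the intercept); NA where
# the bound is not tabulated (n too small for k).
dw_bounds_5pct <- local({
  n <- 6:30
  dl <- cbind(
    k1 = c(0.610, 0.700, 0.763, 0.824, 0.879, 0.927, 0.971, 1.010, 1.045,
           1.077, 1.106, 1.133, 1.158, 1.180, 1.201, 1.221, 1.239, 1.257,
           1.273, 1.288, 1.302, 1.316, 1.328, 1.341, 1.352),
    k2 = c(NA, 0.467, 0.559, 0.629, 0.697, 0.758, 0.812, 0.861, 0.905,
           0.946, 0.982, 1.015, 1.046, 1.074, 1.100, 1.125, 1.147, 1.168,
           1.188, 1.206, 1.224, 1.240, 1.255, 1.270, 1.284),
    k3 = c(NA, NA, 0.368, 0.455, 0.525, 0.595, 0.658, 0.715, 0.767, 0.814,
           0.857, 0.897, 0.933, 0.967, 0.998, 1.026, 1.053, 1.078, 1.101,
           1.123, 1.143, 1.162, 1.181, 1.198, 1.214),
    k4 = c(NA, NA, NA, 0.296, 0.376, 0.444, 0.512, 0.574, 0.632, 0.685,
           0.734, 0.779, 0.820, 0.859, 0.894, 0.927, 0.958, 0.986, 1.013,
           1.038, 1.062, 1.084, 1.104, 1.124, 1.143),
    k5 = c(NA, NA, NA, NA, 0.243, 0.316, 0.379, 0.445, 0.505, 0.562, 0.615,
           0.664, 0.710, 0.752, 0.792, 0.829, 0.863, 0.895, 0.925, 0.953,
           0.979, 1.004, 1.028, 1.050, 1.071))
  du <- cbind(
    k1 = c(1.400, 1.356, 1.332, 1.320, 1.320, 1.324, 1.331, 1.340, 1.350,
           1.361, 1.371, 1.381, 1.391, 1.401, 1.411, 1.420, 1.429, 1.437,
           1.446, 1.454, 1.461, 1.469, 1.476, 1.483, 1.489),
    k2 = c(NA, 1.896, 1.777, 1.699, 1.641, 1.604, 1.579, 1.562, 1.551,
           1.543, 1.539, 1.536, 1.535, 1.536, 1.537, 1.538, 1.541, 1.543,
           1.546, 1.550, 1.553, 1.556, 1.560, 1.563, 1.567),
    k3 = c(NA, NA, 2.287, 2.128, 2.016, 1.928, 1.864, 1.816, 1.779, 1.750,
           1.728, 1.710, 1.696, 1.685, 1.676, 1.669, 1.664, 1.660, 1.656,
           1.654, 1.652, 1.651, 1.650, 1.650, 1.650),
    k4 = c(NA, NA, NA, 2.588, 2.414, 2.283, 2.177, 2.094, 2.030, 1.977,
           1.935, 1.900, 1.872, 1.848, 1.828, 1.812, 1.797, 1.785, 1.775,
           1.767, 1.759, 1.753, 1.747, 1.743, 1.739),
    k5 = c(NA, NA, NA, NA, 2.822, 2.645, 2.506, 2.390, 2.296, 2.220, 2.157,
           2.104, 2.060, 2.023, 1.991, 1.964, 1.940, 1.920, 1.902, 1.886,
           1.873, 1.861, 1.850, 1.841, 1.833))
  rownames(dl) <- rownames(du) <- n
  list(n = n, dl = dl, du = du)
})

#' Durbin-Watson accept/reject/inconclusive decision
#'
#' Compares the DW statistic with the tabulated 5% lower (`dL`) and upper
#' (`dU`) critical bounds: the null hypothesis of no positive first-order
#' autocorrelation is `accepted` when `dw > dU`, `rejected` when `dw < dL`,
#' and the test is `inconclusive` between the bounds.
#'
#' @param dw The DW statistic.
#' @param n Number of observations (years); tabulated for 6..30.
#' @param k Number of regressors excluding the intercept; tabulated for
#'   1..5.
#' @param alpha Significance level; only 0.05 is tabulated.
#' @return One of `"accepted"`, `"rejected"`, `"inconclusive"`; the `dL`
#'   and `dU` bounds used are attached as attributes.
#' @export
dw_decision <- function(dw, n, k, alpha = 0.05) {
  if (alpha != 0.05)
    stop("dw_decision(): only the 5% critical-value table is embedded")
  tb <- dw_bounds_5pct
  if (!(n %in% tb$n) || !(k %in% 1:5))
    stop("dw_decision(): (n = ", n, ", k = ", k,
         ") outside the tabulated range (n in 6..30, k in 1..5)")
  dl <- tb$dl[as.character(n), k]
  du <- tb$du[as.character(n), k]
  if (is.na(dl))
    stop("dw_decision(): bounds not tabulated for n = ", n, ", k = ", k)
  decision <- if (dw > du) "accepted" else if (dw < dl) "rejected" else "inconclusive"
  structure(decision, dL = unname(dl), dU = unname(du))
}

#' Goodness-of-fit suite
#'
#' Computes the coefficient of determination (squared Pearson correlation),
#' Willmott's bounded index of agreement
#' `d = 1 - sum((p-o)^2) / sum((|p-obar| + |o-obar|)^2)`,
#' the Nash-Sutcliffe modeling efficiency
#' `EF = 1 - sum((p-o)^2) / sum((o-obar)^2)`, and the root mean squared
#' error.
#'
#' @param pred,obs Numeric vectors of equal length >= 3; `obs` must not be
#'   constant.
#' @return A list with elements `r2`, `d`, `ef`, `rmse`.  `d` lies in
#'   `[0, 1]`; `EF` in `(-Inf, 1]`, 0 for the observed-mean null model.
#' @export
goodness_of_fit <- function(pred, obs) {
  n <- length(obs)
  if (length(pred) != n || n < 3)
    stop("goodness_of_fit(): need equal lengths >= 3")
  if (stats::sd(obs) == 0) stop("goodness_of_fit(): constant observations")
  sse <- sum((pred - obs)^2)
  sso <- sum((obs - mean(obs))^2)
  dd <- sum((abs(pred - mean(obs)) + abs(obs - mean(obs)))^2)
  list(r2 = if (stats::sd(pred) == 0) 0 else stats::cor(pred, obs)^2,
       d = if (dd == 0) 1 else 1 - sse / dd,
       ef = 1 - sse / sso,
       rmse = sqrt(sse / n))
}
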