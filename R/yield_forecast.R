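# The per-window yield forecasting model: fitting function and S3 methods.

#' Build the candidate design matrix for one forecasting window
#'
#' Reshapes the long national indicator table into a year x regressor
#' matrix for the given window, restricted to the requested regressor
#' groups.  Constant (zero-variance) columns -- e.g. grain dry mass before
#' grain filling -- are dropped and recorded in the `dropped` attribute.
#'
#' @param indicators National long indicator `data.frame` with columns
#'   `year`, `window`, `level`, `name`, `value`.
#' @param window Window day.
#' @param groups Character subset of `c("potential", "water_limited",
#'   "agromet")`.
#' @return Numeric matrix (years x regressors) with year rownames and
#'   [regressor_label()] column names.
#' @export
indicator_design <- function(indicators, window,
                             groups = c("water_limited", "agromet")) {
  stopifnot(all(groups %in% c("potential", "water_limited", "agromet")),
            length(groups) >= 1)
  sub <- indicators[indicators$window == window & indicators$level %in% groups, ]
  if (!nrow(sub)) stop("indicator_design(): no indicators for window ", window)
  sub$label <- regressor_label(sub$name, sub$level)
  years <- sort(unique(sub$year))
  labels <- unique(sub$label)
  M <- matrix(NA_real_, length(years), length(labels),
              dimnames = list(years, labels))
  M[cbind(match(sub$year, years), match(sub$label, labels))] <- sub$value
  if (any(is.na(M))) {
    bad <- which(is.na(M), arr.ind = TRUE)
    stop("indicator_design(): missing cells, e.g. year ",
         years[bad[1, 1]], " / ", labels[bad[1, 2]])
  }
  keep <- apply(M, 2, stats::sd) > 1e-10
  structure(M[, keep, drop = FALSE], dropped = labels[!keep])
}

#' Fit per-window yield forecasting models
#'
#' The package's central fitting function.  The observed annual yield
#' series is detrended once (OLS on calendar year); then, for every
#' forecasting window, a bidirectional stepwise regression
#' ([stepwise_select()]) picks regressors from the window's candidate set,
#' the selected model is cross-validated leave-one-out ([loo_cv()]), the
#' goodness-of-fit suite ([goodness_of_fit()]) is evaluated on the
#' cross-validated predictions, and residual autocorrelation is screened by
#' the Durbin-Watson test with tabulated bounds ([dw_decision()]).
#'
#' @param indicators National long indicator table (`year`, `window`,
#'   `level`, `name`, `value`).
#' @param yields `data.frame` with columns `year`, `yield` [Mg ha-1]; at
#'   least 8 years.
#' @param groups Regressor groups offered to the selection; default the
#'   water-limited model outputs plus the agrometeorological indicators.
#' @param windows Window days; default all windows present in `indicators`.
#' @param alpha_enter,alpha_remove,vif_max Stepwise thresholds (see
#'   [stepwise_select()]).
#' @param reselect_folds If `TRUE`, the stepwise selection itself is redone
#'   inside every cross-validation fold instead of only refitting the
#'   selected set (default `FALSE`).
#' @return An object of class `yield_forecast` with components
#'   `window_models` (per-window [stepwise_select()] fits augmented with CV
#'   results), `diagnostics` (window x {n_selected, r2, d, ef, vif_max, dw,
#'   dw_decision, p_value, sdep} table), `selection` (binary window x
#'   regressor map), `trend`, `yields`, `groups`, `call`.
#' @seealso [summary.yield_forecast()], [predict.yield_forecast()],
#'   [plot.yield_forecast()], [compare_groups()]
#' @export
yield_forecast <- function(indicators, yields,
                           groups = c("water_limited", "agromet"),
                           windows = NULL,
                           alpha_enter = 0.05, alpha_remove = 0.05,
                           vif_max = 5, reselect_folds = FALSE) {
  if (nrow(yields) < 8) stop("yield_forecast(): need at least 8 years of yields")
  if (is.null(windows)) windows <- sort(unique(indicators$window))
  dt <- detrend_yields(yields)
  years <- dt$year
  iy <- indicators[indicators$year %in% years, , drop = FALSE]
  if (!setequal(unique(iy$year), years))
    stop("yield_forecast(): indicators and yields do not share the year axis")

  all_labels <- character(0)
  models <- vector("list", length(windows))
  names(models) <- windows
  diag_rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[i]
    M <- indicator_design(iy, w, groups)
    M <- M[as.character(years), , drop = FALSE]
    all_labels <- union(all_labels, colnames(M))
    y <- dt$detrended
    m <- stepwise_select(M, y, alpha_enter, alpha_remove, vif_max)
    Xs <- M[, m$selected, drop = FALSE]
    cv <- if (reselect_folds)
      loo_reselect(M, y, alpha_enter, alpha_remove, vif_max)
    else loo_cv(Xs, y)
    gof <- goodness_of_fit(cv$pred[!is.na(cv$pred)], y[!is.na(cv$pred)])
    k <- length(m$selected)
    dw <- if (!m$intercept_only) durbin_watson(m$residuals) else NA_real_
    dec <- if (!m$intercept_only && k <= 5 && length(y) %in% 6:30)
      tryCatch(as.character(dw_decision(dw, length(y), k)),
               error = function(e) NA_character_)
    else NA_character_
    m$window <- w
    m$cv <- cv
    m$gof <- gof
    m$dw <- dw
    m$dw_decision <- dec
    models[[i]] <- m
    diag_rows[[i]] <- data.frame(
      window = w, n_selected = k, r2 = gof$r2, d = gof$d, ef = gof$ef,
      vif_max = if (k) max(m$vif) else NA_real_, dw = dw,
      dw_decision = if (is.null(dec) || is.na(dec)) NA_character_ else dec,
      p_value = m$overall_p, sdep = cv$sdep)
  }
  diagnostics <- do.call(rbind, diag_rows)
  sel <- matrix(0L, length(windows), length(all_labels),
                dimnames = list(windows, sort(all_labels)))
  for (i in seq_along(windows))
    sel[i, models[[i]]$selected] <- 1L
  structure(list(window_models = models, diagnostics = diagnostics,
                 selection = sel,
                 trend = list(slope = attr(dt, "slope"),
                              intercept = attr(dt, "intercept"),
                              mean = attr(dt, "mean")),
                 yields = dt, groups = groups, windows = windows,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove,
                 vif_max = vif_max, call = match.call()),
            class = "yield_forecast")
}

# LOO with per-fold re-selection (config option)
loo_reselect <- function(M, y, alpha_enter, alpha_remove, vif_max) {
  n <- length(y)
  pred <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    m <- stepwise_select(M[-t, , drop = FALSE], y[-t],
                         alpha_enter, alpha_remove, vif_max)
    pred[t] <- sum(c(1, M[t, m$selected]) * m$coef)
  }
  list(pred = pred, sdep = sqrt(mean((pred - y)^2)), n_excluded = 0L)
}

#' @export
print.yield_forecast <- function(x, ...) {
  d <- x$diagnostics
  cat("Per-window maize yield forecasting model\n")
  cat(sprintf("  %d years, windows %s days after sowing\n",
              nrow(x$yields), paste(range(x$windows), collapse = "-")))
  cat(sprintf("  regressor groups: %s\n", paste(x$groups, collapse = " + ")))
  cat(sprintf("  detrending slope: %+.3f Mg ha-1 yr-1\n", x$trend$slope))
  best <- d$window[which.max(d$ef)]
  cat(sprintf("  best window by cross-validated EF: day %d (EF = %.2f, SDEP = %.2f Mg ha-1)\n",
              best, max(d$ef), d$sdep[d$window == best]))
  invisible(x)
}

#' Per-window diagnostics table
#'
#' @param object A [yield_forecast()] fit.
#' @param ... Unused.
#' @return The diagnostics `data.frame` (window, number of selected
#'   regressors, cross-validated R2, Willmott d, Nash-Sutcliffe EF, max
#'   VIF, Durbin-Watson statistic and decision, overall-F p-value, SDEP),
#'   printed with the selected regressors per window.
#' @export
summary.yield_forecast <- function(object, ...) {
  d <- object$diagnostics
  d$regressors <- vapply(object$window_models, function(m)
    paste(m$selected, collapse = "+"), "")
  class(d) <- c("summary.yield_forecast", "data.frame")
  d
}

#' @export
print.summary.yield_forecast <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.yield_forecast <- function(object, window = NULL, ...) {
  if (!is.null(window)) {
    m <- object$window_models[[as.character(window)]]
    if (is.null(m)) stop("no model for window ", window)
    return(m$coef)
  }
  lapply(object$window_models, `[[`, "coef")
}

#' @export
residuals.yield_forecast <- function(object, window = NULL, type = c("loo", "ols"),
                                     ...) {
  type <- match.arg(type)
  get1 <- function(m) if (type == "ols") m$residuals else
    object$yields$detrended - m$cv$pred
  if (!is.null(window)) {
    m <- object$window_models[[as.character(window)]]
    if (is.null(m)) stop("no model for window ", window)
    return(get1(m))
  }
  sapply(object$window_models, get1)
}

#' Forecast yields from new indicators
#'
#' Applies a fitted window model to a (new) national indicator table and
#' re-trends: forecast = detrended-scale prediction + fitted trend at the
#' target year - series mean.
#'
#' @param object A [yield_forecast()] fit.
#' @param newdata National long indicator table including a `year` column.
#' @param window Which forecasting window's model to apply; default the
#'   window with the highest cross-validated EF.
#' @param retrend Add the technological trend back (default `TRUE`).
#' @param ... Unused.
#' @return `data.frame` with columns `year` and `forecast` [Mg ha-1].
#' @export
predict.yield_forecast <- function(object, newdata = NULL, window = NULL,
                                   retrend = TRUE, ...) {
  if (is.null(window))
    window <- object$diagnostics$window[which.max(object$diagnostics$ef)]
  m <- object$window_models[[as.character(window)]]
  if (is.null(m)) stop("no model for window ", window)
  if (is.null(newdata)) {
    years <- object$yields$year
    pred <- m$cv$pred
  } else {
    M <- indicator_design(newdata, window, object$groups)
    years <- as.integer(rownames(M))
    Xs <- cbind(1, M[, m$selected, drop = FALSE])
    pred <- drop(Xs %*% m$coef)
  }
  if (retrend)
    pred <- pred + (object$trend$intercept + object$trend$slope * years) -
      object$trend$mean
  data.frame(year = years, forecast = pred)
}

#' Plot a fitted forecasting model
#'
#' `which = "selection"` draws the binary window x regressor selection map
#' (the regressor-selection heatmap); `"ef"` the cross-validated EF by
#' window; `"sdep"` the SDEP by window.
#'
#' @param x A [yield_forecast()] fit.
#' @param which One of `"selection"`, `"ef"`, `"sdep"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.yield_forecast <- function(x, which = c("selection", "ef", "sdep"), ...) {
  which <- match.arg(which)
  d <- x$diagnostics
  if (which == "selection") {
    sel <- x$selection
    op <- graphics::par(mar = c(5, 7, 2, 1))
    on.exit(graphics::par(op))
    graphics::image(seq_len(nrow(sel)), seq_len(ncol(sel)), sel,
                    col = c("grey95", "steelblue4"), axes = FALSE,
                    xlab = "days after sowing", ylab = "",
                    main = "Selected regressors by window", ...)
    graphics::axis(1, seq_len(nrow(sel)), rownames(sel))
    graphics::axis(2, seq_len(ncol(sel)), colnames(sel), las = 2, cex.axis = 0.8)
    graphics::box()
  } else if (which == "ef") {
    graphics::plot(d$window, d$ef, type = "b", pch = 16, ylim = c(0, 1),
                   xlab = "days after sowing", ylab = "EF (LOO)",
                   main = "Cross-validated modeling efficiency", ...)
  } else {
    graphics::plot(d$window, d$sdep, type = "b", pch = 16,
                   xlab = "days after sowing", ylab = "SDEP (Mg/ha)",
                   main = "Cross-validated prediction error", ...)
  }
  invisible(x)
}

#' Compare regressor-group configurations
#'
#' Refits the per-window forecasting model under several regressor-group
#' configurations and collects the cross-validated SDEP and EF curves --
#' e.g. water-limited outputs alone, agrometeorological indicators alone,
#' potential outputs alone, and water-limited + agromet.
#'
#' @inheritParams yield_forecast
#' @param group_sets Named list of group vectors; default the four
#'   configurations above.
#' @param ... Passed to [yield_forecast()].
#' @return `data.frame` with columns `config`, `window`, `sdep`, `ef`.
#' @export
compare_groups <- function(indicators, yields,
                           group_sets = list(
                             water_limited = "water_limited",
                             agromet = "agromet",
                             potential = "potential",
                             wl_agromet = c("water_limited", "agromet")),
                           ...) {
  parts <- lapply(names(group_sets), function(nm) {
    fit <- yield_forecast(indicators, yields, groups = group_sets[[nm]], ...)
    data.frame(config = nm, window = fit$diagnostics$window,
               sdep = fit$diagnostics$sdep, ef = fit$diagnostics$ef)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
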