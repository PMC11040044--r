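# Bidirectional stepwise selection and leave-one-out cross-validation.

# Minimal OLS on a design with explicit intercept; returns everything the
# stepwise loop needs.  Tiny problems (n <= 30, p <= 6), so the normal
# equations are adequate.
ols_fit <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Xi); p <- ncol(Xi)
  xtx <- crossprod(Xi)
  ok <- tryCatch({ xtxi <- solve(xtx); TRUE }, error = function(e) FALSE)
  if (!ok || !all(is.finite(xtxi))) return(NULL)
  coef <- drop(xtxi %*% crossprod(Xi, y))
  resid <- drop(y - Xi %*% coef)
  rss <- sum(resid^2)
  df <- n - p
  if (df <= 0) return(NULL)
  sigma2 <- rss / df
  se <- sqrt(pmax(diag(xtxi), 0) * sigma2)
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  fstat <- overall_p <- NA_real_
  if (p > 1) {
    fstat <- ((tss - rss) / (p - 1)) / sigma2
    overall_p <- stats::pf(fstat, p - 1, df, lower.tail = FALSE)
  }
  list(coef = coef, se = se, t = tval, p = pval, resid = resid, rss = rss,
       tss = tss, sigma = sqrt(sigma2), df = df,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       fstat = fstat, overall_p = overall_p)
}

#' Bidirectional stepwise regressor selection
#'
#' At each step the candidate with the smallest partial-F (equivalently
#' partial-t) p-value below `alpha_enter` enters, provided no variance
#' inflation factor of the resulting model exceeds `vif_max`; after each
#' entry, any included regressor whose p-value rises above `alpha_remove`
#' leaves.  Ties on p-value are broken by larger absolute partial
#' correlation, then lexicographic name.  Entry requires a strict reduction
#' of the residual sum of squares, so the procedure terminates.
#'
#' @param X Numeric candidate matrix, one column per candidate regressor
#'   (named), one row per year.
#' @param y Response vector (detrended yields).
#' @param alpha_enter,alpha_remove Entry and removal significance levels;
#'   default 0.05 each.
#' @param vif_max Largest admissible VIF in the fitted model; default 5.
#' @param max_terms Cap on the number of selected regressors; default keeps
#'   `n - 2` residual degrees of freedom.
#' @return A list of class `window_model`: `selected` (character),
#'   `coef`/`se`/`t`/`p` (including intercept), `vif` (per selected
#'   regressor), `r2`, `sigma`, `overall_p`, `residuals` (in input order),
#'   `intercept_only` flag.
#' @export
stepwise_select <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.05,
                            vif_max = 5, max_terms = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(max_terms)) max_terms <- max(n - 4L, 1L)
  candidates <- colnames(X)
  included <- character(0)
  seen <- character(0)
  rss_cur <- sum((y - mean(y))^2)

  for (iter in seq_len(100L)) {
    # --- entry scan
    pool <- setdiff(candidates, included)
    best <- NULL
    if (length(included) < max_terms && length(pool)) {
      scan <- lapply(pool, function(v) {
        Xt <- X[, c(included, v), drop = FALSE]
        f <- ols_fit(Xt, y)
        if (is.null(f)) return(NULL)
        if (f$rss >= rss_cur - 1e-12) return(NULL)        # no strict SSE gain
        pv <- f$p[[v]]
        if (!is.finite(pv) || pv >= alpha_enter) return(NULL)
        if (ncol(Xt) > 1 && any(vif(Xt) > vif_max)) return(NULL)
        tv <- f$t[[v]]
        list(v = v, p = pv, pc = abs(tv) / sqrt(tv^2 + f$df))
      })
      scan <- Filter(Negate(is.null), scan)
      if (length(scan)) {
        pvals <- vapply(scan, `[[`, 0, "p")
        pcs <- vapply(scan, `[[`, 0, "pc")
        nms <- vapply(scan, `[[`, "", "v")
        ord <- order(pvals, -pcs, nms)
        best <- scan[[ord[1]]]
      }
    }
    if (is.null(best)) break
    included <- c(included, best$v)

    # --- removal scan
    repeat {
      f <- ols_fit(X[, included, drop = FALSE], y)
      pv <- f$p[included]
      worst <- which.max(pv)
      if (length(included) && pv[worst] > alpha_remove) {
        included <- included[-worst]
        if (!length(included)) break
      } else break
    }
    key <- paste(sort(included), collapse = "|")
    if (key %in% seen) break   # cycling guard
    seen <- c(seen, key)
    rss_cur <- if (length(included))
      ols_fit(X[, included, drop = FALSE], y)$rss
    else sum((y - mean(y))^2)
  }

  if (!length(included)) {
    f <- ols_fit(X[, character(0), drop = FALSE], y)
    return(structure(list(selected = character(0), coef = f$coef, se = f$se,
                          t = f$t, p = f$p, vif = numeric(0), r2 = 0,
                          sigma = f$sigma, overall_p = NA_real_,
                          residuals = f$resid, rss = f$rss,
                          intercept_only = TRUE),
                     class = "window_model"))
  }
  Xs <- X[, included, drop = FALSE]
  f <- ols_fit(Xs, y)
  structure(list(selected = included, coef = f$coef, se = f$se, t = f$t,
                 p = f$p, vif = vif(Xs), r2 = f$r2, sigma = f$sigma,
                 overall_p = f$overall_p, residuals = f$resid, rss = f$rss,
                 intercept_only = FALSE),
            class = "window_model")
}

#' @export
print.window_model <- function(x, ...) {
  if (x$intercept_only) {
    cat("Intercept-only model (no candidate passed the entry threshold)\n")
  } else {
    cat("Stepwise regression model\n  regressors:",
        paste(x$selected, collapse = ", "), "\n")
    cm <- cbind(estimate = x$coef, se = x$se, t = x$t, p = x$p)
    print(round(cm, 4))
    cat(sprintf("  R2 = %.3f, sigma = %.3f, overall-F p = %.4g, max VIF = %.2f\n",
                x$r2, x$sigma, x$overall_p, max(x$vif)))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of a fixed regressor set
#'
#' For each year the model (the given columns, selection held fixed) is
#' refit on the remaining `n - 1` years and used to predict the held-out
#' year.  SDEP is the root mean squared prediction error over the predicted
#' folds.  Singular folds are flagged, excluded and counted.
#'
#' @param X Design matrix of the selected regressors (0 columns for an
#'   intercept-only model).
#' @param y Response vector, `length(y) >= ncol(X) + 3`.
#' @return A list: `pred` (per-year LOO predictions, `NA` for excluded
#'   folds), `sdep` [response units], `n_excluded`.
#' @export
loo_cv <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < ncol(X) + 3) stop("loo_cv(): need n >= p + 3")
  pred <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    f <- ols_fit(X[-t, , drop = FALSE], y[-t])
    if (is.null(f)) next
    pred[t] <- sum(c(1, X[t, ]) * f$coef)
  }
  ok <- !is.na(pred)
  if (!any(ok)) stop("loo_cv(): every fold was singular")
  list(pred = pred,
       sdep = sqrt(mean((pred[ok] - y[ok])^2)),
       n_excluded = sum(!ok))
}
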