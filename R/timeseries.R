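# Change-point regression of breeding values on birth year, percent-change
# summaries of the fitted population means, a transformed-residual re-fit
# that tracks additive-variance trends, and plain linear trend analysis of
# production series.

#' Continuous piecewise (change-point) regression
#'
#' Fits a two-segment linear model with a single knot at which the segments
#' meet continuously (the flat-then-trending pattern typical of breeding
#' values over birth years is the special case with a near-zero pre-segment
#' slope). The change-point year is chosen by exhaustive search over
#' observed candidate years minimizing the error sum of squares; ties break
#' towards the earliest year. Candidates must leave at least `guard`
#' observations and two distinct years on each side.
#'
#' @param years,values paired observations (birth year, breeding value).
#' @param guard minimum observations per segment for a candidate year.
#' @param continuous if `FALSE`, the two segments are fitted independently
#'   (discontinuous sensitivity variant).
#' @return a `changepoint_fit`: cp_year, pre/post slopes and intercepts,
#'   `sse`, `sse_line` (single-line fit on the same data), `n`, and fitted
#'   values retrievable with [predict()].
#' @export
fit_changepoint <- function(years, values, guard = 5, continuous = TRUE) {
  assert(length(years) == length(values), "years and values differ in length")
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  n <- length(years)
  assert(n >= 2 * guard + 4, "need at least 2*guard + 4 observations")
  uy <- sort(unique(years))
  cand <- uy[vapply(uy, function(cc) {
    sum(years <= cc) >= guard && sum(years >= cc) >= guard &&
      length(unique(years[years <= cc])) >= 2 &&
      length(unique(years[years >= cc])) >= 2
  }, TRUE)]
  assert(length(cand) > 0, "too few distinct years for any candidate change point")

  best <- NULL
  for (cc in cand) {
    X <- if (continuous) cbind(1, years - cc, pmax(years - cc, 0))
    else cbind(years <= cc, years > cc, (years - cc) * (years <= cc),
               (years - cc) * (years > cc))
    f <- lm.fit(X, values)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(cp = cc, sse = sse, coef = f$coefficients)
  }
  b <- best$coef; cc <- best$cp
  if (continuous) {
    pre_slope <- b[2]; post_slope <- b[2] + b[3]
    pre_int <- b[1] - b[2] * cc; post_int <- b[1] - post_slope * cc
  } else {
    pre_slope <- b[3]; post_slope <- b[4]
    pre_int <- b[1] - b[3] * cc; post_int <- b[2] - b[4] * cc
  }
  line <- lm.fit(cbind(1, years), values)
  structure(list(cp_year = unname(cc), pre_slope = unname(pre_slope),
                 pre_intercept = unname(pre_int), post_slope = unname(post_slope),
                 post_intercept = unname(post_int), sse = best$sse,
                 sse_line = sum(line$residuals^2), n = n,
                 continuous = continuous, years = years, values = values),
            class = "changepoint_fit")
}

#' Build a change-point fit from anchor values
#'
#' Constructs the (exactly determined) continuous two-segment model passing
#' through `(start_year, y_start)`, `(cp_year, y_cp)` and
#' `(end_year, y_end)`. Useful for applying percent-change arithmetic to
#' published fitted values when the underlying series is not available.
#'
#' @param cp_year change-point year.
#' @param y_start,y_cp,y_end fitted values at the three anchor years.
#' @param start_year,end_year range of the series.
#' @export
changepoint_from_values <- function(cp_year, y_start, y_cp, y_end,
                                    start_year, end_year) {
  assert(start_year < cp_year && cp_year < end_year,
         "need start_year < cp_year < end_year")
  pre_slope <- (y_cp - y_start) / (cp_year - start_year)
  post_slope <- (y_end - y_cp) / (end_year - cp_year)
  structure(list(cp_year = cp_year, pre_slope = pre_slope,
                 pre_intercept = y_cp - pre_slope * cp_year,
                 post_slope = post_slope,
                 post_intercept = y_cp - post_slope * cp_year,
                 sse = NA_real_, sse_line = NA_real_, n = 3L,
                 continuous = TRUE, years = NULL, values = NULL),
            class = "changepoint_fit")
}

#' @export
predict.changepoint_fit <- function(object, years = object$years, ...) {
  pre <- object$pre_intercept + object$pre_slope * years
  post <- object$post_intercept + object$post_slope * years
  ifelse(years <= object$cp_year, pre, post)
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("change-point fit: cp_year = %s, pre-slope = %.4g, post-slope = %.4g\n",
              format(x$cp_year), x$pre_slope, x$post_slope))
  if (is.finite(x$sse))
    cat(sprintf("SSE = %.6g (single line: %.6g), n = %d\n", x$sse, x$sse_line, x$n))
  invisible(x)
}

#' Bootstrap percentile interval for the change-point year
#'
#' Case-resampling bootstrap of [fit_changepoint()].
#'
#' @param fit a `changepoint_fit` carrying its data.
#' @param n_boot number of resamples.
#' @param level interval coverage.
#' @param seed integer seed.
#' @export
changepoint_bootstrap <- function(fit, n_boot = 200, level = 0.95, seed = 1) {
  assert(!is.null(fit$years), "fit does not carry its data")
  with_substream(seed, "cp_bootstrap", {
    cps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(fit$n, fit$n, replace = TRUE)
      f <- tryCatch(fit_changepoint(fit$years[i], fit$values[i],
                                    continuous = fit$continuous),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$cp_year
    }, 0)
    a <- (1 - level) / 2
    list(cp_years = cps,
         interval = unname(quantile(cps, c(a, 1 - a), na.rm = TRUE)))
  })
}

#' Percent changes of the fitted population mean around the change point
#'
#' `pre = (yhat(cp) - yhat(start))/yhat(start) * 100` and
#' `post = (yhat(end) - yhat(cp))/yhat(cp) * 100`, with per-year rates
#' obtained by dividing by the segment lengths.
#'
#' @param fit a `changepoint_fit`.
#' @param start_year,end_year summary range containing the change point.
#' @return list with pre/post percent changes, per-year rates, the three
#'   fitted values, and a `defined` flag (FALSE when a divisor is zero).
#' @export
percent_change_summary <- function(fit, start_year, end_year) {
  assert(start_year <= fit$cp_year && fit$cp_year <= end_year,
         "change point must lie within [start_year, end_year]")
  yh <- predict(fit, c(start_year, fit$cp_year, end_year))
  defined <- yh[1] != 0 && yh[2] != 0
  pre <- if (yh[1] != 0) (yh[2] - yh[1]) / yh[1] * 100 else NA_real_
  post <- if (yh[2] != 0) (yh[3] - yh[2]) / yh[2] * 100 else NA_real_
  list(pre_pct = pre, post_pct = post,
       pre_pct_per_year = pre / (fit$cp_year - start_year),
       post_pct_per_year = post / (end_year - fit$cp_year),
       yhat_start = yh[1], yhat_cp = yh[2], yhat_end = yh[3],
       defined = defined)
}

#' Change-point analysis of transformed residuals (variance trend)
#'
#' Residuals from a change-point fit are transformed to positive values as
#' `sqrt((y - yhat)^2) = |y - yhat|` and the change-point procedure is
#' re-run on them. A positive post-change-point slope indicates increasing
#' dispersion of breeding values, i.e. growing additive genetic variance.
#'
#' @param fit a `changepoint_fit` computed on `(years, values)`.
#' @param years,values the series the fit was computed on (defaults to the
#'   data carried by the fit).
#' @param guard passed to [fit_changepoint()].
#' @export
variance_trend <- function(fit, years = fit$years, values = fit$values, guard = 5) {
  assert(!is.null(years) && !is.null(values), "fit does not carry its data")
  r <- sqrt((values - predict(fit, years))^2)
  fit_changepoint(years, r, guard = guard, continuous = fit$continuous)
}

# ---- linear trends ----------------------------------------------------------

#' Ordinary least-squares trend of a year-indexed series
#'
#' @param years,values the series (at least 3 points, 2 distinct years).
#' @return a `trend_fit` with intercept `b0`, slope `b1` (units per year),
#'   `r2`, F-statistic and p-value; predictions via [predict()].
#' @export
fit_linear_trend <- function(years, values) {
  assert(length(years) == length(values), "years and values differ in length")
  assert(length(years) >= 3, "need at least 3 points")
  assert(length(unique(years)) >= 2, "all years identical")
  f <- lm(values ~ years)
  sm <- summary(f)
  fstat <- unname(sm$fstatistic)
  structure(list(b0 = unname(coef(f)[1]), b1 = unname(coef(f)[2]),
                 r2 = sm$r.squared,
                 f_stat = fstat[1],
                 p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                 n = length(years)),
            class = "trend_fit")
}

#' Build a trend fit from published regression coefficients
#' @param b0,b1 intercept and slope (per year).
#' @export
trend_from_coefficients <- function(b0, b1) {
  structure(list(b0 = b0, b1 = b1, r2 = NA_real_, f_stat = NA_real_,
                 p = NA_real_, n = NA_integer_), class = "trend_fit")
}

#' @export
predict.trend_fit <- function(object, years, ...) object$b0 + object$b1 * years

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("linear trend: yhat = %.6g + %.6g * year", x$b0, x$b1))
  if (is.finite(x$r2)) cat(sprintf(" (R2 = %.3f, F = %.4g)", x$r2, x$f_stat))
  cat("\n")
  invisible(x)
}

#' Percent change between two predicted values of a trend
#'
#' `(yhat(year1) - yhat(year0)) / yhat(year0) * 100`.
#'
#' @param fit a `trend_fit`.
#' @param year0,year1 reference and comparison years.
#' @export
percent_change_predicted <- function(fit, year0, year1) {
  y0 <- predict(fit, year0)
  assert(y0 != 0, "predicted value at year0 is zero; percent change undefined")
  (predict(fit, year1) - y0) / y0 * 100
}
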