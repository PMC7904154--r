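# Group-binned ordinary least squares of photosynthetic capacity on SIF /
# SIF yield / APAR, and the Pearson correlation between Vcmax and Jmax.

#' Simple linear regression with the diagnostics the pipeline reports
#'
#' Closed-form OLS of `y` on `x`: slope, intercept, R-squared (explained
#' variance), in-sample RMSE, Pearson correlation and a two-sided t-test
#' p-value for the slope. A constant response is fitted as slope 0 with
#' R-squared 0 (nothing to explain); a constant predictor is an error.
#'
#' @param x predictor values (n >= 3, non-constant).
#' @param y response values.
#' @param x_name,y_name labels carried into the result.
#' @param group optional group label.
#' @return a `"regression_result"` list: `slope`, `intercept`, `r_squared`,
#'   `rmse`, `pearson_cc`, `p_value_slope`, `n`, `group`, `x_name`,
#'   `y_name`.
#' @export
linear_fit <- function(x, y, x_name = "x", y_name = "y", group = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("linear_fit needs n >= 3 (got %d)", n)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopf("constant predictor: OLS slope undefined")
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    res <- list(slope = 0, intercept = mean(y), r_squared = 0, rmse = 0,
                pearson_cc = 0, p_value_slope = 1, n = n, group = group,
                x_name = x_name, y_name = y_name)
    return(structure(res, class = "regression_result"))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  r2 <- max(0, 1 - sse / syy)
  cc <- stats::cor(x, y)
  p <- if (sse <= 1e-14 * syy) 0 else {
    se <- sqrt(sse / (n - 2) / sxx)
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 rmse = sqrt(sse / n), pearson_cc = cc, p_value_slope = p,
                 n = n, group = group, x_name = x_name, y_name = y_name),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<%s ~ %s%s: slope=%.4g, R2=%.3f, RMSE=%.3g, p=%.3g, n=%d>\n",
              x$y_name, x$x_name,
              if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
              x$slope, x$r_squared, x$rmse, x$p_value_slope, x$n))
  invisible(x)
}

#' @export
as.data.frame.regression_result <- function(x, ...) {
  data.frame(group = x$group, x_name = x$x_name, y_name = x$y_name,
             slope = x$slope, intercept = x$intercept,
             r_squared = x$r_squared, rmse = x$rmse,
             pearson_cc = x$pearson_cc, p_value_slope = x$p_value_slope,
             n = x$n, significant = x$p_value_slope < 0.05,
             stringsAsFactors = FALSE)
}

#' Sample Pearson correlation coefficient
#'
#' Errors on constant input rather than returning NA.
#'
#' @param x,y numeric vectors, n >= 3, both non-constant.
#' @export
pearson_cc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3)
    stopf("pearson_cc needs two vectors of equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("pearson_cc undefined for constant input")
  stats::cor(x, y)
}

#' Acquisition-date grouping scheme
#'
#' Maps acquisition dates to time-proximity groups. The defaults are the
#' campaign bins used throughout: three early-July 2017 dates, two
#' late-season 2017 dates, two July 2018 dates. The scheme is data, not
#' code — supply your own to re-bin another campaign.
#'
#' @param ... named character vectors of dates (`"YYYY-MM-DD"`), one per
#'   group. With no arguments the default three-group scheme is returned.
#' @return named list of date vectors, class `"group_scheme"`.
#' @export
group_scheme <- function(...) {
  g <- list(...)
  if (!length(g))
    g <- list(group1 = c("2017-07-06", "2017-07-07", "2017-07-12"),
              group2 = c("2017-07-31", "2017-08-18"),
              group3 = c("2018-07-24", "2018-07-25"))
  all_dates <- unlist(g, use.names = FALSE)
  if (anyDuplicated(all_dates))
    stopf("a date maps to more than one group: %s",
          all_dates[duplicated(all_dates)][1])
  structure(g, class = "group_scheme")
}

#' Assign records' dates to groups
#'
#' @param dates character vector of `"YYYY-MM-DD"` dates.
#' @param scheme a [group_scheme()].
#' @return character vector of group labels; an unmapped date is an error
#'   naming the date.
#' @export
assign_group <- function(dates, scheme = group_scheme()) {
  stopifnot(inherits(scheme, "group_scheme"))
  lut <- stats::setNames(rep(names(scheme), lengths(scheme)),
                         unlist(scheme, use.names = FALSE))
  g <- lut[as.character(dates)]
  if (anyNA(g))
    stopf("date %s is not mapped to any group", dates[which(is.na(g))[1]])
  unname(g)
}

#' Group-binned regression of capacity on a SIF-derived predictor
#'
#' One OLS fit per time group plus a pooled all-data fit, with a
#' significance flag at p < 0.05. Rows with missing predictor or response
#' are dropped and recorded in the `"dropped"` attribute (conservation of
#' records). Per-group results are computed independently of the pooled
#' fit.
#'
#' @param records data.frame with the predictor and response columns plus
#'   either a `group` column or a `date` column mapped through `scheme`.
#' @param x_var predictor column name (e.g. `"SIF"`, `"SIF_yield"`,
#'   `"APAR"`).
#' @param y_var response column name (e.g. `"Vcmax"`, `"Jmax"`).
#' @param scheme a [group_scheme()] used when `records` has no `group`
#'   column.
#' @return data.frame of results, one row per group plus `"pooled"`;
#'   attribute `"dropped"` records excluded rows and reasons.
#' @export
grouped_regression <- function(records, x_var, y_var,
                               scheme = group_scheme()) {
  stopifnot(is.data.frame(records),
            all(c(x_var, y_var) %in% names(records)))
  if (!"group" %in% names(records)) {
    if (!"date" %in% names(records))
      stopf("records need a 'group' or 'date' column")
    records$group <- assign_group(records$date, scheme)
  }
  ok <- is.finite(records[[x_var]]) & is.finite(records[[y_var]])
  dropped <- records[!ok, , drop = FALSE]
  if (nrow(dropped))
    dropped$reason <- sprintf("missing %s or %s", x_var, y_var)
  kept <- records[ok, , drop = FALSE]
  groups <- unique(kept$group)
  fits <- lapply(groups, function(g) {
    d <- kept[kept$group == g, ]
    as.data.frame(linear_fit(d[[x_var]], d[[y_var]], x_var, y_var, g))
  })
  pooled <- as.data.frame(linear_fit(kept[[x_var]], kept[[y_var]],
                                     x_var, y_var, "pooled"))
  out <- rbind(do.call(rbind, fits), pooled)
  attr(out, "dropped") <- dropped
  out
}
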