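#' Yield loss relative to the normal sowing date
#'
#' Percentage shortfall of a treatment yield relative to the normal-sowing
#' yield: `(y_ns - y)/y_ns * 100`. Negative values indicate a yield gain.
#'
#' @param y_ns Grain yield of the normal sowing date (kg/ha, `> 0`).
#' @param y Grain yield of the compared sowing date (kg/ha); vectorised.
#' @return Yield loss in percent.
#' @examples
#' yield_loss(6578.9, 5674.8)
#' @export
yield_loss <- function(y_ns, y) {
  if (!is.numeric(y_ns) || any(!is.finite(y_ns)) || any(y_ns <= 0)) {
    stop("`y_ns` must be positive and finite", call. = FALSE)
  }
  (y_ns - y) / y_ns * 100
}

#' Percent yield advantage of one sowing date over another
#'
#' Computes `(Y_A / Y_B - 1) * 100` within each season, then averages across
#' seasons (the reporting convention for multi-season trials).
#'
#' @param yields A data frame of treatment-mean yields with columns `season`,
#'   `sowing_date`, `grain_yield`.
#' @param a,b Sowing-date labels; both must appear in every season.
#' @return The cross-season mean advantage of `a` over `b`, in percent.
#' @examples
#' pct_advantage(trial_yields(), "5-Nov", "21-Nov")
#' @export
pct_advantage <- function(yields, a, b) {
  yields <- check_yields(yields)
  per_season <- purrr::map_dbl(unique(yields$season), function(s) {
    ys <- yields[yields$season == s, , drop = FALSE]
    ya <- ys$grain_yield[ys$sowing_date == a]
    yb <- ys$grain_yield[ys$sowing_date == b]
    if (length(ya) != 1L || length(yb) != 1L) {
      stop("sowing dates `", a, "` and `", b, "` must each appear once in season ",
           s, call. = FALSE)
    }
    (ya / yb - 1) * 100
  })
  mean(per_season)
}

check_yields <- function(yields, cols = "grain_yield") {
  stopifnot(is.data.frame(yields))
  need <- c("season", "sowing_date", cols)
  if (!all(need %in% names(yields))) {
    stop("yield table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(yields)
}

#' Yield loss per day of sowing-date displacement
#'
#' Regresses the per-season yield losses (relative to the normal sowing date,
#' see [yield_loss()]) on the absolute displacement in days from the normal
#' sowing date. Because the underlying field procedure behind published
#' per-day loss rates is rarely recoverable from treatment means, all three
#' common conventions are computed and returned side by side, clearly
#' labelled, rather than a single number:
#' * `pooled_ols` — one ordinary least-squares line through all
#'   season-by-treatment losses;
#' * `per_season_ols` — a separate OLS slope per season, then the mean slope
#'   (its standard error is the SE of the mean across season slopes);
#' * `through_origin` — least squares with no intercept (loss forced to 0 at
#'   the normal date), pooled.
#'
#' @param yields Treatment-mean yields: `season`, `sowing_date`,
#'   `grain_yield`. At least 3 sowing dates per season are required.
#' @param normal Label of the normal sowing date.
#' @param offsets Named numeric vector giving, for each sowing-date label,
#'   the signed or absolute displacement in days from the normal date (the
#'   absolute value is used). Not needed when `sowing_date` is a `Date`.
#' @return A tibble with columns `method`, `slope` (percent loss per day),
#'   `se`, `intercept` (`NA` for the through-origin variant).
#' @export
loss_per_day_regression <- function(yields, normal, offsets = NULL) {
  yields <- check_yields(yields)
  if (is.null(offsets)) {
    if (!inherits(yields$sowing_date, "Date")) {
      stop("supply `offsets` (days from normal) or use Date sowing dates",
           call. = FALSE)
    }
    normal_date <- as.Date(normal)
    yields$days_off <- abs(as.numeric(yields$sowing_date - normal_date))
  } else {
    if (is.null(names(offsets)) || !all(yields$sowing_date %in% names(offsets))) {
      stop("`offsets` must be named with every sowing-date label", call. = FALSE)
    }
    yields$days_off <- abs(offsets[as.character(yields$sowing_date)])
  }
  losses <- purrr::map_dfr(unique(yields$season), function(s) {
    ys <- yields[yields$season == s, , drop = FALSE]
    if (nrow(ys) < 3L) stop("need at least 3 sowing dates per season", call. = FALSE)
    y_ns <- ys$grain_yield[as.character(ys$sowing_date) == as.character(normal)]
    if (length(y_ns) != 1L) {
      stop("normal sowing date `", normal, "` must appear once in season ", s,
           call. = FALSE)
    }
    tibble::tibble(season = s, x = ys$days_off, loss = yield_loss(y_ns, ys$grain_yield))
  })

  pooled <- lm(loss ~ x, data = losses)
  origin <- lm(loss ~ x - 1, data = losses)
  season_slopes <- purrr::map_dbl(unique(losses$season), function(s) {
    coef(lm(loss ~ x, data = losses[losses$season == s, ]))[["x"]]
  })
  se_of <- function(fit, term) summary(fit)$coefficients[term, "Std. Error"]
  tibble::tibble(
    method = c("pooled_ols", "per_season_ols", "through_origin"),
    slope = c(coef(pooled)[["x"]], mean(season_slopes), coef(origin)[["x"]]),
    se = c(
      se_of(pooled, "x"),
      if (length(season_slopes) > 1L)
        stats::sd(season_slopes) / sqrt(length(season_slopes)) else NA_real_,
      se_of(origin, "x")
    ),
    intercept = c(coef(pooled)[["(Intercept)"]], NA_real_, NA_real_)
  )
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation between two numeric vectors with the usual
#' two-sided p-value from `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2`
#' degrees of freedom (as returned by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero variance.
#' @return A list with elements `r`, `p`, `n` and the significance label
#'   `stars` (`"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise).
#' @examples
#' pearson_r(c(50, 46, 43, 39), c(17.93, 18.23, 19.84, 20.25))
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(r = r, p = p, n = length(x),
       stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}

#' Ratio threshold for a target yield from a fitted line
#'
#' Solves `target = slope * x + intercept` for the mature-to-jointing
#' accumulation ratio `x`. Vectorised over coefficients.
#'
#' @param slope,intercept Linear coefficients (kg/ha per unit ratio; kg/ha).
#' @param target Target grain yield in kg/ha (default 6000).
#' @return The ratio at which the fitted line reaches `target`.
#' @examples
#' mean(ratio_threshold(c(306.03, 636.93), c(4511.69, 3924.05)))
#' @export
ratio_threshold <- function(slope, intercept, target = 6000) {
  if (any(slope == 0)) stop("threshold undefined: zero slope", call. = FALSE)
  (target - intercept) / slope
}

#' Yield regression on mature-to-jointing accumulation ratios
#'
#' Per-season ordinary least squares of grain yield on the mature-to-jointing
#' accumulation ratio (M/J), the standard summary relating end-of-season
#' per-stem accumulation structure to plot yield. For each season the fitted
#' line is solved for the ratio at which yield reaches `target`
#' ([ratio_threshold()]); the cross-season mean threshold is the headline
#' number. Ratios at or below 1 are unusual (accumulation should grow) and
#' trigger a warning, not an error.
#'
#' @param points A data frame with columns `season`, `ratio`, `grain_yield`
#'   (and optionally `variable`); at least 3 points per season.
#' @param target Target grain yield, kg/ha (default 6000).
#' @return A list of class `ratio_regression` with `per_season` (tibble of
#'   `season`, `slope`, `intercept`, `r`, `p`, `n`, `threshold`),
#'   `threshold_mean`, and `target`.
#' @export
fit_ratio_regression <- function(points, target = 6000) {
  stopifnot(is.data.frame(points))
  if (!all(c("season", "ratio", "grain_yield") %in% names(points))) {
    stop("`points` must have columns season, ratio, grain_yield", call. = FALSE)
  }
  if (any(points$ratio <= 1)) {
    warning("some mature-to-jointing ratios are <= 1; accumulation usually grows",
            call. = FALSE)
  }
  per_season <- purrr::map_dfr(unique(points$season), function(s) {
    ps <- points[points$season == s, , drop = FALSE]
    if (nrow(ps) < 3L) stop("need at least 3 ratio points in season ", s, call. = FALSE)
    fit <- lm(grain_yield ~ ratio, data = ps)
    ct <- pearson_r(ps$ratio, ps$grain_yield)
    slope <- coef(fit)[["ratio"]]
    intercept <- coef(fit)[["(Intercept)"]]
    tibble::tibble(
      season = s, slope = slope, intercept = intercept,
      r = ct$r, p = ct$p, n = nrow(ps),
      threshold = ratio_threshold(slope, intercept, target)
    )
  })
  structure(
    list(per_season = per_season,
         threshold_mean = mean(per_season$threshold),
         target = target),
    class = "ratio_regression"
  )
}

#' @export
print.ratio_regression <- function(x, ...) {
  cat("Yield ~ mature/jointing ratio regression (target ",
      format(x$target), " kg/ha)\n", sep = "")
  print(x$per_season)
  cat(sprintf("Cross-season mean threshold ratio: %.2f\n", x$threshold_mean))
  invisible(x)
}

#' Percentage of productive tillers
#'
#' Share of the peak tiller population that survives to bear spikes at
#' maturity: `at_maturity / peak * 100`.
#'
#' @param peak Peak tiller count (`> 0`, `>= at_maturity`).
#' @param at_maturity Tiller count at maturity (`>= 0`).
#' @return Percentage in `[0, 100]`; vectorised.
#' @export
productive_tiller_pct <- function(peak, at_maturity) {
  if (any(peak <= 0)) stop("`peak` must be positive", call. = FALSE)
  if (any(at_maturity < 0) || any(at_maturity > peak)) {
    stop("`at_maturity` must lie in [0, peak]", call. = FALSE)
  }
  at_maturity / peak * 100
}
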