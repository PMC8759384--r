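#' Thermal time (growing degree days) over a date interval
#'
#' Sums daily mean temperature above a base temperature over
#' `[start, end]`, both endpoints included:
#' `sum(max(t_mean - base, 0))` in degree-days. With the default base of
#' 0 degrees C this is the accumulated temperature conventionally reported
#' for whole-season summaries of wheat trials.
#'
#' @param weather A weather data frame with columns `date` (Date, consecutive
#'   days, no gaps) and `t_mean` (daily mean temperature, degrees C).
#' @param start,end Dates bounding the interval (inclusive on both sides);
#'   must lie within the series.
#' @param base Base temperature in degrees C (default 0).
#' @return Thermal time in degree-days (non-negative scalar).
#' @examples
#' w <- data.frame(date = as.Date("2020-01-01") + 0:9, t_mean = 10)
#' accumulated_temperature(w, w$date[1], w$date[10])  # 100
#' @export
accumulated_temperature <- function(weather, start, end, base = 0) {
  check_weather(weather)
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("`start` must not be after `end`", call. = FALSE)
  if (start < min(weather$date) || end > max(weather$date)) {
    stop("interval [", start, ", ", end, "] outside the weather series", call. = FALSE)
  }
  sel <- weather$date >= start & weather$date <= end
  sum(pmax(weather$t_mean[sel] - base, 0))
}

check_weather <- function(weather) {
  stopifnot(is.data.frame(weather))
  if (!all(c("date", "t_mean") %in% names(weather))) {
    stop("weather table must have columns `date` and `t_mean`", call. = FALSE)
  }
  d <- as.Date(weather$date)
  if (nrow(weather) > 1L && any(diff(d) != 1)) {
    stop("weather dates must be consecutive daily records with no gaps", call. = FALSE)
  }
  invisible(weather)
}

# Start indices and lengths of runs of TRUE in a logical vector.
cold_runs <- function(is_cold, run) {
  r <- rle(is_cold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= run
  list(starts = starts[keep], lengths = r$lengths[keep])
}

#' Onset of the wintering period
#'
#' First date, at or after `after`, that begins a run of at least `run`
#' consecutive days with mean temperature below `threshold`. The default
#' rule (below 10 degrees C for three or more consecutive days) is the
#' conventional definition of the wintering onset for winter wheat; the date
#' bounds the "thermal time from sowing to wintering" summary.
#'
#' @inheritParams accumulated_temperature
#' @param after Earliest admissible date (e.g. the sowing date).
#' @param threshold Temperature threshold, degrees C (default 10).
#' @param run Minimum run length in days (default 3).
#' @return The onset date, or `NA` (with class `Date`) when no qualifying
#'   cold run exists after `after`.
#' @export
wintering_onset <- function(weather, after = min(as.Date(weather$date)),
                            threshold = 10, run = 3) {
  check_weather(weather)
  after <- as.Date(after)
  d <- as.Date(weather$date)
  sel <- d >= after
  if (!any(sel)) stop("`after` lies beyond the weather series", call. = FALSE)
  runs <- cold_runs(weather$t_mean[sel] < threshold, run)
  if (length(runs$starts) == 0L) return(as.Date(NA))
  d[sel][runs$starts[1L]]
}

#' Total length of the cold period
#'
#' Number of days belonging to runs of at least `run` consecutive days with
#' mean temperature below `threshold`, over the whole series. Isolated cold
#' days (runs shorter than `run`) do not count.
#'
#' @inheritParams wintering_onset
#' @return Total days (integer-valued numeric).
#' @export
cold_period_length <- function(weather, threshold = 10, run = 3) {
  check_weather(weather)
  runs <- cold_runs(weather$t_mean < threshold, run)
  sum(runs$lengths)
}

#' Mean daily temperature during grain filling
#'
#' Arithmetic mean of daily mean temperature over `[flowering, end_filling]`,
#' endpoints included.
#'
#' @inheritParams accumulated_temperature
#' @param flowering,end_filling Dates bounding the filling stage;
#'   `flowering < end_filling`.
#' @return Mean temperature in degrees C.
#' @export
mean_filling_temperature <- function(weather, flowering, end_filling) {
  flowering <- as.Date(flowering); end_filling <- as.Date(end_filling)
  if (!(flowering < end_filling)) {
    stop("`flowering` must precede `end_filling`", call. = FALSE)
  }
  check_weather(weather)
  if (flowering < min(weather$date) || end_filling > max(weather$date)) {
    stop("filling interval outside the weather series", call. = FALSE)
  }
  sel <- weather$date >= flowering & weather$date <= end_filling
  mean(weather$t_mean[sel])
}

#' Season thermal and phenology summary per treatment
#'
#' Combines a weather series and a phenology table into the per-treatment
#' summary conventionally tabulated for sowing-date trials: days from sowing
#' to flowering, filling duration, accumulated temperature over the whole
#' growth period (sowing to end of filling), thermal time from sowing to the
#' wintering onset, and mean filling temperature.
#'
#' @param weather Weather data frame (`date`, `t_mean`, optionally a
#'   `season` column when several seasons are stacked).
#' @param phenology Data frame with columns `season`, `sowing_date`, `stage`,
#'   `date`; stages must include `sowing`, `flowering` and `maturity` (the
#'   end of filling). A `wintering` stage is used when present, otherwise the
#'   onset is derived from the weather with [wintering_onset()].
#' @param base Base temperature for thermal sums (default 0).
#' @param threshold,run Wintering rule passed to [wintering_onset()].
#' @return A tibble with one row per `(season, sowing_date)` and columns
#'   `days_to_flowering`, `filling_days`, `accum_temp_whole`,
#'   `thermal_sow_to_wintering`, `mean_filling_temp`.
#' @export
thermal_summary <- function(weather, phenology, base = 0, threshold = 10, run = 3) {
  need <- c("season", "sowing_date", "stage", "date")
  if (!all(need %in% names(phenology))) {
    stop("phenology table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  phenology <- tibble::as_tibble(phenology)
  phenology$date <- as.Date(phenology$date)
  groups <- dplyr::group_split(dplyr::group_by(phenology, .data$season, .data$sowing_date))
  purrr::map_dfr(groups, function(g) {
    wx <- if ("season" %in% names(weather)) {
      weather[weather$season == g$season[1L], , drop = FALSE]
    } else weather
    stage_date <- function(s) {
      d <- g$date[g$stage == s]
      if (length(d) != 1L) stop("treatment ", g$season[1L], "/", g$sowing_date[1L],
                                " needs exactly one `", s, "` stage", call. = FALSE)
      d
    }
    sowing <- stage_date("sowing")
    flowering <- stage_date("flowering")
    maturity <- stage_date("maturity")
    winter <- if ("wintering" %in% g$stage) stage_date("wintering") else {
      wintering_onset(wx, after = sowing, threshold = threshold, run = run)
    }
    tibble::tibble(
      season = g$season[1L],
      sowing_date = g$sowing_date[1L],
      days_to_flowering = as.numeric(flowering - sowing),
      filling_days = as.numeric(maturity - flowering),
      accum_temp_whole = accumulated_temperature(wx, sowing, maturity, base),
      thermal_sow_to_wintering = if (is.na(winter)) NA_real_
        else if (winter <= sowing) 0
        else accumulated_temperature(wx, sowing, winter - 1, base),
      mean_filling_temp = mean_filling_temperature(wx, flowering, maturity)
    )
  })
}

check_summary <- function(summaries, cols) {
  stopifnot(is.data.frame(summaries))
  need <- c("season", "sowing_date", cols)
  if (!all(need %in% names(summaries))) {
    stop("summary table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(summaries)
}

#' Phenology-duration changes relative to a reference sowing date
#'
#' For each non-reference sowing date, computes the per-season reduction in
#' days from sowing to flowering ("flowering moved forward by") and in total
#' growth duration (days to flowering plus filling days), then averages
#' across seasons. Differences are computed within each season first, so the
#' cross-season average matches the convention used in trial reports.
#'
#' @param summaries A per-treatment summary table (as from
#'   [thermal_summary()]) with columns `season`, `sowing_date`,
#'   `days_to_flowering`, `filling_days`.
#' @param reference The reference sowing-date label, present in every season.
#' @return A tibble with one row per sowing date (the reference row is all
#'   zeros): `flowering_advance_d` and `duration_reduction_d` (cross-season
#'   means, positive when the treatment flowers earlier / grows for fewer
#'   days than the reference).
#' @export
duration_deltas <- function(summaries, reference) {
  summaries <- check_summary(summaries, c("days_to_flowering", "filling_days"))
  deltas <- per_season_reference_delta(
    summaries, reference,
    function(ref, trt) tibble::tibble(
      flowering_advance_d = ref$days_to_flowering - trt$days_to_flowering,
      duration_reduction_d = (ref$days_to_flowering + ref$filling_days) -
        (trt$days_to_flowering + trt$filling_days)
    )
  )
  dplyr::summarise(dplyr::group_by(deltas, .data$sowing_date),
                   flowering_advance_d = mean(.data$flowering_advance_d),
                   duration_reduction_d = mean(.data$duration_reduction_d),
                   .groups = "drop")
}

#' Pre-winter thermal-time reduction relative to a reference sowing date
#'
#' Per-season percentage reduction in thermal time from sowing to wintering,
#' `(ref - treatment)/ref * 100`, averaged across seasons. Both the raw mean
#' and its integer rounding (the reporting convention) are returned.
#'
#' @param summaries Summary table with columns `season`, `sowing_date`,
#'   `thermal_sow_to_wintering`.
#' @inheritParams duration_deltas
#' @return A tibble per sowing date (0 for the reference itself) with
#'   `reduction_pct` (raw cross-season mean) and `reduction_pct_rounded`
#'   (nearest integer).
#' @export
thermal_reduction_pct <- function(summaries, reference) {
  summaries <- check_summary(summaries, "thermal_sow_to_wintering")
  if (any(summaries$thermal_sow_to_wintering[summaries$sowing_date == reference] == 0)) {
    stop("reference thermal time is zero; percentage reduction undefined", call. = FALSE)
  }
  deltas <- per_season_reference_delta(
    summaries, reference,
    function(ref, trt) tibble::tibble(
      reduction_pct = (ref$thermal_sow_to_wintering - trt$thermal_sow_to_wintering) /
        ref$thermal_sow_to_wintering * 100
    )
  )
  out <- dplyr::summarise(dplyr::group_by(deltas, .data$sowing_date),
                          reduction_pct = mean(.data$reduction_pct),
                          .groups = "drop")
  out$reduction_pct_rounded <- round(out$reduction_pct)
  out
}

# Pair every treatment with the reference within each season and apply
# `f(ref_row, treatment_row)`; the reference paired with itself gives zeros.
per_season_reference_delta <- function(summaries, reference, f) {
  seasons <- unique(summaries$season)
  purrr::map_dfr(seasons, function(s) {
    season_rows <- summaries[summaries$season == s, , drop = FALSE]
    ref <- season_rows[season_rows$sowing_date == reference, , drop = FALSE]
    if (nrow(ref) != 1L) {
      stop("reference sowing date `", reference, "` missing (or duplicated) in season ",
           s, call. = FALSE)
    }
    purrr::map_dfr(seq_len(nrow(season_rows)), function(i) {
      dplyr::bind_cols(
        tibble::tibble(season = s, sowing_date = season_rows$sowing_date[i]),
        f(ref, season_rows[i, , drop = FALSE])
      )
    })
  })
}
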