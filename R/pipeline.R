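#' Run the full sowing-date analysis pipeline
#'
#' Orchestrates every analysis stage over one experiment's tables: logistic
#' fits per treatment and variable ([fit_growth_table()]), closed-form
#' characteristic values ([eigenvalue_table()]), thermal/phenology summaries
#' ([thermal_summary()]) with duration and thermal-time changes relative to
#' the reference sowing date, treatment-mean yields with losses relative to
#' the normal date, and the yield vs mature/jointing ratio regressions with
#' threshold solving ([fit_ratio_regression()]). Treatments whose growth
#' series cannot be fitted are flagged in the fit table's `note` column and
#' do not abort the run.
#'
#' @param weather,growth,yields,phenology Data frames in the package's CSV
#'   dialects, or paths to such CSV files, or a `synthetic_experiment` passed
#'   as `weather` (in which case the other tables are taken from it).
#' @param reference Reference (earliest) sowing-date label for
#'   duration/thermal deltas; defaults to the first label encountered.
#' @param normal Normal sowing-date label for yield losses; defaults to the
#'   highest-yielding date.
#' @param base Base temperature for thermal sums (degrees C, default 0).
#' @param threshold,run Wintering-onset rule (see [wintering_onset()]).
#' @param target Target grain yield for ratio-threshold solving (kg/ha).
#' @param jointing_stage,maturity_stage Stage labels used to form the
#'   mature-to-jointing accumulation ratios from the growth table.
#' @return A list of class `wheatdyn_report` with tibbles `fits`,
#'   `eigenvalues`, `thermal`, `duration_deltas`, `thermal_reduction`,
#'   `yield_summary`, `loss_per_day`, `ratio_points`, and per-variable
#'   `ratio_regression` results.
#' @examples
#' exp <- make_experiment(synthetic_config(seed = 42))
#' rep <- run_pipeline(exp)
#' rep$eigenvalues
#' @export
run_pipeline <- function(weather, growth = NULL, yields = NULL, phenology = NULL,
                         reference = NULL, normal = NULL,
                         base = 0, threshold = 10, run = 3, target = 6000,
                         jointing_stage = "jointing", maturity_stage = "maturity") {
  if (inherits(weather, "synthetic_experiment")) {
    exp <- weather
    weather <- exp$weather; growth <- exp$growth
    yields <- exp$yields; phenology <- exp$phenology
  }
  weather <- if (is.character(weather)) read_weather_csv(weather) else tibble::as_tibble(weather)
  growth <- if (is.character(growth)) read_growth_csv(growth) else tibble::as_tibble(growth)
  yields <- if (is.character(yields)) read_yield_csv(yields) else tibble::as_tibble(yields)
  phenology <- if (is.character(phenology)) read_phenology_csv(phenology) else tibble::as_tibble(phenology)

  fits <- fit_growth_table(growth)
  ok <- !is.na(fits$k)
  eig <- eigenvalue_table(fits[ok, c("season", "sowing_date", "variable",
                                     "w_max", "a", "k")])
  thermal <- thermal_summary(weather, phenology, base = base,
                             threshold = threshold, run = run)
  if (is.null(reference)) {
    sow <- phenology[phenology$stage == "sowing", , drop = FALSE]
    reference <- sow$sowing_date[which.min(as.Date(sow$date))]
  }
  deltas <- duration_deltas(thermal, reference)
  reduction <- thermal_reduction_pct(thermal, reference)

  yield_means <- dplyr::summarise(
    dplyr::group_by(yields, .data$season, .data$sowing_date),
    grain_yield = mean(.data$grain_yield), n = dplyr::n(), .groups = "drop"
  )
  if (is.null(normal)) {
    by_date <- dplyr::summarise(dplyr::group_by(yield_means, .data$sowing_date),
                                y = mean(.data$grain_yield), .groups = "drop")
    normal <- by_date$sowing_date[which.max(by_date$y)]
  }
  yield_summary <- dplyr::mutate(
    dplyr::group_by(yield_means, .data$season),
    loss_pct = yield_loss(.data$grain_yield[.data$sowing_date == normal],
                          .data$grain_yield)
  )
  yield_summary <- dplyr::ungroup(yield_summary)

  phen_days <- stage_days_table(phenology, c(jointing_stage, maturity_stage))
  ratio_points <- growth_ratio_points(growth, phen_days, yield_means,
                                      jointing_stage, maturity_stage)
  ratio_fits <- lapply(split(ratio_points, ratio_points$variable),
                       fit_ratio_regression, target = target)

  loss_reg <- tryCatch(
    loss_per_day_regression(yield_means, normal,
                            offsets = sowing_offsets(phenology, normal)),
    error = function(e) tibble::tibble(method = character(), slope = numeric(),
                                       se = numeric(), intercept = numeric())
  )

  structure(
    list(
      fits = fits, eigenvalues = eig, thermal = thermal,
      duration_deltas = deltas, thermal_reduction = reduction,
      yield_summary = yield_summary, loss_per_day = loss_reg,
      ratio_points = ratio_points, ratio_regression = ratio_fits,
      reference = reference, normal = normal, target = target
    ),
    class = "wheatdyn_report"
  )
}

# days-after-sowing of selected stages, per treatment
stage_days_table <- function(phenology, stages) {
  phenology$date <- as.Date(phenology$date)
  groups <- dplyr::group_split(dplyr::group_by(tibble::as_tibble(phenology),
                                               .data$season, .data$sowing_date))
  purrr::map_dfr(groups, function(g) {
    sowing <- g$date[g$stage == "sowing"]
    out <- tibble::tibble(season = g$season[1L], sowing_date = g$sowing_date[1L])
    for (s in stages) {
      d <- g$date[g$stage == s]
      out[[s]] <- if (length(d) == 1L && length(sowing) == 1L)
        as.numeric(d - sowing) else NA_real_
    }
    out
  })
}

# observed mature/jointing accumulation ratios joined to treatment-mean yields
growth_ratio_points <- function(growth, phen_days, yield_means,
                                jointing_stage, maturity_stage) {
  means <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(growth),
                    .data$season, .data$sowing_date, .data$variable, .data$stage),
    value = mean(.data$value), .groups = "drop"
  )
  j <- means[means$stage == jointing_stage, ]
  m <- means[means$stage == maturity_stage, ]
  pts <- dplyr::inner_join(
    dplyr::rename(j[c("season", "sowing_date", "variable", "value")],
                  jointing_value = "value"),
    dplyr::rename(m[c("season", "sowing_date", "variable", "value")],
                  maturity_value = "value"),
    by = c("season", "sowing_date", "variable")
  )
  pts$ratio <- pts$maturity_value / pts$jointing_value
  dplyr::inner_join(pts, yield_means[c("season", "sowing_date", "grain_yield")],
                    by = c("season", "sowing_date"))
}

# day offsets of each sowing-date label from the normal date, taken from the
# phenology's sowing rows (identical across seasons in a sowing-date design)
sowing_offsets <- function(phenology, normal) {
  sow <- phenology[phenology$stage == "sowing",
                   c("season", "sowing_date", "date")]
  s1 <- sow[sow$season == sow$season[1L], , drop = FALSE]
  nd <- as.Date(s1$date[s1$sowing_date == normal])
  if (length(nd) != 1L) stop("normal sowing date `", normal,
                             "` not found in phenology", call. = FALSE)
  setNames(abs(as.numeric(as.Date(s1$date) - nd)), s1$sowing_date)
}

#' @export
print.wheatdyn_report <- function(x, ...) {
  cat("Sowing-date analysis report\n")
  cat("  reference:", x$reference, "  normal:", x$normal,
      "  target:", x$target, "kg/ha\n")
  cat("  fits:", nrow(x$fits), "treatments (",
      sum(is.na(x$fits$k)), "flagged )\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes each result table of a [run_pipeline()] report as a CSV file and
#' the ratio-regression summaries as JSON.
#'
#' @param report A `wheatdyn_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "wheatdyn_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("fits", "eigenvalues", "thermal", "duration_deltas",
              "thermal_reduction", "yield_summary", "loss_per_day",
              "ratio_points")
  paths <- character(0)
  for (nm in tables) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(report[[nm]], p)
    paths <- c(paths, p)
  }
  rr <- purrr::map(report$ratio_regression, function(r) {
    list(per_season = r$per_season, threshold_mean = r$threshold_mean,
         target = r$target)
  })
  p <- file.path(dir, "ratio_regression.json")
  jsonlite::write_json(rr, p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(paths, p))
}
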