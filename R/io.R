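#' Read a daily weather CSV
#'
#' Expected columns: `date` (ISO-8601), `t_min`, `t_max`, `precipitation`,
#' optionally `t_mean` and `season`. When `t_mean` is absent it is computed
#' as `(t_min + t_max)/2` with a message. Dates are validated to be
#' consecutive (per season when a `season` column is present).
#'
#' @param path Path to the CSV file.
#' @return A weather tibble.
#' @export
read_weather_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("date", "t_min", "t_max")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("weather CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x$date <- parse_date_column(x$date, "weather")
  if (!"t_mean" %in% names(x)) {
    message("weather CSV has no `t_mean`; using (t_min + t_max)/2")
    x$t_mean <- (x$t_min + x$t_max) / 2
  }
  if (any(x$t_min > x$t_mean | x$t_mean > x$t_max)) {
    stop("weather CSV: need t_min <= t_mean <= t_max on every day", call. = FALSE)
  }
  groups <- if ("season" %in% names(x)) split(x, x$season) else list(x)
  for (g in groups) check_weather(g[order(g$date), , drop = FALSE])
  tibble::as_tibble(x)
}

parse_date_column <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(d) || any(is.na(d))) {
    stop(what, " CSV: unparseable `date` values (ISO-8601 expected)", call. = FALSE)
  }
  d
}

#' Read a per-stem growth CSV
#'
#' Expected columns: `season`, `sowing_date`, `stage`, `days_after_sowing`,
#' `variable` (`dma`/`na`), `value`, `replicate`.
#'
#' @param path Path to the CSV file.
#' @return A growth tibble suitable for [fit_growth_table()].
#' @export
read_growth_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("season", "sowing_date", "stage", "days_after_sowing",
            "variable", "value", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("growth CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x$variable <- tolower(x$variable)
  bad <- setdiff(unique(x$variable), c("dma", "na"))
  if (length(bad)) stop("growth CSV: unknown variable(s) ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x$value)) || any(x$value < 0)) {
    stop("growth CSV: `value` must be finite and >= 0", call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read a plot-level yield CSV
#'
#' Expected columns: `season`, `sowing_date`, `grain_yield`, `spike_number`,
#' `kernels_per_spike`, `tkw`, `replicate` (measure columns beyond
#' `grain_yield` optional).
#'
#' @param path Path to the CSV file.
#' @return A yield tibble.
#' @export
read_yield_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("season", "sowing_date", "grain_yield")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("yield CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$grain_yield <= 0)) stop("yield CSV: grain_yield must be > 0", call. = FALSE)
  tibble::as_tibble(x)
}

#' Read a phenology CSV
#'
#' Expected columns: `season`, `sowing_date`, `stage`, `date` (ISO-8601).
#' Stage dates must be strictly increasing within each treatment.
#'
#' @param path Path to the CSV file.
#' @return A phenology tibble.
#' @export
read_phenology_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("season", "sowing_date", "stage", "date")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("phenology CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x$date <- parse_date_column(x$date, "phenology")
  ok <- vapply(split(x, paste(x$season, x$sowing_date)),
               function(g) !is.unsorted(g$date[order(match(g$stage, g$stage))],
                                        strictly = FALSE),
               logical(1))
  if (!all(ok)) stop("phenology CSV: stage dates must not decrease within a treatment",
                     call. = FALSE)
  tibble::as_tibble(x)
}

#' Write a synthetic experiment to CSV files plus a truth JSON
#'
#' Emits `weather.csv`, `phenology.csv`, `growth.csv`, `yield.csv` in exactly
#' the dialects the `read_*_csv()` functions consume, plus `truth.json`
#' recording the generating parameters.
#'
#' @param experiment A `synthetic_experiment` from [make_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    weather = file.path(dir, "weather.csv"),
    phenology = file.path(dir, "phenology.csv"),
    growth = file.path(dir, "growth.csv"),
    yield = file.path(dir, "yield.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(experiment$weather, paths[["weather"]])
  readr::write_csv(experiment$phenology, paths[["phenology"]])
  readr::write_csv(experiment$growth, paths[["growth"]])
  readr::write_csv(experiment$yields, paths[["yield"]])
  truth <- experiment$truth
  jsonlite::write_json(
    list(
      params = purrr::map(truth$params, unclass),
      ratios = truth$ratios,
      yield_models = truth$yield_models,
      thermal_thresholds = as.list(truth$thermal_thresholds),
      seed = truth$config$seed
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Render a result table as CSV, JSON or markdown text
#'
#' CSV and JSON renderings are lossless (full numeric precision); the
#' markdown rendering is for human inspection and honours an optional
#' per-column `digits` rounding.
#'
#' @param result A data frame.
#' @param dialect One of `"csv"`, `"json"`, `"markdown"`.
#' @param digits Optional number of decimals for markdown cells.
#' @return A single string.
#' @export
render_table <- function(result, dialect = c("csv", "json", "markdown"),
                         digits = NULL) {
  stopifnot(is.data.frame(result))
  dialect <- match.arg(dialect)
  switch(dialect,
    csv = readr::format_csv(result),
    json = as.character(jsonlite::toJSON(result, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA)),
    markdown = render_markdown(result, digits)
  )
}

render_markdown <- function(df, digits = NULL) {
  fmt <- function(v) {
    if (is.numeric(v) && !is.null(digits)) v <- round(v, digits)
    as.character(v)
  }
  cols <- names(df)
  if (nrow(df) == 0L) {
    body <- character(0)
  } else {
    cells <- lapply(df, fmt)
    body <- vapply(seq_len(nrow(df)), function(i) {
      paste0("| ", paste(vapply(cells, `[[`, "", i), collapse = " | "), " |")
    }, character(1))
  }
  paste(c(
    paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    body, ""
  ), collapse = "\n")
}
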