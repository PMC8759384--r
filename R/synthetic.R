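# Run `code` under a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic sowing-date experiment
#'
#' Assembles and validates the configuration driving [make_experiment()].
#' Defaults emulate a two-season winter wheat sowing-date trial in a
#' subtropical monsoon climate: four sowings from late October to late
#' November, a sinusoidal temperature year with a mid-January trough and
#' AR(1) day-to-day noise, logistic per-stem accumulation with parameters in
#' the envelopes typical of such trials, six stage-sampled observations per
#' curve with multiplicative log-normal noise, and plot yields linear in the
#' mature-to-jointing dry-matter ratio.
#'
#' @param seed Integer RNG seed (mandatory; the generator is fully
#'   deterministic given the config and seed).
#' @param n_seasons Number of seasons (default 2).
#' @param start_year First season's sowing-year (default 2018; season `i`
#'   spans 1 October of `start_year + i - 1` to 30 June of the next year).
#' @param sowing_dates Month-day strings (`"mm-dd"`) of the sowing dates.
#' @param weather List: `mean` and `amplitude` of the annual sinusoid
#'   (degrees C), `trough` (`"mm-dd"` of the coldest day), `noise_sd`
#'   (stationary sd of the AR(1) deviation, degrees C), `ar1` (lag-1
#'   coefficient in `[0, 1)`), `half_range` (half the daily min-max spread).
#' @param growth Per-variable parameter envelopes: for each of `dma` and
#'   `na`, ranges for `w_max`, `k` (per day, must stay within (0.05, 0.15))
#'   and for the inflection time `tm` (days after sowing); the shape constant
#'   is derived as `a = exp(k * tm)` so sampled curves always inflect within
#'   the season.
#' @param sampling List: `thermal_thresholds`, a named increasing vector of
#'   degree-day thresholds (base 0, from sowing) at which growth is sampled
#'   (default six stages: seedling, tillering, jointing, booting, flowering,
#'   maturity); `noise_sd`, sd of the multiplicative log-normal observation
#'   noise.
#' @param yield List: `slope` and `intercept` vectors (recycled per season)
#'   of the yield \eqn{\sim} DMA mature/jointing ratio line, `sd` of the additive
#'   yield noise (kg/ha), `n_rep` replicates per treatment.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_seasons = 2L,
                             start_year = 2018L,
                             sowing_dates = c("10-28", "11-05", "11-13", "11-21"),
                             weather = list(),
                             growth = list(),
                             sampling = list(),
                             yield = list()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  }
  weather <- utils::modifyList(
    list(mean = 18, amplitude = 9.6, trough = "01-15",
         noise_sd = 1.5, ar1 = 0.6, half_range = 4),
    weather
  )
  growth <- utils::modifyList(
    list(
      dma = list(w_max = c(3.0, 4.0), k = c(0.070, 0.134), tm = c(130, 160)),
      na  = list(w_max = c(44, 55),  k = c(0.072, 0.111), tm = c(120, 145))
    ),
    growth
  )
  sampling <- utils::modifyList(
    list(
      thermal_thresholds = c(seedling = 250, tillering = 500, jointing = 1430,
                             booting = 1580, flowering = 1700, maturity = 2350),
      noise_sd = 0.05
    ),
    sampling
  )
  yield <- utils::modifyList(
    list(slope = c(306.03, 636.93), intercept = c(4511.69, 3924.05),
         sd = 200, n_rep = 3L),
    yield
  )
  stopifnot(weather$ar1 >= 0, weather$ar1 < 1, weather$noise_sd >= 0,
            sampling$noise_sd >= 0, yield$sd >= 0,
            length(sampling$thermal_thresholds) >= 4L,
            !is.unsorted(sampling$thermal_thresholds, strictly = TRUE))
  for (v in c("dma", "na")) {
    kr <- growth[[v]]$k
    if (min(kr) <= 0.05 || max(kr) >= 0.15) {
      stop("growth `k` range for ", v, " must lie within (0.05, 0.15)", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_seasons = as.integer(n_seasons),
         start_year = as.integer(start_year), sowing_dates = sowing_dates,
         weather = weather, growth = growth, sampling = sampling, yield = yield),
    class = "synthetic_config"
  )
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature as an annual sinusoid with its trough at the
#' configured mid-winter date plus stationary AR(1) noise; `t_min`/`t_max`
#' are the mean minus/plus `half_range`; precipitation is an intermittent
#' gamma process. With `noise_sd = 0` the series is the exact sinusoid. The
#' winter trough guarantees that a wintering onset exists for autumn sowing.
#'
#' @param config A [synthetic_config()].
#' @param season Season index in `1:n_seasons`.
#' @param seed Optional seed; when `NULL` (default) the current RNG stream is
#'   consumed (as inside [make_experiment()]).
#' @return A weather tibble: `season`, `date`, `t_min`, `t_mean`, `t_max`,
#'   `precipitation`.
#' @export
gen_weather <- function(config, season = 1L, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(seed, {
    year <- config$start_year + season - 1L
    dates <- seq(as.Date(sprintf("%d-10-01", year)),
                 as.Date(sprintf("%d-06-30", year + 1L)), by = "day")
    trough <- as.Date(sprintf("%d-%s", year + 1L, config$weather$trough))
    phase <- as.numeric(dates - trough) / 365.25
    det <- config$weather$mean - config$weather$amplitude * cos(2 * pi * phase)
    n <- length(dates)
    if (config$weather$noise_sd > 0) {
      innov_sd <- config$weather$noise_sd * sqrt(1 - config$weather$ar1^2)
      eps <- numeric(n)
      eps[1L] <- rnorm(1L, 0, config$weather$noise_sd)
      for (i in seq_len(n - 1L)) {
        eps[i + 1L] <- config$weather$ar1 * eps[i] + rnorm(1L, 0, innov_sd)
      }
    } else {
      eps <- numeric(n)
    }
    t_mean <- det + eps
    wet <- rbinom(n, 1L, 0.25)
    precip <- wet * round(rgamma(n, shape = 0.8, scale = 8), 1)
    tibble::tibble(
      season = season_label(config, season),
      date = dates,
      t_min = t_mean - config$weather$half_range,
      t_mean = t_mean,
      t_max = t_mean + config$weather$half_range,
      precipitation = precip
    )
  })
}

season_label <- function(config, season) {
  year <- config$start_year + season - 1L
  sprintf("%d-%d", year, year + 1L)
}

#' Generate one noisy growth series from known logistic truth
#'
#' Samples the logistic curve at the given stage days and applies
#' multiplicative log-normal noise: `w_i = W(t_i) * exp(e_i)`,
#' `e_i ~ N(0, noise_sd^2)`. Multiplicative noise reflects that per-stem
#' accumulation is positive and spans orders of magnitude between seedling
#' and maturity.
#'
#' @param truth A [logistic_params()] object (the generating parameters).
#' @param stage_days Strictly increasing vector of sampling days
#'   (length `>= 4`).
#' @param noise_sd Sd of the log-scale noise (`0` gives exact curve values).
#' @param seed Optional local seed (see [gen_weather()]).
#' @return A tibble with columns `t`, `w`.
#' @export
gen_growth_series <- function(truth, stage_days, noise_sd = 0.05, seed = NULL) {
  truth <- as_logistic_params(truth)
  if (length(stage_days) < 4L || is.unsorted(stage_days, strictly = TRUE)) {
    stop("`stage_days` must be >= 4 strictly increasing days (3 free parameters)",
         call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  with_local_seed(seed, {
    w <- as.numeric(logistic_value(truth, stage_days))
    if (noise_sd > 0) w <- w * exp(rnorm(length(w), 0, noise_sd))
    tibble::tibble(t = as.numeric(stage_days), w = w)
  })
}

#' Generate replicate plot yields from mature/jointing ratios
#'
#' Yields follow the linear model `yield = slope * ratio + intercept + e`,
#' `e ~ N(0, sd^2)`, with `n_rep` replicates per treatment.
#'
#' @param ratios A data frame with columns `season`, `sowing_date`, `ratio`.
#' @param model List with `slope`, `intercept`, `sd` (kg/ha) and `n_rep`.
#' @param seed Optional local seed.
#' @return A tibble `season`, `sowing_date`, `replicate`, `ratio`,
#'   `grain_yield`.
#' @export
gen_yields <- function(ratios, model, seed = NULL) {
  stopifnot(is.data.frame(ratios),
            all(c("season", "sowing_date", "ratio") %in% names(ratios)),
            is.finite(model$slope), is.finite(model$intercept))
  n_rep <- model$n_rep %||% 3L
  sd <- model$sd %||% 0
  with_local_seed(seed, {
    purrr::map_dfr(seq_len(nrow(ratios)), function(i) {
      mu <- model$slope * ratios$ratio[i] + model$intercept
      tibble::tibble(
        season = ratios$season[i],
        sowing_date = ratios$sowing_date[i],
        replicate = seq_len(n_rep),
        ratio = ratios$ratio[i],
        grain_yield = mu + rnorm(n_rep, 0, sd)
      )
    })
  })
}

#' Generate a complete synthetic sowing-date experiment
#'
#' Composes the weather, phenology, growth and yield generators into a full
#' experiment with recorded ground truth. One weather realisation is shared
#' by all sowing dates within a season (the field design: treatments differ
#' only in sowing date). Phenological stages are placed where the
#' accumulated temperature from each sowing date crosses the configured
#' thermal thresholds, so delayed sowing propagates into later, compressed
#' phenology exactly as thermal-time physiology dictates; the wintering date
#' additionally follows the cold-run rule ([wintering_onset()]). Yields are
#' generated from the true (noise-free) DMA mature/jointing ratios.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_experiment` with elements `weather`,
#'   `phenology` (stages `sowing`, `wintering`, and one per sampling
#'   threshold), `growth` (long table: `season`, `sowing_date`, `stage`,
#'   `days_after_sowing`, `variable`, `value`, `replicate`), `yields`, and
#'   `truth` (generating logistic parameters per treatment and variable,
#'   stage days, and the yield-model coefficients per season).
#' @examples
#' exp <- make_experiment(synthetic_config(seed = 42))
#' names(exp)
#' @export
make_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  thresholds <- config$sampling$thermal_thresholds
  stages <- names(thresholds)

  weather <- purrr::map_dfr(seq_len(config$n_seasons), function(s) gen_weather(config, s))

  acc <- list(); phen <- list(); growth <- list(); truth_params <- list()
  ratio_rows <- list()
  for (s in seq_len(config$n_seasons)) {
    lab <- season_label(config, s)
    wx <- weather[weather$season == lab, , drop = FALSE]
    year <- config$start_year + s - 1L
    for (sd_md in config$sowing_dates) {
      sowing <- as.Date(sprintf("%d-%s", year, sd_md))
      sd_lab <- sub("^0", "", format(sowing, "%d-%b"))
      sel <- wx$date >= sowing
      gdd <- cumsum(pmax(wx$t_mean[sel], 0))
      stage_days <- vapply(thresholds, function(th) {
        i <- which(gdd >= th)[1L]
        if (is.na(i)) NA_real_ else as.numeric(i - 1L)  # day 0 = sowing
      }, numeric(1))
      if (any(is.na(stage_days))) {
        stop("season too short/cool: thermal threshold never reached for sowing ",
             sd_lab, call. = FALSE)
      }
      winter <- wintering_onset(wx, after = sowing)
      if (is.na(winter)) {
        stop("weather too warm: no wintering onset after sowing ", sd_lab,
             call. = FALSE)
      }
      phen_rows <- tibble::tibble(
        season = lab, sowing_date = sd_lab,
        stage = c("sowing", "wintering", stages),
        date = c(sowing, winter, sowing + stage_days)
      )
      phen[[length(phen) + 1L]] <- phen_rows[order(phen_rows$date), ]
      for (v in c("dma", "na")) {
        env <- config$growth[[v]]
        k <- runif(1L, env$k[1L], env$k[2L])
        tm <- runif(1L, env$tm[1L], env$tm[2L])
        w_max <- runif(1L, env$w_max[1L], env$w_max[2L])
        pars <- logistic_params(w_max, exp(k * tm), k, variable = v)
        truth_params[[paste(lab, sd_lab, v, sep = "|")]] <- pars
        series <- gen_growth_series(pars, stage_days,
                                    noise_sd = config$sampling$noise_sd)
        growth[[length(growth) + 1L]] <- tibble::tibble(
          season = lab, sowing_date = sd_lab, stage = stages,
          days_after_sowing = series$t, variable = v, value = series$w,
          replicate = 1L
        )
        if (v == "dma") {
          w_true <- logistic_value(pars, stage_days)
          ratio_rows[[length(ratio_rows) + 1L]] <- tibble::tibble(
            season = lab, sowing_date = sd_lab,
            ratio = as.numeric(w_true[["maturity"]] / w_true[["jointing"]])
          )
        }
      }
    }
  }
  ratios <- dplyr::bind_rows(ratio_rows)
  yield_models <- purrr::map(seq_len(config$n_seasons), function(s) {
    list(slope = rep_len(config$yield$slope, config$n_seasons)[s],
         intercept = rep_len(config$yield$intercept, config$n_seasons)[s],
         sd = config$yield$sd, n_rep = config$yield$n_rep)
  })
  names(yield_models) <- vapply(seq_len(config$n_seasons), season_label,
                                character(1), config = config)
  yields <- purrr::map_dfr(names(yield_models), function(lab) {
    gen_yields(ratios[ratios$season == lab, , drop = FALSE], yield_models[[lab]])
  })

  structure(
    list(
      weather = weather,
      phenology = dplyr::bind_rows(phen),
      growth = dplyr::bind_rows(growth),
      yields = yields,
      truth = list(params = truth_params, ratios = ratios,
                   yield_models = yield_models,
                   thermal_thresholds = thresholds, config = config)
    ),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic sowing-date experiment\n")
  cat("  seasons:     ", paste(unique(x$weather$season), collapse = ", "), "\n")
  cat("  sowing dates:", paste(unique(x$phenology$sowing_date), collapse = ", "), "\n")
  cat("  growth rows: ", nrow(x$growth), "   yield rows:", nrow(x$yields), "\n")
  invisible(x)
}
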