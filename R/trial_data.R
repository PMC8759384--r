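#' Reference sowing-date trial: thermal and phenology summary
#'
#' Published per-treatment growth-time and weather statistics from a
#' two-season winter wheat sowing-date field trial on the Jianghan Plain
#' (middle-lower Yangtze River Basin; cv. Zhengmai 9023; four sowing dates,
#' 28 October to 21 November, in the 2018--2019 and 2019--2020 seasons).
#' These tables are bundled so that the derived statistics of the package
#' (thermal-time reductions, duration changes, correlations, ratio
#' thresholds) can be recomputed directly from the trial summaries.
#'
#' @return A tibble with columns `season`, `sowing_date`,
#'   `days_to_flowering` (d), `filling_days` (d), `accum_temp_whole`
#'   (degree-days, whole growth period), `thermal_sow_to_wintering`
#'   (degree-days), `mean_filling_temp` (degrees C).
#' @seealso [trial_yields()], [trial_logistic_coefficients()],
#'   [trial_ratio_equations()]
#' @export
trial_thermal_summary <- function() {
  tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    days_to_flowering = c(164, 159, 153, 149, 146, 143, 142, 138),
    filling_days = c(38, 37, 36, 36, 50, 46, 43, 39),
    accum_temp_whole = c(2141.2, 2048.6, 1978.9, 1985.2,
                         2304.6, 2187.1, 2140.7, 2028.8),
    thermal_sow_to_wintering = c(623.0, 486.2, 397.6, 310.2,
                                 741.6, 601.6, 469.3, 357.4),
    mean_filling_temp = c(20.08, 20.28, 20.48, 20.71,
                          17.93, 18.23, 19.84, 20.25)
  )
}

#' Reference sowing-date trial: grain yield and yield components
#'
#' Treatment-mean grain yield and yield components from the bundled
#' two-season sowing-date trial (see [trial_thermal_summary()]).
#'
#' @return A tibble with columns `season`, `sowing_date`, `grain_yield`
#'   (kg/ha), `spike_number` (10^4/ha), `kernels_per_spike`, `tkw`
#'   (1000-kernel weight, g).
#' @export
trial_yields <- function() {
  tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    grain_yield = c(6403.8, 6578.9, 5674.8, 5569.7,
                    6980.0, 7241.7, 5958.3, 5625.0),
    spike_number = c(444.0, 484.3, 437.7, 371.7, 432.0, 466.7, 411.7, 391.3),
    kernels_per_spike = c(40.8, 37.8, 37.9, 41.0, 40.9, 38.9, 40.5, 42.0),
    tkw = c(40.5, 40.6, 40.9, 41.1, 46.9, 47.2, 47.7, 48.1)
  )
}

#' Reference sowing-date trial: tiller counts
#'
#' Treatment-mean tiller populations from the bundled trial: counts at the
#' jointing and maturity stages, the peak count, and the published
#' percentage of productive tillers.
#'
#' @return A tibble with columns `season`, `sowing_date`, `tillers_jointing`,
#'   `tillers_maturity`, `peak_tillers` (all counts per m^2) and
#'   `productive_pct`.
#' @export
trial_tillers <- function() {
  tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    tillers_jointing = c(530.67, 636.00, 596.00, 640.00,
                         524.00, 642.33, 660.00, 701.33),
    tillers_maturity = c(444.00, 484.33, 437.67, 371.67,
                         432.00, 466.67, 411.67, 391.33),
    peak_tillers = c(785.33, 754.67, 596.00, 640.00,
                     1078.67, 876.00, 660.00, 701.33),
    productive_pct = c(56.65, 64.23, 73.45, 58.33, 40.06, 53.48, 62.38, 55.80)
  )
}

#' Reference sowing-date trial: fitted logistic coefficients
#'
#' Published logistic regression coefficients `(w_max, a, k)` and `R^2` for
#' per-stem dry-matter accumulation (`variable = "dma"`, g/stem) and nitrogen
#' accumulation (`variable = "na"`, mg/stem) against days after sowing, for
#' every season-by-sowing-date treatment of the bundled trial. Each curve was
#' fitted to six stage-sampled time points.
#'
#' Feeding these rows to [eigenvalue_table()] reproduces the published
#' characteristic-value tables ([trial_eigenvalues()]) in closed form.
#'
#' @return A tibble with columns `season`, `sowing_date`, `variable`,
#'   `w_max`, `a`, `k`, `r_squared`.
#' @export
trial_logistic_coefficients <- function() {
  dma <- tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    variable = "dma",
    w_max = c(3.6217, 3.0897, 3.5946, 3.9149, 3.1812, 3.1866, 3.0814, 3.2251),
    a = c(4101240.31, 420518907.20, 45779.88, 48761.68,
          109524.11, 91308.58, 20681.61, 10799.99),
    k = c(0.0976, 0.1339, 0.0701, 0.0722, 0.0862, 0.0836, 0.0734, 0.0692),
    r_squared = c(0.9941, 0.9909, 0.9992, 0.9995, 0.9925, 0.9949, 0.9977, 0.9981)
  )
  na <- tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    variable = "na",
    w_max = c(44.2207, 44.6148, 46.4937, 50.2932,
              44.8498, 51.9671, 52.0154, 54.2685),
    a = c(436306.39, 839280.29, 1030959.01, 3464573.17,
          28575.36, 12335.05, 12551.56, 62975.43),
    k = c(0.0906, 0.0960, 0.0986, 0.1109, 0.0834, 0.0724, 0.0741, 0.0888),
    r_squared = c(0.9808, 0.9874, 0.9932, 0.9980, 0.9787, 0.9782, 0.9838, 0.9872)
  )
  dplyr::bind_rows(dma, na)
}

#' Reference sowing-date trial: published characteristic values
#'
#' The published fast-accumulation-phase characteristic values (onset `t1`,
#' termination `t2`, duration, mean rate `vt`, inflection time `tm`, maximum
#' rate `vm`) for every treatment and variable of the bundled trial, at the
#' precision they were printed (times to 0.1 d, rates to 0.01 per day; DMA
#' rates in g/stem/d, nitrogen rates in mg/stem/d). Used to validate the
#' closed-form [growth_eigenvalues()] derivation.
#'
#' @return A tibble with columns `season`, `sowing_date`, `variable`, `t1`,
#'   `t2`, `duration`, `vt`, `tm`, `vm`.
#' @export
trial_eigenvalues <- function() {
  dma <- tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    variable = "dma",
    t1 = c(142.5, 138.5, 134.2, 131.4, 119.4, 120.9, 117.4, 115.3),
    t2 = c(169.5, 158.2, 171.8, 167.9, 150.0, 152.4, 153.3, 153.3),
    duration = c(27.0, 19.7, 37.5, 36.5, 30.6, 31.5, 35.9, 38.1),
    vt = c(0.08, 0.09, 0.06, 0.06, 0.06, 0.06, 0.05, 0.05),
    tm = c(156.0, 148.4, 153.0, 149.6, 134.7, 136.6, 135.4, 134.3),
    vm = c(0.09, 0.10, 0.06, 0.07, 0.07, 0.07, 0.06, 0.06)
  )
  na <- tibble::tibble(
    season = rep(c("2018-2019", "2019-2020"), each = 4L),
    sowing_date = rep(c("28-Oct", "5-Nov", "13-Nov", "21-Nov"), 2L),
    variable = "na",
    t1 = c(128.8, 128.4, 127.0, 123.9, 107.3, 111.9, 109.6, 109.6),
    t2 = c(157.9, 155.8, 153.7, 147.7, 138.8, 148.3, 145.1, 139.3),
    duration = c(29.1, 27.4, 26.7, 23.8, 31.6, 36.4, 35.5, 29.7),
    vt = c(0.88, 0.94, 1.01, 1.22, 0.82, 0.82, 0.85, 1.06),
    tm = c(143.3, 142.1, 140.4, 135.8, 123.1, 130.1, 127.3, 124.5),
    vm = c(1.00, 1.07, 1.15, 1.39, 0.93, 0.94, 0.96, 1.20)
  )
  dplyr::bind_rows(dma, na)
}

#' Reference sowing-date trial: yield vs mature/jointing ratio lines
#'
#' Published per-season linear regressions of grain yield (kg/ha) on the
#' mature-to-jointing accumulation ratio, for dry matter (M_D/J_D) and
#' nitrogen (M_N/J_N). Solving each line for a 6,000 kg/ha target with
#' [ratio_threshold()] and averaging across seasons yields the trial's
#' headline threshold ratios.
#'
#' @return A tibble with columns `variable`, `season`, `slope`, `intercept`.
#' @export
trial_ratio_equations <- function() {
  tibble::tibble(
    variable = c("dma", "dma", "na", "na"),
    season = rep(c("2018-2019", "2019-2020"), 2L),
    slope = c(306.03, 636.93, 698.98, 1273.29),
    intercept = c(4511.69, 3924.05, 3904.74, 3485.91)
  )
}
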