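test_that("accumulated temperature sums degree days inclusively and additively", {
  w <- flat_weather(rep(10, 10))
  expect_equal(accumulated_temperature(w, w$date[1], w$date[10]), 100)

  # additivity with the split day assigned to the later interval
  cfg <- synthetic_config(seed = 3)
  wx <- gen_weather(cfg, 1, seed = 3)
  a <- wx$date[20]; b <- wx$date[200]; s <- wx$date[100]
  expect_equal(
    accumulated_temperature(wx, a, s - 1) + accumulated_temperature(wx, s, b),
    accumulated_temperature(wx, a, b),
    tolerance = 1e-12
  )

  # brute-force daily loop oracle
  brute <- 0
  for (i in seq_len(nrow(wx))) {
    if (wx$date[i] >= a && wx$date[i] <= b) brute <- brute + max(wx$t_mean[i], 0)
  }
  expect_equal(accumulated_temperature(wx, a, b), brute, tolerance = 1e-9)

  # base subtraction is a no-op at base 0 when all temperatures are positive
  wpos <- flat_weather(c(5, 8, 12))
  expect_equal(accumulated_temperature(wpos, wpos$date[1], wpos$date[3], base = 0),
               sum(wpos$t_mean))

  expect_error(accumulated_temperature(w, w$date[1] - 5, w$date[3]), "outside")
  expect_error(accumulated_temperature(w, w$date[3], w$date[1]), "after")
})

test_that("wintering onset finds the first qualifying cold run", {
  w <- flat_weather(c(12, 9, 9, 9, 12))
  expect_equal(wintering_onset(w), w$date[2])
  expect_true(is.na(wintering_onset(flat_weather(rep(11, 10)))))
  # a run shorter than `run` does not qualify
  expect_true(is.na(wintering_onset(flat_weather(c(12, 9, 9, 12, 12)))))
  # relaxing the run length can only move the onset earlier
  cfg <- synthetic_config(seed = 5)
  wx <- gen_weather(cfg, 1, seed = 5)
  o1 <- wintering_onset(wx, run = 1)
  o3 <- wintering_onset(wx, run = 3)
  expect_true(o1 <= o3)
  # injected cold spell at a known date is found
  wk <- flat_weather(rep(15, 60))
  wk$t_mean[31:40] <- 5
  expect_equal(wintering_onset(wk), wk$date[31])
})

test_that("cold period length counts only qualifying runs", {
  # two spells of 5 and 4 days separated by a warm day
  tm <- c(12, rep(5, 5), 12, rep(5, 4), 12)
  expect_equal(cold_period_length(flat_weather(tm)), 9)
  # runs of length 2 never count under the default 3-day rule
  expect_equal(cold_period_length(flat_weather(c(12, 5, 5, 12, 5, 5, 12))), 0)
  # a single 89-day spell
  expect_equal(cold_period_length(flat_weather(c(15, rep(6, 89), 15))), 89)
})

test_that("mean filling temperature averages the stage window", {
  w <- flat_weather(rep(20, 15))
  expect_equal(mean_filling_temperature(w, w$date[3], w$date[9]), 20)
  w2 <- flat_weather(c(18, 22))
  expect_equal(mean_filling_temperature(w2, w2$date[1], w2$date[2]), 20)
  cfg <- synthetic_config(seed = 9)
  wx <- gen_weather(cfg, 1, seed = 9)
  a <- wx$date[150]; b <- wx$date[190]
  expect_equal(mean_filling_temperature(wx, a, b),
               mean(wx$t_mean[wx$date >= a & wx$date <= b]), tolerance = 1e-12)
  expect_error(mean_filling_temperature(w, w$date[5], w$date[5]), "precede")
})

test_that("duration deltas reproduce the trial's flowering and growth-span changes", {
  sm <- trial_thermal_summary()
  dd <- duration_deltas(sm, reference = "28-Oct")
  # 16-day delay: flowering moved forward by mean(164-153, 146-142) = 7.5 d
  expect_equal(dd$flowering_advance_d[dd$sowing_date == "13-Nov"], 7.5)
  # full set of flowering advances vs the earliest sowing
  expect_equal(dd$flowering_advance_d[dd$sowing_date == "5-Nov"], 4.0)
  expect_equal(dd$flowering_advance_d[dd$sowing_date == "21-Nov"], 11.5)
  # 24-day delay: growth duration shortened by mean(202-185, 196-177) = 18 d
  expect_equal(dd$duration_reduction_d[dd$sowing_date == "21-Nov"], 18)
  # reference against itself is zero
  expect_equal(dd$flowering_advance_d[dd$sowing_date == "28-Oct"], 0)
  expect_equal(dd$duration_reduction_d[dd$sowing_date == "28-Oct"], 0)
  expect_error(duration_deltas(sm, reference = "1-Jan"), "missing")
})

test_that("pre-winter thermal-time reductions follow the per-season-then-average convention", {
  sm <- trial_thermal_summary()
  tr <- thermal_reduction_pct(sm, reference = "28-Oct")
  # 24-day delay: mean of (623.0-310.2)/623.0 and (741.6-357.4)/741.6 -> 51%
  expect_equal(tr$reduction_pct_rounded[tr$sowing_date == "21-Nov"], 51)
  r24 <- mean(c((623.0 - 310.2) / 623.0, (741.6 - 357.4) / 741.6)) * 100
  expect_equal(tr$reduction_pct[tr$sowing_date == "21-Nov"], r24, tolerance = 1e-12)
  # 8-day delay: raw mean 20.4%, within 1 point of the reported 21%
  expect_lte(abs(tr$reduction_pct_rounded[tr$sowing_date == "5-Nov"] - 21), 1)
  # 16-day delay within 1 point of the reported 37%
  expect_lte(abs(tr$reduction_pct_rounded[tr$sowing_date == "13-Nov"] - 37), 1)
  # identical thermal time means zero reduction
  expect_equal(tr$reduction_pct[tr$sowing_date == "28-Oct"], 0)

  sm0 <- sm
  sm0$thermal_sow_to_wintering[sm0$sowing_date == "28-Oct"] <- 0
  expect_error(thermal_reduction_pct(sm0, "28-Oct"), "zero")
})

test_that("thermal_summary composes stage dates and weather into the trial layout", {
  cfg <- synthetic_config(seed = 21)
  exp <- make_experiment(cfg)
  sm <- thermal_summary(exp$weather, exp$phenology)
  expect_equal(nrow(sm), 8L)
  expect_true(all(sm$filling_days > 0))
  expect_true(all(sm$thermal_sow_to_wintering >= 0))
  # per-treatment values agree with direct recomputation from the phenology
  ph <- exp$phenology
  g <- ph[ph$season == sm$season[1] & ph$sowing_date == sm$sowing_date[1], ]
  sowing <- g$date[g$stage == "sowing"]
  flowering <- g$date[g$stage == "flowering"]
  maturity <- g$date[g$stage == "maturity"]
  expect_equal(sm$days_to_flowering[1], as.numeric(flowering - sowing))
  expect_equal(sm$filling_days[1], as.numeric(maturity - flowering))
  wx <- exp$weather[exp$weather$season == sm$season[1], ]
  expect_equal(sm$accum_temp_whole[1],
               accumulated_temperature(wx, sowing, maturity), tolerance = 1e-9)
})
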