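test_that("synthetic config validates its envelopes", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, growth = list(dma = list(
    w_max = c(3, 4), k = c(0.01, 0.2), tm = c(130, 160)))), "0.05")
  cfg <- synthetic_config(seed = 1)
  expect_s3_class(cfg, "synthetic_config")
  expect_true(!is.unsorted(cfg$sampling$thermal_thresholds, strictly = TRUE))
})

test_that("weather generation is deterministic and noiseless weather is the sinusoid", {
  cfg <- synthetic_config(seed = 4)
  w1 <- gen_weather(cfg, 1, seed = 4)
  w2 <- gen_weather(cfg, 1, seed = 4)
  expect_identical(w1, w2)

  cfg0 <- synthetic_config(seed = 4, weather = list(noise_sd = 0))
  w0 <- gen_weather(cfg0, 1, seed = 4)
  trough <- as.Date("2019-01-15")
  expected <- cfg0$weather$mean - cfg0$weather$amplitude *
    cos(2 * pi * as.numeric(w0$date - trough) / 365.25)
  expect_equal(w0$t_mean, expected, tolerance = 1e-12)
  expect_true(all(w0$t_min <= w0$t_mean & w0$t_mean <= w0$t_max))
  # the wintering onset of the pure sinusoid is its first sub-threshold day
  first_cold <- w0$date[which(w0$t_mean < 10)[1]]
  expect_equal(wintering_onset(w0), first_cold)
})

test_that("cold-period length of default weather stays in the pilot band", {
  for (s in 1:5) {
    cfg <- synthetic_config(seed = s)
    len <- cold_period_length(gen_weather(cfg, 1, seed = s))
    expect_gte(len, 20); expect_lte(len, 85)
  }
})

test_that("growth series generation honours the truth and its noise model", {
  truth <- logistic_params(3.2, 2e5, 0.09)
  days <- c(30, 70, 110, 150, 180, 210)
  s0 <- gen_growth_series(truth, days, noise_sd = 0)
  expect_equal(s0$w, as.numeric(logistic_value(truth, days)), tolerance = 1e-15)
  fit <- fit_logistic(s0)
  expect_lt(abs(fit$params$k - truth$k) / truth$k, 1e-7)

  s1 <- gen_growth_series(truth, days, noise_sd = 0.05, seed = 10)
  s2 <- gen_growth_series(truth, days, noise_sd = 0.05, seed = 10)
  expect_identical(s1, s2)
  expect_true(all(s1$w > 0))

  expect_error(gen_growth_series(truth, c(150), noise_sd = 0), ">= 4")
  expect_error(gen_growth_series(truth, c(30, 30, 70, 110), noise_sd = 0),
               "increasing")
})

test_that("yield generation inverts the ratio line exactly at zero noise", {
  model <- list(slope = 306.03, intercept = 4511.69, sd = 0, n_rep = 3L)
  r_star <- ratio_threshold(model$slope, model$intercept, 6000)
  y <- gen_yields(tibble::tibble(season = "s", sowing_date = "d", ratio = r_star),
                  model, seed = 1)
  expect_equal(nrow(y), 3L)
  expect_equal(y$grain_yield, rep(6000, 3), tolerance = 1e-9)

  # zero-noise yields let the regression recover the generating line exactly
  ratios <- tibble::tibble(season = "s", sowing_date = letters[1:4],
                           ratio = c(2, 3.5, 5, 6.5))
  y4 <- gen_yields(ratios, model, seed = 2)
  rr <- fit_ratio_regression(y4)
  expect_equal(rr$per_season$slope, model$slope, tolerance = 1e-9)
  expect_equal(rr$per_season$intercept, model$intercept, tolerance = 1e-9)
})

test_that("threshold estimation from noisy synthetic yields is nearly unbiased", {
  model <- list(slope = 306.03, intercept = 4511.69, sd = 300, n_rep = 3L)
  true_thr <- ratio_threshold(model$slope, model$intercept, 6000)
  ratios <- tibble::tibble(season = "s", sowing_date = letters[1:4],
                           ratio = c(2.5, 4, 5.5, 7))
  set.seed(123)
  est <- replicate(500, {
    fit_ratio_regression(gen_yields(ratios, model))$threshold_mean
  })
  expect_lt(abs(mean(est) - true_thr), 0.1)
})

test_that("full experiments are deterministic, self-consistent and within envelopes", {
  cfg <- synthetic_config(seed = 42)
  e1 <- make_experiment(cfg)
  e2 <- make_experiment(cfg)
  expect_identical(e1$weather, e2$weather)
  expect_identical(e1$growth, e2$growth)
  expect_identical(e1$yields, e2$yields)

  # truth parameters stay within the configured envelopes
  for (key in names(e1$truth$params)) {
    p <- e1$truth$params[[key]]
    v <- attr(p, "variable")
    env <- cfg$growth[[v]]
    expect_gte(p$w_max, env$w_max[1]); expect_lte(p$w_max, env$w_max[2])
    expect_gte(p$k, env$k[1]); expect_lte(p$k, env$k[2])
    tm <- log(p$a) / p$k
    expect_gte(tm, env$tm[1]); expect_lte(tm, env$tm[2])
  }

  # growth observations are the true curve times log-normal noise: positive,
  # and stage days match the phenology dates
  expect_true(all(e1$growth$value > 0))
  ph <- e1$phenology
  g <- e1$growth
  one <- g[g$season == g$season[1] & g$sowing_date == g$sowing_date[1] &
             g$variable == "dma", ]
  stages <- ph[ph$season == one$season[1] & ph$sowing_date == one$sowing_date[1], ]
  sowing <- stages$date[stages$stage == "sowing"]
  for (i in seq_len(nrow(one))) {
    expect_equal(as.numeric(stages$date[stages$stage == one$stage[i]] - sowing),
                 one$days_after_sowing[i])
  }

  # delayed sowing under the shared winter accumulates less pre-winter warmth
  sm <- thermal_summary(e1$weather, e1$phenology)
  for (s in unique(sm$season)) {
    ss <- sm[sm$season == s, ]
    ord <- order(as.Date(paste0("2000-", c("28-Oct" = "10-28", "5-Nov" = "11-05",
      "13-Nov" = "11-13", "21-Nov" = "11-21")[ss$sowing_date])))
    expect_true(all(diff(ss$thermal_sow_to_wintering[ord]) < 0))
  }
})

test_that("written experiments round-trip through the CSV readers", {
  dir <- tempfile("exp")
  exp <- make_experiment(synthetic_config(seed = 42))
  paths <- write_experiment(exp, dir)
  expect_true(all(file.exists(paths)))

  wx <- read_weather_csv(paths[["weather"]])
  expect_equal(wx$t_mean, exp$weather$t_mean, tolerance = 1e-9)
  g <- read_growth_csv(paths[["growth"]])
  expect_equal(g$value, exp$growth$value, tolerance = 1e-9)
  y <- read_yield_csv(paths[["yield"]])
  expect_equal(y$grain_yield, exp$yields$grain_yield, tolerance = 1e-9)
  p <- read_phenology_csv(paths[["phenology"]])
  expect_equal(nrow(p), nrow(exp$phenology))

  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 42L)
  expect_equal(length(truth$params), length(exp$truth$params))
  unlink(dir, recursive = TRUE)
})
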