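test_that("yield loss is a scale-free percentage shortfall", {
  expect_equal(round(yield_loss(6578.9, 5674.8), 2), 13.74)
  expect_equal(yield_loss(5000, 5000), 0)
  expect_equal(yield_loss(100, 120), -20)
  # scale invariance
  expect_equal(yield_loss(3 * 6578.9, 3 * 5674.8), yield_loss(6578.9, 5674.8),
               tolerance = 1e-12)
  expect_error(yield_loss(0, 10), "positive")
})

test_that("cross-season yield advantages match the trial's reported percentages", {
  y <- trial_yields()
  expect_equal(round(pct_advantage(y, "5-Nov", "28-Oct"), 1), 3.2)
  expect_equal(round(pct_advantage(y, "5-Nov", "13-Nov"), 1), 18.7)
  expect_equal(round(pct_advantage(y, "5-Nov", "21-Nov"), 1), 23.4)
  expect_equal(pct_advantage(y, "5-Nov", "5-Nov"), 0)
  expect_error(pct_advantage(y, "5-Nov", "1-Jan"), "appear")
})

test_that("loss-per-day regression reports the three labelled conventions", {
  y <- trial_yields()
  offs <- c("28-Oct" = 8, "5-Nov" = 0, "13-Nov" = 8, "21-Nov" = 16)

  # first season only, through the origin: sum(xy)/sum(x^2)
  y1 <- y[y$season == "2018-2019", ]
  reg1 <- loss_per_day_regression(y1, "5-Nov", offs)
  expect_equal(round(reg1$slope[reg1$method == "through_origin"], 2), 0.98)
  loss1 <- yield_loss(6578.9, y1$grain_yield)
  x1 <- unname(offs[y1$sowing_date])
  expect_equal(reg1$slope[reg1$method == "through_origin"],
               ols_oracle(x1, loss1, intercept = FALSE)$slope, tolerance = 1e-12)

  # both seasons, pooled OLS ~ 1.18 %/day, against the normal-equation oracle
  reg <- loss_per_day_regression(y, "5-Nov", offs)
  expect_equal(nrow(reg), 3L)
  expect_setequal(reg$method, c("pooled_ols", "per_season_ols", "through_origin"))
  expect_equal(round(reg$slope[reg$method == "pooled_ols"], 2), 1.18)
  loss2 <- yield_loss(7241.7, y$grain_yield[y$season == "2019-2020"])
  pooled <- ols_oracle(c(x1, x1), c(loss1, loss2))
  expect_equal(reg$slope[reg$method == "pooled_ols"], pooled$slope, tolerance = 1e-10)
  expect_equal(reg$intercept[reg$method == "pooled_ols"], pooled$intercept,
               tolerance = 1e-10)
  expect_true(all(is.finite(reg$se)))

  # all losses zero -> zero slope everywhere
  flat <- tibble::tibble(season = "s", sowing_date = names(offs), grain_yield = 6000)
  reg0 <- loss_per_day_regression(flat, "5-Nov", offs)
  expect_equal(reg0$slope, rep(0, 3), tolerance = 1e-12)

  expect_error(loss_per_day_regression(y[1:2, ], "5-Nov", offs), "3 sowing dates")
})

test_that("pearson_r reproduces the trial correlations and their conventions", {
  # second-season filling days vs mean filling temperature
  ct <- pearson_r(c(50, 46, 43, 39), c(17.93, 18.23, 19.84, 20.25))
  expect_equal(round(ct$r, 2), -0.94)
  # two-sided p from t = r*sqrt((n-2)/(1-r^2)) on n-2 df; at n = 4 this
  # correlation sits just above the 5% two-sided cut
  t_stat <- ct$r * sqrt((ct$n - 2) / (1 - ct$r^2))
  expect_equal(ct$p, 2 * pt(-abs(t_stat), ct$n - 2), tolerance = 1e-12)
  expect_lt(ct$p, 0.06)

  # treatment-mean yields vs spike numbers pooled across seasons (n = 8)
  y <- trial_yields()
  ct2 <- pearson_r(y$grain_yield, y$spike_number)
  expect_equal(round(ct2$r, 2), 0.73)
  expect_lt(ct2$p, 0.05)

  # exact linear relation and affine invariance
  x <- c(1, 3, 4, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(2)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(pearson_r(5 * u - 2, v)$r, pearson_r(u, v)$r, tolerance = 1e-12)
  expect_equal(pearson_r(-u, v)$r, -pearson_r(u, v)$r, tolerance = 1e-12)
  expect_lte(abs(pearson_r(u, v)$r), 1)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("ratio thresholds solve the fitted lines for the target yield", {
  eq <- trial_ratio_equations()
  dma <- eq[eq$variable == "dma", ]
  na <- eq[eq$variable == "na", ]
  expect_equal(round(mean(ratio_threshold(dma$slope, dma$intercept)), 2), 4.06)
  expect_equal(round(mean(ratio_threshold(na$slope, na$intercept)), 2), 2.49)
  expect_error(ratio_threshold(0, 5), "zero slope")
})

test_that("ratio regression recovers generating lines and thresholds", {
  # points exactly on a line through (r*, 6000): threshold is r*
  r_star <- 4.5; slope <- 500
  ratios <- c(2, 3.5, 5, 6)
  pts <- tibble::tibble(season = "s1", ratio = ratios,
                        grain_yield = 6000 + slope * (ratios - r_star))
  rr <- fit_ratio_regression(pts)
  expect_equal(rr$threshold_mean, r_star, tolerance = 1e-10)
  expect_equal(rr$per_season$slope, slope, tolerance = 1e-10)

  # agreement with the normal-equation oracle on a noisy instance
  set.seed(31)
  pts2 <- tibble::tibble(season = "s1", ratio = runif(8, 2, 7))
  pts2$grain_yield <- 400 * pts2$ratio + 4000 + rnorm(8, 0, 150)
  rr2 <- fit_ratio_regression(pts2)
  o <- ols_oracle(pts2$ratio, pts2$grain_yield)
  expect_equal(rr2$per_season$slope, o$slope, tolerance = 1e-10)
  expect_equal(rr2$per_season$intercept, o$intercept, tolerance = 1e-10)

  # bias shrinks with the noise
  bias_at <- function(sd) {
    set.seed(77)
    mean(replicate(60, {
      ratios <- runif(6, 2, 7)
      pts <- tibble::tibble(season = "s", ratio = ratios,
                            grain_yield = 400 * ratios + 4000 + rnorm(6, 0, sd))
      fit_ratio_regression(pts)$threshold_mean - (6000 - 4000) / 400
    }))
  }
  expect_lt(abs(bias_at(10)), abs(bias_at(400)) + 1e-9)
  expect_lt(abs(bias_at(10)), 0.01)

  expect_warning(
    fit_ratio_regression(tibble::tibble(season = "s", ratio = c(0.5, 2, 3),
                                        grain_yield = c(4000, 5000, 6000))),
    "<= 1"
  )
})

test_that("productive tiller percentage is a guarded ratio", {
  expect_equal(round(productive_tiller_pct(785.33, 444.00), 2), 56.54)
  expect_equal(productive_tiller_pct(620, 620), 100)
  expect_equal(productive_tiller_pct(600, 0), 0)
  expect_error(productive_tiller_pct(0, 0), "positive")
  expect_error(productive_tiller_pct(100, 150), "0, peak")
})
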