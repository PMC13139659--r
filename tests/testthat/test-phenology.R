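test_that("thermal_time accumulates clipped daily degree days", {
  w <- data.frame(date = as.Date("2020-05-01") + 0:2,
                  tmin_C = c(5, 10, -6), tmax_C = c(15, 20, 2))
  expect_equal(thermal_time(w, "2020-05-01", "2020-05-01"), 10)
  expect_equal(thermal_time(w, "2020-05-01", "2020-05-02"), 25)
  expect_equal(thermal_time(w, "2020-05-03", "2020-05-03"), 0)  # clipped
  expect_equal(thermal_time(w, "2020-05-01", "2020-05-01", t_base = 4), 6)
  expect_error(thermal_time(w, "2020-04-30", "2020-05-01"), "outside")
  expect_error(thermal_time(w, "2020-05-02", "2020-05-01"), "from_date")
})

test_that("thermal_time is additive over adjacent windows", {
  set.seed(21)
  n <- 200
  # temperatures on a quarter-degree grid keep every sum exact in floating
  # point, so additivity can be asserted with equality
  tmin <- round(runif(n, -5, 15) * 4) / 4
  w <- data.frame(date = as.Date("2019-11-01") + seq_len(n) - 1,
                  tmin_C = tmin, tmax_C = tmin + round(runif(n, 0, 40)) / 4)
  for (i in 1:25) {
    cuts <- sort(sample(n, 3))
    a <- w$date[cuts[1]]; b <- w$date[cuts[2]]; cc <- w$date[cuts[3]]
    expect_identical(thermal_time(w, a, b) + thermal_time(w, b + 1, cc),
                     thermal_time(w, a, cc))
  }
})

test_that("stage_tt interpolates weekly scouting to the stage date", {
  w <- flat_weather(30, 10, 20, start = "2020-05-01")  # 15 degCd / day
  stages <- data.frame(bbch = c(59, 67), date = as.Date(c("2020-05-11",
                                                          "2020-05-19")))
  # stage observed exactly
  exact <- stage_tt(rbind(stages, data.frame(bbch = 61,
                                             date = as.Date("2020-05-13"))),
                    w, 61)
  expect_equal(exact, thermal_time(w, "2020-05-01", "2020-05-13"))
  # interpolated: BBCH 61 at 1/4 of an 8-day gap -> day 11 + 2 = May 13,
  # a whole day: TT = 13 * 15
  expect_equal(stage_tt(stages, w, 61), 13 * 15)
  # fractional day: BBCH 62 at 3/8 of the gap -> May 11 + 3 days -> May 14,
  # exactly; BBCH 62.5 -> 3.5 days -> May 14.5: TT = 14*15 + 0.5*15 = 217.5
  expect_equal(stage_tt(stages, w, 62.5), 217.5)
  expect_error(stage_tt(stages, w, 51), "coverage error")
  expect_error(stage_tt(stages, w, 90), "coverage error")
})

test_that("senescence fit recovers noiseless logistic parameters", {
  tt <- seq(1500, 3000, length.out = 14)
  truth <- list(gca_max = 1, tt50 = 2200, k = 0.01)
  gca <- truth$gca_max / (1 + exp(truth$k * (tt - truth$tt50)))
  fit <- fit_senescence(data.frame(tt = tt, gca = gca))
  expect_equal(fit$gca_max, truth$gca_max, tolerance = 1e-6)
  expect_equal(fit$tt50, truth$tt50, tolerance = 1e-6)
  expect_equal(fit$k, truth$k, tolerance = 1e-6)

  expect_error(fit_senescence(data.frame(tt = tt[1:3], gca = gca[1:3])),
               "at least 4 points")
  expect_error(fit_senescence(data.frame(tt = tt, gca = rev(gca))),
               "increases")
})

test_that("TT50 is nearly unbiased under noise and degrades monotonically", {
  tt <- seq(1600, 2800, length.out = 12)
  truth_tt50 <- 2200
  clean <- 1 / (1 + exp(0.01 * (tt - truth_tt50)))
  est <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    fit_senescence(data.frame(tt = tt,
                              gca = clean + rnorm(12, 0, 0.02)))$tt50
  }, numeric(1))
  expect_lt(abs(mean(est) - truth_tt50), 15)

  rmse <- sapply(c(0, 0.01, 0.05), function(s) {
    set.seed(31)
    e <- replicate(50, fit_senescence(
      data.frame(tt = tt, gca = pmax(0, clean + rnorm(12, 0, s))))$tt50)
    sqrt(mean((e - truth_tt50)^2))
  })
  expect_true(all(diff(rmse) >= 0))
})

test_that("green canopy duration is TT50 minus anthesis and scale-free", {
  tt <- seq(1500, 3000, length.out = 14)
  gca <- 1 / (1 + exp(0.01 * (tt - 2200)))
  fit <- fit_senescence(data.frame(tt = tt, gca = gca))
  expect_equal(green_canopy_duration(fit, 1500), 700, tolerance = 1e-6)
  # vertical scaling of the series leaves GCD unchanged
  fit2 <- fit_senescence(data.frame(tt = tt, gca = 2 * gca))
  expect_equal(green_canopy_duration(fit2, 1500),
               green_canopy_duration(fit, 1500), tolerance = 1e-6)
  expect_error(green_canopy_duration(fit, 2300), "ordering error")
})

test_that("default simulated seasons put 50% GCA in the expected window", {
  # anthesis ~1450-1550 degCd and fitted TT50 within 2086-2336 degCd,
  # the realistic maturing window for winter wheat
  cfg <- sim_config(seed = 13)
  w <- simulate_weather("2019-10-15", "2020-07-31", seed = 101)
  for (gi in c(1, 5, 8)) {
    cp <- cfg$canopy[gi, ]
    s <- simulate_canopy(cp$tt50, cp$k, cp$tt_anthesis, w,
                         noise_sd = 0.02, seed = 40 + gi)
    fit <- fit_senescence(s[c("tt", "gca")])
    expect_gt(fit$tt50, 2086 - 60)
    expect_lt(fit$tt50, 2336 + 60)
    gcd <- green_canopy_duration(fit, cp$tt_anthesis)
    expect_gt(gcd, 400)
    expect_lt(gcd, 1000)
  }
})
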