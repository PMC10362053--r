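test_that("DVI hits its endpoints exactly and respects the base temperature", {
  w <- toy_weather(61, tmean = 20)
  ph <- toy_phenology(head_day = 31, mat_day = 61)
  d <- compute_dvi(w, ph)
  expect_equal(d$dvi[1], 0)
  expect_equal(d$dvi[d$date == ph$heading_date], 1, tolerance = 1e-12)
  expect_equal(d$dvi[d$date == ph$maturity_date], 2, tolerance = 1e-12)
  expect_true(all(diff(d$dvi) >= 0))

  # a 10 C day contributes nothing (exceedance above the base)
  tm <- rep(20, 61); tm[5] <- 10
  d2 <- compute_dvi(weather_series("s", w$date, tm, w$srad_mj_m2), ph)
  expect_equal(diff(d2$dvi)[4], 0)
})

test_that("DVI matches the hand-summed cumulative-ratio oracle", {
  # 10-day phase alternating 15/25 C: effective 5/15, phase sum 100
  dates <- seq(as.Date("2000-05-01"), by = 1, length.out = 21)
  tm <- c(20, rep(c(15, 25), 5), rep(20, 10))
  w <- weather_series("s", dates, tm, rep(15, 21))
  ph <- phenology_record(dates[1], dates[11], dates[21])
  d <- compute_dvi(w, ph)
  expect_equal(d$dvi[2:5], c(0.05, 0.20, 0.25, 0.40), tolerance = 1e-12)
})

test_that("undevelopable phases and uncovered seasons are rejected", {
  w <- toy_weather(61, tmean = 8)   # never exceeds the base temperature
  expect_error(compute_dvi(w, toy_phenology()), "undevelopable")
  wshort <- toy_weather(40)
  expect_error(compute_dvi(wshort, toy_phenology()), "cover")
})

test_that("canopy interception follows the logistic-plus-decline curve", {
  p <- cgm_params()
  expect_equal(canopy_interception(0, p), p$f0, tolerance = 1e-9)
  expect_gte(canopy_interception(p$dvi_closure, p), 0.95 * p$f_max)
  # direct re-evaluation of the documented formula on a grid
  k <- (log(p$f_max / p$f0 - 1) - log(1 / 0.95 - 1)) / p$dvi_closure
  x0 <- log(p$f_max / p$f0 - 1) / k
  grid <- seq(0, 2, by = 0.05)
  manual <- pmin(p$f_max, pmax(0,
    p$f_max / (1 + exp(-k * (pmin(grid, 1) - x0))) -
      p$senescence_rate * pmax(0, grid - 1)))
  expect_equal(canopy_interception(grid, p), manual, tolerance = 1e-12)
  # nondecreasing pre-heading, bounded, declining after heading
  pre <- canopy_interception(seq(0, 1, 0.01), p)
  expect_true(all(diff(pre) >= 0))
  expect_true(all(pre >= 0 & pre <= p$f_max))
  expect_lt(canopy_interception(1.5, p), canopy_interception(1, p))
  expect_error(canopy_interception(2.5, p), "0, 2")
})

test_that("temperature response is the documented trapezoid", {
  p <- cgm_params()
  expect_equal(temperature_factor(p$t_low, p), 0)
  expect_equal(temperature_factor((p$t_opt1 + p$t_opt2) / 2, p), 1)
  expect_equal(temperature_factor((p$t_low + p$t_opt1) / 2, p), 0.5)
  # piecewise-linear interpolation oracle over a grid
  grid <- seq(0, 50, by = 0.25)
  oracle <- approx(x = c(-1e6, p$t_low, p$t_opt1, p$t_opt2, p$t_high, 1e6),
                   y = c(0, 0, 1, 1, 0, 0), xout = grid)$y
  expect_equal(temperature_factor(grid, p), oracle, tolerance = 1e-12)
  expect_error(cgm_params(t_opt1 = 5), "knots")
})

test_that("cooling degree-days accumulate the shortfall below 20 C", {
  p <- cgm_params()
  n <- 61
  ph <- toy_phenology(head_day = 31, mat_day = 61)
  base <- rep(25, n)
  w0 <- weather_series("s", toy_weather(n)$date, base, rep(15, n))
  d <- compute_dvi(w0, ph)
  win <- which(d$dvi >= p$dvi_lo & d$dvi <= p$dvi_hi)
  expect_gt(length(win), 3)
  # all window days warm -> 0
  expect_equal(cooling_degree_days(w0, d, p), 0)
  # three window days at 17 C -> 9 C d
  tm <- base; tm[win[1:3]] <- 17
  w1 <- weather_series("s", w0$date, tm, w0$srad_mj_m2)
  expect_equal(cooling_degree_days(w1, compute_dvi(w1, ph), p), 9,
               tolerance = 1e-9)
  # mixed series {22, 18, 15, 21} -> 2 + 5 = 7
  tm2 <- base; tm2[win[1:4]] <- c(22, 18, 15, 21)
  w2 <- weather_series("s", w0$date, tm2, w0$srad_mj_m2)
  expect_equal(cooling_degree_days(w2, compute_dvi(w2, ph), p), 7,
               tolerance = 1e-9)
})

test_that("spikelet fertility is a normalized logistic in CDD", {
  p <- cgm_params()
  expect_equal(spikelet_fertility(0, p), 1)
  # midpoint of the symmetric logistic, up to the fertility(0)=1 rescaling
  raw0 <- 1 / (1 + exp(-p$cdd_steepness * p$cdd50))
  expect_equal(spikelet_fertility(p$cdd50, p), 0.5 / raw0, tolerance = 1e-12)
  grid <- seq(0, 200, by = 1)
  manual <- (1 / (1 + exp(p$cdd_steepness * (grid - p$cdd50)))) / raw0
  expect_equal(spikelet_fertility(grid, p), pmin(1, manual), tolerance = 1e-12)
  expect_true(all(diff(spikelet_fertility(grid, p)) <= 0))
  expect_error(spikelet_fertility(-1, p), "cdd")
})

test_that("potential yield obeys its invariants and scale properties", {
  p <- cgm_params()
  w <- toy_weather(121, tmean = 24, srad = 16)
  ph <- toy_phenology(head_day = 81, mat_day = 121)
  r <- simulate_potential_yield(w, ph, p)
  expect_gte(r$yp, 0)
  expect_true(r$fertility >= 0 && r$fertility <= 1)
  # zero radiation -> zero yield
  w0 <- weather_series("s", w$date, w$tmean_c, rep(0, nrow(w)))
  expect_equal(simulate_potential_yield(w0, ph, p)$yp, 0)
  # linear in harvest index and RUE
  p_half_hi <- cgm_params(harvest_index = p$harvest_index / 2)
  expect_equal(simulate_potential_yield(w, ph, p_half_hi)$yp, r$yp / 2,
               tolerance = 1e-12)
  p_double_rue <- cgm_params(rue_base = p$rue_base * 2)
  expect_equal(simulate_potential_yield(w, ph, p_double_rue)$yp, 2 * r$yp,
               tolerance = 1e-12)
  # monotone in any single day's radiation
  for (day in c(1, 60, 121)) {
    srad2 <- w$srad_mj_m2; srad2[day] <- srad2[day] + 5
    w2 <- weather_series("s", w$date, w$tmean_c, srad2)
    expect_gte(simulate_potential_yield(w2, ph, p)$yp, r$yp)
  }
  # determinism
  expect_identical(simulate_potential_yield(w, ph, p)$yp, r$yp)
})

test_that("a 3-day toy season matches step-by-step daily accounting", {
  # tiny 3-day season: transplanting day then two days to heading/maturity
  dates <- seq(as.Date("2000-07-01"), by = 1, length.out = 3)
  tm <- c(22, 25, 18); sr <- c(10, 20, 15)
  w <- weather_series("s", dates, tm, sr)
  ph <- phenology_record(dates[1], dates[2], dates[3])
  p <- cgm_params(dvi_lo = 0.5, dvi_hi = 1.0)
  # oracle: dvi = (0, 1, 2); spreadsheet-style accounting
  dvi <- c(0, 1, 2)
  interc <- canopy_interception(dvi, p)
  tfac <- temperature_factor(tm, p)
  biomass_t_ha <- sum(sr * interc * p$rue_base * tfac) * 0.01
  cdd <- max(0, 20 - tm[2])           # only day 2 (dvi=1) is in [0.5, 1]
  fert <- spikelet_fertility(cdd, p)
  yp_oracle <- biomass_t_ha * p$harvest_index * fert / 0.86
  r <- simulate_potential_yield(w, ph, p)
  expect_equal(r$cdd, cdd)
  expect_equal(r$yp, yp_oracle, tolerance = 1e-12)
})

test_that("cold snaps depress fertility and potential yield", {
  p <- cgm_params()
  w <- toy_weather(121, tmean = 24, srad = 16)
  ph <- toy_phenology(head_day = 81, mat_day = 121)
  base <- simulate_potential_yield(w, ph, p)
  d <- compute_dvi(w, ph)
  win <- which(d$dvi >= p$dvi_lo & d$dvi <= p$dvi_hi)
  tm <- w$tmean_c; tm[win] <- 13
  wc <- weather_series("s", w$date, tm, w$srad_mj_m2)
  cold <- simulate_potential_yield(wc, ph, p)
  expect_gt(cold$cdd, 0)
  expect_lt(cold$fertility, base$fertility)
  expect_lt(cold$yp, base$yp)
})
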