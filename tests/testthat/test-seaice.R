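mk_grid <- function(dates, lats, lons, sic) {
  g <- expand.grid(date = dates, i = seq_along(lats))
  data.frame(date = g$date, lat = lats[g$i], lon = lons[g$i],
             sic_percent = sic)
}
stn <- list(id = "G1", latitude = -60, longitude = 0)

test_that("station series averages cells inside the 50 km radius only", {
  dates <- seq(as.Date("2013-01-01"), by = "day", length.out = 10)
  g <- mk_grid(dates, c(-60.1, -59.9), c(0.05, -0.05), 80)
  ser <- station_series(g, stn)
  expect_true(all(ser$sic == 80))
  expect_identical(attr(ser, "station"), "G1")

  # one cell at 49 km (100%), one at 51 km (0%): only the first counts
  dlat49 <- 49 / 111.195; dlat51 <- 51 / 111.195
  g <- rbind(mk_grid(dates, -60 + dlat49, 0, 100),
             mk_grid(dates, -60 + dlat51, 0, 0))
  ser <- station_series(g, stn)
  expect_true(all(ser$sic == 100))

  far <- mk_grid(dates, -65, 10, 50)
  expect_error(station_series(far, stn), "G1")
})

test_that("short gaps interpolate linearly, long gaps stay missing", {
  dates <- seq(as.Date("2013-01-01"), by = "day", length.out = 20)
  keep <- setdiff(seq_along(dates), c(5, 6, 7, 12:18))
  g <- mk_grid(dates[keep], -60, 0, 10 * seq_along(keep))
  ser <- station_series(g, stn)
  expect_identical(nrow(ser), 20L)
  expect_false(anyNA(ser$sic[5:7]))     # 3-day gap: filled
  expect_true(all(is.na(ser$sic[12:18])))  # 7-day gap: left missing
  # interpolation is linear between the flanking observations
  expect_equal(ser$sic[5:7],
               approx(c(4, 8), ser$sic[c(4, 8)], xout = 5:7)$y)
})

test_that("synthetic sinusoid recovers its closed form through averaging", {
  cfg <- synth_config(seed = 2, ice_noise_sd = 0, years = 2013)
  grid <- generate_ice(cfg, years = 2013)
  st <- cfg$stations[1, ]
  ser <- station_series(grid, list(id = st$id, latitude = st$latitude,
                                   longitude = st$longitude))
  expect_equal(ser$sic, ice_closed_form(cfg, ser$date), tolerance = 1e-10)
  # with noise, the 50 km mean tracks the closed form within sampling error
  cfgn <- synth_config(seed = 2, ice_noise_sd = 3, years = 2013)
  gridn <- generate_ice(cfgn, years = 2013)
  sern <- station_series(gridn, list(id = st$id, latitude = st$latitude,
                                     longitude = st$longitude))
  resid <- sern$sic - ice_closed_form(cfgn, sern$date)
  interior <- ice_closed_form(cfgn, sern$date) > 10 &
    ice_closed_form(cfgn, sern$date) < 90  # clipping-free region
  expect_lt(max(abs(resid[interior])), 3 * 4 / sqrt(5))
})

test_that("monthly means follow their definition and skip empty months", {
  dates <- seq(as.Date("2013-04-01"), by = "day", length.out = 30)
  mm <- monthly_mean(data.frame(date = dates, sic = 50))
  expect_equal(mm$mean_sic, 50)
  mm <- monthly_mean(data.frame(date = dates, sic = rep(c(0, 100), 15)))
  expect_equal(mm$mean_sic, 50)
  ser <- data.frame(date = dates, sic = c(rep(NA, 30)))
  expect_identical(nrow(monthly_mean(ser)), 0L)
  # series order does not matter for station_series
  g <- mk_grid(dates, c(-60.1, -59.9), c(0, 0), runif(60, 0, 100))
  s1 <- station_series(g, stn)
  s2 <- station_series(g[sample(nrow(g)), ], stn)
  expect_equal(s1, s2)
})

test_that("edge crossings fire on strict threshold passage", {
  dates <- seq(as.Date("2013-02-01"), by = "day", length.out = 4)
  ev <- crossings(data.frame(date = dates, sic = c(20, 16, 14, 10)))
  expect_identical(ev$type, "retreat")
  expect_identical(ev$date, dates[3])
  ev <- crossings(data.frame(date = dates, sic = c(10, 14, 16, 20)))
  expect_identical(ev$type, "advance")
  expect_identical(ev$date, dates[3])
  ev <- crossings(data.frame(date = dates, sic = rep(50, 4)))
  expect_identical(nrow(ev), 0L)
  # monotone series gives at most one event; alternation always holds
  set.seed(8)
  for (i in 1:10) {
    x <- cumsum(runif(40, -10, 10)) + 15
    x <- pmin(100, pmax(0, x))
    ev <- crossings(data.frame(date = seq(as.Date("2013-01-01"), by = "day",
                                          length.out = 40), sic = x))
    if (nrow(ev) > 1)
      expect_true(all(ev$type[-1] != ev$type[-nrow(ev)]))
  }
  mono <- crossings(data.frame(date = dates, sic = c(40, 30, 10, 5)))
  expect_identical(nrow(mono), 1L)
})

test_that("song/ice lags reproduce the worked 54- and 12-day constructions", {
  ev <- structure(data.frame(date = as.Date(c("2013-01-01", "2013-05-01")),
                             type = c("retreat", "advance")),
                  class = c("crossing_events", "data.frame"))
  lag <- song_ice_lags(as.Date("2013-02-24"), as.Date("2013-05-13"), ev)
  expect_equal(lag$retreat_lag, 54)
  expect_equal(lag$advance_lag, 12)
  expect_identical(lag$retreat_flag, "ok")
  # song before any retreat: flagged, lag to the next event is negative
  lag2 <- song_ice_lags(as.Date("2012-12-15"), as.Date("2013-05-13"), ev)
  expect_identical(lag2$retreat_flag, "song_before_event")
  expect_lt(lag2$retreat_lag, 0)
  none <- structure(data.frame(date = as.Date(character(0)),
                               type = character(0)),
                    class = c("crossing_events", "data.frame"))
  lag3 <- song_ice_lags(as.Date("2013-02-24"), as.Date("2013-05-13"), none)
  expect_true(is.na(lag3$retreat_lag))
  expect_identical(lag3$advance_flag, "undefined")
})

test_that("the default synthetic cycle crosses the edge twice a year", {
  cfg <- synth_config(seed = 4, ice_noise_sd = 0, years = 2012:2013)
  closed <- data.frame(
    date = seq(as.Date("2012-01-01"), as.Date("2013-12-31"), by = "day"))
  closed$sic <- ice_closed_form(cfg, closed$date)
  ev <- crossings(closed)
  for (yr in c("2012", "2013")) {
    sub <- ev[format(ev$date, "%Y") == yr, ]
    expect_identical(sum(sub$type == "retreat"), 1L)
    expect_identical(sum(sub$type == "advance"), 1L)
  }
})
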