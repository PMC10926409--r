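# shared fixture: a 10-year synthetic history, its climatology, and an
# observed current year, all seeded
.pcFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    hist <- generateWeather(weatherScenario(
      meanAnnual = 13, seasonalAmplitude = 11, diurnalRange = 8,
      noiseSd = 2, noiseAutocorr = 0.5, years = 2011:2020, seed = 55))
    clim <- buildClimatology(hist)
    obs <- generateWeather(weatherScenario(
      meanAnnual = 13, seasonalAmplitude = 11, diurnalRange = 8,
      noiseSd = 2, noiseAutocorr = 0.5, years = 2021L, seed = 56))
    cache <<- list(hist = hist, clim = clim, obs = obs)
    cache
  }
})

test_that("a 30-day horizon with a 7-day forecast draws 23 climatology days", {
  fx <- .pcFixture()
  anchor <- as.Date("2021-03-13")
  fcst <- syntheticForecast(fx$clim, anchor, ndays = 7, seed = 3)
  asm <- assembleForecast(fx$obs, fcst, fx$clim, anchor)
  src <- sourceLabels(asm)
  expect_equal(sum(src == "forecast"), 7L)
  expect_equal(sum(src == "climatology"), 23L)
  expect_equal(sum(src == "observed"), as.integer(anchor -
                                                    as.Date("2021-01-01")) + 1)
  d <- dates(asm)
  expect_equal(d[length(d)], anchor + 30)
  expect_true(all(diff(as.integer(d)) == 1))
})

test_that("assembly is a pure stitch: per-day values match a flat loop", {
  fx <- .pcFixture()
  anchor <- as.Date("2021-05-10")
  fcst <- syntheticForecast(fx$clim, anchor, ndays = 7, seed = 4)
  asm <- assembleForecast(fx$obs, fcst, fx$clim, anchor)
  d <- dates(asm)
  for (i in seq_along(d)) {
    expected <- if (d[i] <= anchor) tmin(fx$obs)[match(d[i], dates(fx$obs)), 1]
      else if (d[i] <= anchor + 7) tmin(fcst)[match(d[i], dates(fcst)), 1]
      else tmin(fx$clim)[as.POSIXlt(d[i])$yday + 1, 1]
    expect_equal(tmin(asm@cube)[i, 1], expected)
  }
})

test_that("forecast slots filled with climatology equal the pure stitch", {
  fx <- .pcFixture()
  anchor <- as.Date("2021-04-20")
  doy <- as.POSIXlt(anchor + 1:7)$yday + 1
  climAsFcst <- DailyWeatherCube(anchor + 1:7,
                                 tmin = tmin(fx$clim)[doy, , drop = FALSE],
                                 tmax = tmax(fx$clim)[doy, , drop = FALSE],
                                 coords = cellCoords(fx$clim))
  a <- assembleForecast(fx$obs, climAsFcst, fx$clim, anchor)
  b <- assembleForecast(fx$obs, NULL, fx$clim, anchor)
  expect_equal(tmin(a@cube), tmin(b@cube))
  th <- thermalThresholds(3, 38)
  expect_equal(ddAccumulate(a@cube, th), ddAccumulate(b@cube, th))
})

test_that("misaligned forecasts are rejected naming the dates", {
  fx <- .pcFixture()
  anchor <- as.Date("2021-03-13")
  gap <- syntheticForecast(fx$clim, anchor + 1, ndays = 7, seed = 5)
  expect_error(assembleForecast(fx$obs, gap, fx$clim, anchor),
               format(anchor + 1))
})

test_that("cold assemblies keep the same stage and trigger no events", {
  clim <- buildClimatology(lapply(2011:2012, function(y)
    constantCube(1, y, diurnal = 4)))
  obs <- constantCube(1, 2021, diurnal = 4)
  anchor <- as.Date("2021-03-13")
  asm <- assembleForecast(obs, NULL, clim, anchor)
  out <- stageOutlook(asm, spongyMothProfile())
  expect_equal(out$now$stage, "egg")
  expect_equal(out$plus7$stage, "egg")
  expect_equal(out$plus30$stage, "egg")
  expect_false(any(out$events$withinHorizon))
})

test_that("a constant-20 C assembly reaches adult emergence in-window", {
  clim <- buildClimatology(lapply(2011:2012, function(y)
    constantCube(20, y)))
  obs <- constantCube(20, 2021)
  anchor <- as.Date("2021-01-01") + 79          # day 80
  asm <- assembleForecast(obs, NULL, clim, anchor)
  out <- stageOutlook(asm, spongyMothProfile())
  expect_equal(out$now$stage, "pupae")
  # oracle timeline: cumulative reaches 1143 on day 83
  emer <- out$events[out$events$event == "adult_emergence", ]
  expect_equal(emer$date, as.Date("2021-01-01") - 1 + 83)
  expect_true(emer$withinHorizon)
  expect_equal(out$plus30$stage, "complete")
})

test_that("a cold spring forecasts larvae with emergence out of window", {
  # spring running ~6 C cool: larval stage at the anchor, no emergence
  clim <- buildClimatology(lapply(2011:2012, function(y)
    constantCube(12, y)))
  obs <- constantCube(12, 2021)
  anchor <- as.Date("2021-04-15")
  out <- stageOutlook(assembleForecast(obs, NULL, clim, anchor),
                      spongyMothProfile())
  expect_equal(out$now$stage, "larvae")
  emer <- out$events[out$events$event == "adult_emergence", ]
  expect_false(emer$withinHorizon)
})

test_that("year comparison flags pace against the 10-year mean", {
  # identical prior years: current equal to them is "on pace"
  flatYear <- cumsum(rep(5, 200))
  prior <- setNames(lapply(1:12, function(i) flatYear),
                    as.character(2009:2020))
  expect_equal(compareYears(prior, flatYear, anchorDoy = 150)$flag, "on_pace")
  # only the 10 most recent years enter the mean
  prior2 <- prior
  prior2[["2009"]] <- cumsum(rep(50, 200))
  prior2[["2010"]] <- cumsum(rep(50, 200))
  cmp <- compareYears(prior2, flatYear, anchorDoy = 150)
  expect_equal(cmp$flag, "on_pace")
  expect_equal(cmp$yearsUsed, as.character(2011:2020))
  # uniformly warmer current year runs earlier
  th <- thermalThresholds(3, 38)
  base <- 12 - 11 * cos(2 * pi * (1:200 - 15) / 365)
  cur <- cumsum(ddDay(base + 2 - 4, base + 2 + 4, th))
  ref <- cumsum(ddDay(base - 4, base + 4, th))
  prior3 <- setNames(lapply(1:10, function(i) ref), as.character(2011:2020))
  expect_equal(compareYears(prior3, cur, anchorDoy = 180)$flag, "earlier")
  expect_equal(compareYears(prior3, ref - 1, anchorDoy = 180)$flag, "later")
  # mean curve equals a flat pointwise average over seeded synthetic years
  set.seed(61)
  dec <- lapply(1:10, function(i) cumsum(runif(200, 0, 10)))
  names(dec) <- as.character(2011:2020)
  cmp2 <- compareYears(dec, dec[[1]], anchorDoy = 120)
  flatMean <- sapply(1:200, function(j)
    mean(sapply(dec, function(v) v[j])))
  expect_equal(cmp2$meanCurve, flatMean)
  expect_warning(compareYears(dec[1:3], dec[[1]]), "fewer than 10")
})
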