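test_that("condition day counts respect the consecutive-run rule", {
  d <- seq(as.Date("2020-07-01"), by = "day", length.out = 10)
  tmx <- c(25, 31, 25, 32, 25, 33, 25, 25, 25, 25)  # 3 isolated hot days
  cube <- DailyWeatherCube(d, tmx - 10, tmx)
  one <- conditionDays(cube, conditionSpec("tmax", "gt", 30))
  expect_equal(rasterValues(one$count), 3)
  expect_equal(rasterValues(one$binary), 1L)
  two <- conditionDays(cube, conditionSpec("tmax", "gt", 30,
                                           minConsecutive = 2))
  expect_equal(rasterValues(two$count), 0)
  expect_equal(rasterValues(two$binary), 0L)
})

test_that("condition day counts match a flat run-length scan", {
  set.seed(19)
  d <- seq(as.Date("2020-01-01"), as.Date("2020-12-30"), by = "day")
  tmn <- runif(365, -5, 20)
  cube <- DailyWeatherCube(d, tmn, tmn + 10)
  for (k in c(1L, 2L, 4L)) {
    spec <- conditionSpec("tmean", "ge", 15, minConsecutive = k)
    got <- rasterValues(conditionDays(cube, spec)$count)
    sat <- (tmn + tmn + 10) / 2 >= 15
    # flat scan: count days inside runs of >= k satisfying days
    cnt <- 0; run <- 0
    for (i in seq_along(sat)) {
      if (sat[i]) run <- run + 1
      if (!sat[i] || i == length(sat)) {
        if (run >= k) cnt <- cnt + run
        run <- 0
      }
    }
    expect_equal(got, cnt)
    # k = 1 dominates any larger k
    if (k > 1)
      expect_gte(rasterValues(conditionDays(
        cube, conditionSpec("tmean", "ge", 15))$count), got)
  }
  expect_error(conditionDays(cube, conditionSpec("precip", "ge", 1)),
               "precip")
})

test_that("years-suitable counts cold-snap years by construction", {
  snaps <- data.frame(year = c(2003L, 2007L, 2012L), doy = c(40L, 35L, 50L),
                      tmin = c(-25, -23, -30))
  sc <- weatherScenario(meanAnnual = 14, seasonalAmplitude = 9, noiseSd = 1,
                        coldSnaps = snaps, years = 2001:2020, seed = 6)
  cube <- generateWeather(sc)
  res <- lethalSuitability(cube, -21.5)
  expect_equal(rasterValues(res$years), 17)
  expect_equal(res$yearsUsed, c(r1c1 = 20))
  # flat per-year minimum scan oracle
  yrs <- splitYears(cube)
  flat <- sum(vapply(yrs, function(cb) min(tmin(cb)[, 1]) > -21.5,
                     logical(1)))
  expect_equal(rasterValues(res$years), flat)
  # vacuous threshold: every year suitable
  expect_equal(rasterValues(lethalSuitability(cube, -Inf)$years), 20)
  # lowering the threshold never decreases the count
  base <- rasterValues(res$years)
  for (thr in c(-20, -22, -24, -26, -31)) {
    v <- rasterValues(lethalSuitability(cube, thr)$years)
    if (thr < -21.5) expect_gte(v, base) else expect_lte(v, base)
  }
})

test_that("a day exactly at the lethal threshold is lethal", {
  d <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  tmn <- rep(0, length(d)); tmn[30] <- -21.5
  cube <- DailyWeatherCube(d, tmn, tmn + 10)
  expect_equal(rasterValues(lethalSuitability(cube, -21.5)$years), 0)
  tmn[30] <- -21.499
  cube <- DailyWeatherCube(d, tmn, tmn + 10)
  expect_equal(rasterValues(lethalSuitability(cube, -21.5)$years), 1)
})

test_that("cell-years failing coverage drop out of the denominator", {
  d <- seq(as.Date("2020-01-01"), as.Date("2021-12-31"), by = "day")
  tmn <- matrix(0, length(d), 2)
  tmn[1:30, 2] <- NA                      # 2020 unusable at cell 2
  cube <- DailyWeatherCube(d, tmn, tmn + 10)
  res <- suppressWarnings(lethalSuitability(cube, -21.5))
  expect_equal(unname(res$yearsUsed), c(2, 1))
  expect_equal(unname(rasterValues(res$years)), c(2, 1))
})

test_that("precipitation accumulates and thresholds correctly", {
  d <- seq(as.Date("2020-06-01"), by = "day", length.out = 30)
  cube <- DailyWeatherCube(d, rep(10, 30), rep(20, 30),
                           precip = rep(2, 30))
  res <- precipAccumulation(cube, threshold = 50, comparator = "ge")
  expect_equal(rasterValues(res$accumulated), 60)
  expect_equal(rasterValues(res$binary), 1L)
  expect_equal(rasterValues(precipAccumulation(cube, threshold = 61)$binary),
               0L)
  set.seed(2)
  pr <- rexp(30, 1 / 3)
  cube2 <- DailyWeatherCube(d, rep(10, 30), rep(20, 30), precip = pr)
  expect_equal(rasterValues(precipAccumulation(cube2)$accumulated), sum(pr))
  noPr <- DailyWeatherCube(d, rep(10, 30), rep(20, 30))
  expect_error(precipAccumulation(noPr), "no precipitation")
})

test_that("hardiness banding hits the worked examples", {
  expect_equal(hardinessZone(-10, units = "F"), "6a")
  expect_equal(hardinessZone(0, units = "F"), "7a")
  expect_equal(hardinessZone(-24.7, units = "C"), "5b")  # -12.46 F
  expect_equal(hardinessZone(-100, units = "F"), "1a")
  expect_equal(hardinessZone(85, units = "F"), "13b")
})

test_that("hardiness banding is total, monotone and half-open", {
  f <- seq(-70, 75, by = 0.1)
  z <- hardinessZone(f, units = "F")
  expect_false(anyNA(z))
  lvl <- paste0(rep(1:13, each = 2), c("a", "b"))
  idx <- match(z, lvl)
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
  # 5 F steps move exactly one half-zone inside the banded range
  g <- seq(-60, 65, by = 5)
  expect_equal(diff(match(hardinessZone(g, units = "F"), lvl)),
               rep(1L, length(g) - 1))
  # right-open: the boundary belongs to the upper band
  expect_equal(hardinessZone(-5, units = "F"), "6b")
  expect_equal(hardinessZone(-5 - 1e-9, units = "F"), "6a")
})

test_that("hardiness raster averages annual extremes per cell", {
  extremes <- rbind(c(-12, 3), c(-8, 5))     # two years, two cells (F)
  co <- data.frame(cell = c("a", "b"), lat = 1:2, lon = 1:2)
  r <- hardinessRaster(extremes, co, units = "F")
  expect_equal(rasterValues(r), c("6a", "7a"))  # means -10 and 4 F
  expect_equal(nYears(r), 2L)
})

test_that("mask combination is elementwise with missing propagation", {
  co <- data.frame(cell = c("a", "b"), lat = 1:2, lon = 1:2)
  r1 <- SuitabilityRaster(c(1L, 0L), co, "m1")
  r2 <- SuitabilityRaster(c(1L, 1L), co, "m2")
  expect_equal(rasterValues(combineMasks(list(r1, r2), "and")), c(1L, 0L))
  expect_equal(rasterValues(combineMasks(list(r1), "and")),
               rasterValues(r1))
  set.seed(33)
  rs <- lapply(1:3, function(i)
    SuitabilityRaster(sample(0:1, 2, TRUE), co, "m"))
  vals <- sapply(rs, rasterValues)
  expect_equal(rasterValues(combineMasks(rs, "or")),
               as.integer(apply(vals, 1, max)))
  andv <- rasterValues(combineMasks(rs, "and"))
  orv <- rasterValues(combineMasks(rs, "or"))
  for (r in rs) {
    expect_true(all(andv <= rasterValues(r)))
    expect_true(all(orv >= rasterValues(r)))
  }
  r3 <- SuitabilityRaster(c(NA_integer_, 1L), co, "m3")
  expect_equal(rasterValues(combineMasks(list(r2, r3), "and")), c(NA, 1L))
  bad <- SuitabilityRaster(1L, co[1, ], "m")
  expect_error(combineMasks(list(r1, bad)), "co-registered")
})
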