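test_that("constant 20 C gives the worked spongy moth timeline", {
  tl <- runStaged(constantCube(20), spongyMothProfile())
  tr <- tl@transitions
  d0 <- as.Date("2021-01-01") - 1
  expect_equal(tr$completed[tr$stage == "egg"], d0 + 17)     # 17 * 17 = 289
  expect_equal(tr$completed[tr$stage == "larvae"], d0 + 63)  # + 46 d @ 12.8
  expect_equal(tr$completed[tr$stage == "pupae"], d0 + 84)   # + 21 d @ 13.4
  expect_equal(tl@days$ddCumulative[17], 289)
  # emergence marker: cumulative reaches 1143 on pupal day 20 (day 83)
  expect_equal(unname(tl@eventDates["adult_emergence"]), d0 + 83)
  expect_equal(tl@days$stage[30], "larvae")
  expect_equal(tl@days$stage[100], "complete")
})

test_that("temperatures below every threshold leave the timeline in stage 1", {
  tl <- runStaged(constantCube(1), spongyMothProfile())
  expect_true(all(tl@days$stage == "egg"))
  expect_equal(max(tl@days$ddCumulative), 0)
  expect_true(all(is.na(tl@transitions$completed)))
  expect_true(all(is.na(tl@eventDates)))
})

test_that("a single-stage profile reduces to plain accumulation", {
  th <- thermalThresholds(6, 35)
  profile <- pestProfile("one", stages = list(lifeStage("all", th, 1e6)))
  set.seed(14)
  d <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  tmn <- runif(365, -5, 25)
  cube <- DailyWeatherCube(d, tmn, tmn + 10)
  tl <- runStaged(cube, profile)
  expect_equal(tl@days$ddCumulative, unname(ddAccumulate(cube, th)[, 1]))
})

test_that("the staged run matches an independent scalar day loop", {
  profile <- spongyMothProfile()
  lowers <- c(3, 7.2, 6.6); uppers <- c(38, 41, 41); reqs <- c(282, 583, 277)
  set.seed(42)
  for (rep in 1:25) {
    d <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
    base <- 12 - 11 * cos(2 * pi * (seq_len(365) - 15) / 365)
    tmn <- base + rnorm(365, sd = 4) - 4
    tmx <- tmn + 8
    cube <- DailyWeatherCube(d, tmn, tmx)
    tl <- runStaged(cube, profile)
    oracle <- stagedOracle(tmn, tmx, lowers, uppers, reqs, sineHorizDD)
    expect_equal(tl@days$ddCumulative, oracle$cum)
    stageNames <- c("egg", "larvae", "pupae", "complete")
    expect_equal(tl@days$stage, stageNames[pmin(oracle$stageIdx, 4)])
    expectDone <- as.Date("2020-12-31") + ifelse(is.na(oracle$doneDay),
                                                 NA, oracle$doneDay)
    expect_equal(tl@transitions$completed, expectDone, ignore_attr = TRUE)
  }
})

test_that("stage degree-days are conserved into the cumulative track", {
  tl <- runStaged(constantCube(20), spongyMothProfile())
  days <- tl@days
  done <- tl@transitions$completed
  atCompletion <- days$ddInStage[match(done, days$date)]
  final <- days$ddCumulative[nrow(days)]
  # completed stages + post-completion accumulation = cumulative total
  post <- days$ddInStage[nrow(days)]
  expect_equal(sum(atCompletion) + post, final)
})

test_that("warmer series never delay events or transitions", {
  profile <- spongyMothProfile()
  set.seed(8)
  for (rep in 1:10) {
    d <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
    base <- 12 - 11 * cos(2 * pi * (seq_len(365) - 15) / 365) +
      rnorm(365, sd = 3)
    warm <- base + runif(365, 0, 3)
    a <- runStaged(DailyWeatherCube(d, base - 4, base + 4), profile)
    b <- runStaged(DailyWeatherCube(d, warm - 4, warm + 4), profile)
    for (k in seq_along(a@eventDates)) {
      if (!is.na(a@eventDates[k]))
        expect_lte(as.integer(b@eventDates[k]), as.integer(a@eventDates[k]))
    }
  }
})

test_that("stageOnDate reports boundaries and event status", {
  profile <- pestProfile("sm-feb", stages = spongyMothProfile()@stages,
                         startDate = "02-01",
                         events = spongyMothProfile()@events)
  tl <- runStaged(constantCube(20), profile)
  expect_equal(stageOnDate(tl, "2021-01-15")$stage, "pre-season")
  expect_error(stageOnDate(tl, "2022-06-01"), "outside")
  tl2 <- runStaged(constantCube(20), spongyMothProfile())
  q <- stageOnDate(tl2, as.Date("2021-01-30"))
  expect_equal(q$stage, "larvae")
  expect_equal(unname(q$events["adult_emergence"]), "not_reached")
  expect_equal(q$activity, "pre")
  # marker reached exactly on the >= boundary day
  evDay <- tl2@eventDates["adult_emergence"]
  q2 <- stageOnDate(tl2, evDay)
  expect_match(unname(q2$events["adult_emergence"]), "reached_on")
  expect_equal(q2$activity, "active")
  q3 <- stageOnDate(tl2, tl2@eventDates["flight_end"])
  expect_equal(q3$activity, "post")
})

test_that("voltinism arithmetic follows the floor rule", {
  cube <- constantCube(25, year = 2021)
  res <- generationsPerYear(cube, oabProfile())
  # 13.9 DD/day * 365 = 5073.5; floor(5073.5 / 1486) = 3
  expect_equal(unname(res$perYear["2021", 1]), 3)
  expect_equal(unname(res$fractional["2021", 1]), 5073.5 / 1486)
  expect_equal(rasterValues(res$mean), 3)
  # below the lower threshold: zero generations
  cold <- generationsPerYear(constantCube(8, year = 2021), oabProfile())
  expect_equal(unname(cold$perYear["2021", 1]), 0)
  # floor(x) <= fractional < floor(x) + 1
  expect_true(all(res$perYear <= res$fractional &
                    res$fractional < res$perYear + 1))
})

test_that("identical years average to each year's generation count", {
  d <- seq(as.Date("2018-01-01"), as.Date("2020-12-31"), by = "day")
  cube <- DailyWeatherCube(d, rep(25, length(d)), rep(25, length(d)))
  res <- generationsPerYear(cube, oabProfile())
  expect_equal(rasterValues(res$mean), mean(res$perYear[, 1]))
  expect_true(all(res$perYear[, 1] == res$perYear[1, 1]))
})

test_that("incomplete years are excluded with a warning", {
  d <- seq(as.Date("2020-01-01"), as.Date("2021-06-30"), by = "day")
  cube <- DailyWeatherCube(d, rep(25, length(d)), rep(25, length(d)))
  expect_warning(res <- generationsPerYear(cube, oabProfile()), "2021")
  expect_equal(rownames(res$perYear), "2020")
})
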