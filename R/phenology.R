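# Multi-stage phenology: stage-switched degree-day accumulation.
#
# Transition rule (daily resolution, no within-day carry-over): the full
# degree-days of the day on which a stage's requirement is met credit that
# stage; the next stage starts the following day. After the final stage
# completes, the cumulative track keeps accruing under the final stage's
# thresholds so that event markers beyond the stage-requirement sum (e.g.
# an adult-emergence marker) remain reachable.

.runStagedCell <- function(d, tn, tx, profile, startDate) {
  nStages <- length(profile@stages)
  stageNames <- vapply(profile@stages, function(s) s@name, character(1))
  reqs <- vapply(profile@stages, function(s) s@ddRequirement, numeric(1))
  n <- length(d)
  stage <- character(n); ddAdded <- ddIn <- ddCum <- numeric(n)
  completed <- rep(as.Date(NA), nStages)
  si <- 1L; inStage <- 0; cum <- 0; dead <- FALSE
  for (i in seq_len(n)) {
    if (d[i] < startDate) {
      stage[i] <- "pre-season"; ddAdded[i] <- 0
      ddIn[i] <- 0; ddCum[i] <- 0
      next
    }
    th <- profile@stages[[min(si, nStages)]]@thresholds
    dd <- if (is.na(tn[i]) || is.na(tx[i])) NA_real_ else ddDay(tn[i], tx[i], th)
    if (dead || is.na(dd)) {
      dead <- TRUE
      stage[i] <- if (si > nStages) "complete" else stageNames[si]
      ddAdded[i] <- NA_real_; ddIn[i] <- NA_real_; ddCum[i] <- NA_real_
      next
    }
    inStage <- inStage + dd; cum <- cum + dd
    stage[i] <- if (si > nStages) "complete" else stageNames[si]
    ddAdded[i] <- dd; ddIn[i] <- inStage; ddCum[i] <- cum
    if (si <= nStages && inStage >= reqs[si]) {
      completed[si] <- d[i]
      si <- si + 1L
      inStage <- 0
    }
  }
  ev <- rep(as.Date(NA), length(profile@events))
  names(ev) <- names(profile@events)
  for (k in seq_along(profile@events)) {
    hit <- which(!is.na(ddCum) & ddCum >= profile@events[k])
    if (length(hit)) ev[k] <- d[hit[1]]
  }
  new("StageTimeline", cell = "cell",
      days = data.frame(date = d, stage = stage, ddAdded = ddAdded,
                        ddInStage = ddIn, ddCumulative = ddCum,
                        stringsAsFactors = FALSE),
      transitions = data.frame(stage = stageNames, completed = completed,
                               stringsAsFactors = FALSE),
      eventDates = ev, profileName = profile@name)
}

#' Run the staged phenology model
#'
#' Tracks a pest through its ordered life stages over one season. From
#' the profile's start date the model accrues \code{\link{ddDay}}
#' degree-days under the active stage's thresholds; when the accrued
#' degree-days within a stage reach its requirement at the end of a day,
#' the next stage begins the following day (the completing day's full
#' degree-days credit the completing stage). The cumulative track sums
#' all accrued degree-days; each event marker's date is the first day the
#' cumulative track reaches it.
#'
#' @param cube a \linkS4class{DailyWeatherCube} covering the season.
#' @param profile a \linkS4class{PestProfile} with stages.
#' @param year calendar year to run (default: year of the cube's first day).
#' @param end last day to run (default: the earlier of Dec 31 of `year`
#'   and the cube's last day). May extend past Dec 31 for forecast runs.
#' @param drop if TRUE (default) return a bare \linkS4class{StageTimeline}
#'   for single-cell cubes instead of a one-element list.
#' @return A \linkS4class{StageTimeline} per cell (named list), or a
#'   single timeline when `drop = TRUE` and the cube has one cell.
#' @examples
#' d <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
#' cube <- DailyWeatherCube(d, rep(20, length(d)), rep(20, length(d)))
#' tl <- runStaged(cube, spongyMothProfile())
#' tl@transitions
#' @export
runStaged <- function(cube, profile, year = NULL, end = NULL, drop = TRUE) {
  stopifnot(is(cube, "DailyWeatherCube"), is(profile, "PestProfile"))
  if (!length(profile@stages)) stop("profile has no stages")
  d <- dates(cube)
  if (is.null(year)) year <- as.integer(format(d[1], "%Y"))
  startDate <- as.Date(paste0(year, "-", profile@startDate))
  if (is.null(end)) end <- min(d[length(d)], as.Date(paste0(year, "-12-31")))
  end <- as.Date(end)
  if (startDate < d[1] || end > d[length(d)])
    stop("cube does not cover ", format(startDate), "..", format(end))
  idx <- which(d <= end)
  out <- lapply(seq_len(nCells(cube)), function(j) {
    tl <- .runStagedCell(d[idx], tmin(cube)[idx, j], tmax(cube)[idx, j],
                         profile, startDate)
    tl@cell <- cellCoords(cube)$cell[j]
    tl
  })
  names(out) <- cellCoords(cube)$cell
  if (drop && length(out) == 1) out[[1]] else out
}

#' Query a timeline on a date
#'
#' Reports the active stage on a date together with the status of each
#' cumulative event marker (`not_reached` or `reached_on <date>`). When
#' the profile defines a flight window (two or more markers), `activity`
#' summarises the cumulative position: `"pre"` before the first marker,
#' `"active"` between the first and last, `"post"` past the last.
#'
#' @param timeline a \linkS4class{StageTimeline}.
#' @param date a date within the timeline.
#' @return list with elements `stage`, `ddCumulative`, `events` (named
#'   character) and `activity`.
#' @export
stageOnDate <- function(timeline, date) {
  stopifnot(is(timeline, "StageTimeline"))
  date <- as.Date(date)
  i <- match(date, timeline@days$date)
  if (is.na(i)) stop("date ", format(date), " outside the timeline")
  ev <- vapply(seq_along(timeline@eventDates), function(k) {
    evd <- timeline@eventDates[k]
    if (!is.na(evd) && evd <= date)
      paste("reached_on", format(evd)) else "not_reached"
  }, character(1))
  names(ev) <- names(timeline@eventDates)
  cum <- timeline@days$ddCumulative[i]
  activity <- NA_character_
  if (length(ev) >= 2 && !is.na(cum)) {
    first <- timeline@eventDates[1]
    last <- timeline@eventDates[length(timeline@eventDates)]
    activity <- if (is.na(first) || date < first) "pre"
      else if (is.na(last) || date < last) "active" else "post"
  }
  list(stage = timeline@days$stage[i], ddCumulative = cum,
       events = ev, activity = activity)
}

#' Generations per year (voltinism)
#'
#' For each full calendar year, accumulates degree-days Jan 1 to Dec 31
#' under the profile's generation thresholds; completed generations are
#' `floor(annual DD / dd per generation)`. The mean over usable years is
#' returned per cell, along with the per-year completed counts and the
#' fractional (un-floored) generations. Cell-years failing the coverage
#' rule (\code{\link{coverageOK}}) are excluded from that cell's mean.
#'
#' @param cube a multi-year \linkS4class{DailyWeatherCube}.
#' @param profile a \linkS4class{PestProfile} with generation parameters.
#' @param years years to use (default: all full years in the cube).
#' @return list: `mean` (\linkS4class{SuitabilityRaster}, float),
#'   `perYear` (years x cells integer matrix), `fractional` (same shape,
#'   float), `yearsUsed` (per-cell usable-year count).
#' @examples
#' d <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
#' cube <- DailyWeatherCube(d, rep(25, length(d)), rep(25, length(d)))
#' generationsPerYear(cube, oabProfile())$perYear  # 3 completed generations
#' @export
generationsPerYear <- function(cube, profile, years = NULL) {
  stopifnot(is(cube, "DailyWeatherCube"), is(profile, "PestProfile"))
  if (is.null(profile@genThresholds) || is.na(profile@ddPerGeneration))
    stop("profile has no generation parameters")
  byYear <- splitYears(cube)
  full <- vapply(byYear, function(cb) {
    d <- dates(cb)
    format(d[1], "%m-%d") == "01-01" && format(d[length(d)], "%m-%d") == "12-31"
  }, logical(1))
  if (any(!full)) {
    warning("excluding incomplete year(s): ",
            paste(names(byYear)[!full], collapse = ", "))
    byYear <- byYear[full]
  }
  if (!is.null(years)) byYear <- byYear[names(byYear) %in% as.character(years)]
  if (!length(byYear)) stop("no full calendar years to analyse")
  nc <- nCells(cube)
  frac <- gen <- matrix(NA_real_, length(byYear), nc,
                        dimnames = list(names(byYear), cellCoords(cube)$cell))
  usable <- matrix(FALSE, length(byYear), nc)
  for (k in seq_along(byYear)) {
    cb <- byYear[[k]]
    acc <- ddAccumulate(cb, profile@genThresholds)
    annual <- acc[nrow(acc), ]
    usable[k, ] <- coverageOK(cb) & !is.na(annual)
    frac[k, ] <- annual / profile@ddPerGeneration
    gen[k, ] <- floor(frac[k, ])
  }
  gen[!usable] <- NA_real_; frac[!usable] <- NA_real_
  meanGen <- colMeans(gen, na.rm = TRUE)
  meanGen[colSums(usable) == 0] <- NA_real_
  list(mean = SuitabilityRaster(unname(meanGen), cellCoords(cube),
                                "mean_generations_per_year",
                                period = range(names(byYear)),
                                nYears = length(byYear)),
       perYear = gen, fractional = frac,
       yearsUsed = stats::setNames(colSums(usable), cellCoords(cube)$cell))
}
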