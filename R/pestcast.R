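# 30-day forecast assembly and stage outlooks.
#
# The assembled series runs from January 1 of the anchor year to 30 days
# past the anchor: observed weather through the anchor, a short-term
# (normally 7-day) forecast, and daily climatology for the rest of the
# horizon (23 days when the forecast covers 7). Climatology days are
# drawn by day of year; a Feb 29 in the horizon takes the day-59 values.

#' Assemble a 30-day forecast series
#'
#' Stitches observed weather (Jan 1 through the anchor date), a
#' short-term forecast (anchor+1 onward, at most covering the horizon)
#' and a daily climatology (remaining days) into one gap-free daily
#' series ending exactly 30 days after the anchor, with per-day source
#' labels.
#'
#' @param observed \linkS4class{DailyWeatherCube} covering Jan 1..anchor.
#' @param forecast \linkS4class{DailyWeatherCube} starting at anchor+1
#'   (normally 7 days), or NULL to draw the whole horizon from
#'   climatology.
#' @param clim a \linkS4class{DailyClimatology} on the same cells.
#' @param anchor the forecast issue date.
#' @return A \linkS4class{ForecastAssembly}.
#' @export
assembleForecast <- function(observed, forecast, clim, anchor) {
  stopifnot(is(observed, "DailyWeatherCube"), is(clim, "DailyClimatology"))
  anchor <- as.Date(anchor)
  year <- format(anchor, "%Y")
  jan1 <- as.Date(paste0(year, "-01-01"))
  d <- dates(observed)
  if (d[1] > jan1 || d[length(d)] < anchor)
    stop("observed must cover ", format(jan1), "..", format(anchor))
  obsIdx <- which(d >= jan1 & d <= anchor)
  horizon <- anchor + 1:30
  nc <- nCells(observed)
  tmn <- tmin(observed)[obsIdx, , drop = FALSE]
  tmx <- tmax(observed)[obsIdx, , drop = FALSE]
  src <- rep("observed", length(obsIdx))
  fdates <- as.Date(character())
  if (!is.null(forecast)) {
    stopifnot(is(forecast, "DailyWeatherCube"))
    fdates <- dates(forecast)
    if (fdates[1] != anchor + 1)
      stop("forecast must start the day after the anchor (",
           format(anchor + 1), "), got ", format(fdates[1]))
    fdates <- fdates[fdates <= anchor + 30]
    fidx <- seq_along(fdates)
    tmn <- rbind(tmn, tmin(forecast)[fidx, , drop = FALSE])
    tmx <- rbind(tmx, tmax(forecast)[fidx, , drop = FALSE])
    src <- c(src, rep("forecast", length(fdates)))
  }
  climDates <- horizon[!horizon %in% fdates]
  if (length(climDates)) {
    doy <- .doy365(climDates)
    tmn <- rbind(tmn, tmin(clim)[doy, , drop = FALSE])
    tmx <- rbind(tmx, tmax(clim)[doy, , drop = FALSE])
    src <- c(src, rep("climatology", length(climDates)))
  }
  allDates <- c(d[obsIdx], fdates, climDates)
  if (any(diff(as.integer(allDates)) != 1L))
    stop("assembly has gaps or overlaps at: ",
         paste(format(allDates[which(diff(as.integer(allDates)) != 1L) + 1]),
               collapse = ", "))
  cube <- DailyWeatherCube(allDates, tmin = tmn, tmax = tmx,
                           coords = cellCoords(observed))
  new("ForecastAssembly", cube = cube, anchor = anchor, source = src)
}

#' Stage outlook from an assembled forecast
#'
#' Runs the staged phenology model over an assembled series and reports
#' the predicted stage at the anchor ("now"), 7 days out and 30 days out,
#' together with each event marker's date and whether it falls inside the
#' 30-day window.
#'
#' @param assembly a \linkS4class{ForecastAssembly}.
#' @param profile a staged \linkS4class{PestProfile}.
#' @param cell cell index to report (default 1).
#' @return list: `anchor`, `now`, `plus7`, `plus30` (each a
#'   \code{\link{stageOnDate}} result), `events` (data.frame: event, date,
#'   withinHorizon), and the underlying `timeline`.
#' @export
stageOutlook <- function(assembly, profile, cell = 1L) {
  stopifnot(is(assembly, "ForecastAssembly"), is(profile, "PestProfile"))
  anchor <- assembly@anchor
  tl <- runStaged(assembly@cube, profile,
                  year = as.integer(format(anchor, "%Y")),
                  end = anchor + 30, drop = FALSE)[[cell]]
  ev <- data.frame(event = names(tl@eventDates),
                   date = unname(tl@eventDates),
                   withinHorizon = !is.na(tl@eventDates) &
                     tl@eventDates > anchor & tl@eventDates <= anchor + 30,
                   stringsAsFactors = FALSE)
  list(anchor = anchor,
       now = stageOnDate(tl, anchor),
       plus7 = stageOnDate(tl, anchor + 7),
       plus30 = stageOnDate(tl, anchor + 30),
       events = ev, timeline = tl)
}

#' Compare the current year's accumulation with prior years
#'
#' Aligns cumulative degree-day curves by day of year, averages the (up
#' to) 10 most recent prior years pointwise, and flags whether the
#' current year is running "earlier" (cumulative degree-days at the
#' anchor day exceed the prior-year mean at the same day of year),
#' "later", or "on_pace" on an exact tie.
#'
#' @param priorYears named list (by year) of numeric cumulative-DD
#'   vectors, each indexed by day of year.
#' @param current numeric cumulative-DD vector for the current year, up
#'   to the anchor day.
#' @param anchorDoy day of year at which to compare (default: last day of
#'   `current`).
#' @return list: `meanCurve` (pointwise mean over the years used),
#'   `yearsUsed`, `flag` ("earlier" / "later" / "on_pace"), `currentDD`
#'   and `meanDD` at the anchor day.
#' @export
compareYears <- function(priorYears, current, anchorDoy = length(current)) {
  stopifnot(length(priorYears) >= 1)
  if (length(priorYears) < 10)
    warning("fewer than 10 prior years; averaging ", length(priorYears))
  ord <- order(as.integer(names(priorYears)))
  priorYears <- priorYears[ord]
  use <- priorYears[seq.int(max(1, length(priorYears) - 9), length(priorYears))]
  len <- min(vapply(use, length, integer(1)))
  curve <- rowMeans(vapply(use, function(v) v[seq_len(len)], numeric(len)))
  cur <- current[anchorDoy]
  m <- curve[anchorDoy]
  flag <- if (isTRUE(all.equal(cur, m))) "on_pace"
          else if (cur > m) "earlier" else "later"
  list(meanCurve = curve, yearsUsed = names(use), flag = flag,
       currentDD = cur, meanDD = m)
}
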