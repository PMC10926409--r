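# Plain-text I/O for daily weather and analytic rasters.
#
# Station series: CSV with header date,tmin,tmax[,precip], ISO dates.
# Grids: long-format CSV with header date,lat,lon,tmin,tmax[,precip],
# one row per (day, cell). Internal units are degrees C and mm; Fahrenheit
# input is converted exactly ((F - 32) * 5/9) at read time.

# map dates to a 365-day day-of-year: Feb 29 folds into day 59 (Feb 28)
.doy365 <- function(dates) {
  md <- format(as.Date(dates), "%m-%d")
  md[md == "02-29"] <- "02-28"
  ref <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  match(md, format(ref, "%m-%d"))
}

#' Read a daily weather file
#'
#' Reads a station series (`date,tmin,tmax[,precip]`) or a long-format
#' grid (`date,lat,lon,tmin,tmax[,precip]`) CSV into a validated
#' \linkS4class{DailyWeatherCube}. Temperatures are converted to degrees C
#' when `units = "F"`. The file is rejected when the time step is not
#' daily or any row has `tmax < tmin` (the offending dates are named).
#'
#' @param path CSV file path.
#' @param units temperature units in the file: "C" or "F".
#' @return A \linkS4class{DailyWeatherCube}.
#' @seealso \code{\link{writeWeather}} for the inverse.
#' @export
readWeather <- function(path, units = c("C", "F")) {
  units <- tryCatch(match.arg(units), error = function(e)
    stop("unknown temperature units: ", units[1]))
  if (!file.exists(path)) stop("weather file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("date", "tmin", "tmax")
  if (!all(need %in% names(df)))
    stop("weather CSV must have columns date,tmin,tmax")
  df$date <- as.Date(df$date)
  conv <- function(x) if (units == "F") (x - 32) * 5 / 9 else x
  gridded <- all(c("lat", "lon") %in% names(df))
  if (gridded) {
    key <- paste(df$lat, df$lon, sep = "_")
    cells <- unique(key)
    coords <- data.frame(cell = cells,
                         lat = df$lat[match(cells, key)],
                         lon = df$lon[match(cells, key)],
                         stringsAsFactors = FALSE)
    d <- sort(unique(df$date))
    shape <- function(v) {
      m <- matrix(NA_real_, length(d), length(cells))
      m[cbind(match(df$date, d), match(key, cells))] <- v
      m
    }
    tmn <- conv(shape(df$tmin)); tmx <- conv(shape(df$tmax))
    pr <- if ("precip" %in% names(df)) shape(df$precip) else NULL
  } else {
    d <- df$date
    coords <- data.frame(cell = "station", lat = NA_real_, lon = NA_real_,
                         stringsAsFactors = FALSE)
    tmn <- matrix(conv(df$tmin), ncol = 1)
    tmx <- matrix(conv(df$tmax), ncol = 1)
    pr <- if ("precip" %in% names(df)) matrix(df$precip, ncol = 1) else NULL
  }
  if (length(d) > 1 && any(diff(as.integer(d)) != 1L))
    stop("time step is not daily in ", path)
  bad <- which(rowSums(!is.na(tmn) & !is.na(tmx) & tmx < tmn) > 0)
  if (length(bad))
    stop("tmax < tmin on: ", paste(format(d[bad]), collapse = ", "))
  DailyWeatherCube(d, tmin = tmn, tmax = tmx, precip = pr, coords = coords)
}

#' Write a weather cube
#'
#' Writes a \linkS4class{DailyWeatherCube} to CSV in the layout
#' \code{\link{readWeather}} reads back: a station series for single-cell
#' cubes, long-format grid rows otherwise. Values are written in degrees C
#' and mm.
#'
#' @param cube a \linkS4class{DailyWeatherCube}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWeather <- function(cube, path) {
  stopifnot(is(cube, "DailyWeatherCube"))
  co <- cellCoords(cube)
  if (nrow(co) == 1 && is.na(co$lat[1])) {
    df <- data.frame(date = format(dates(cube)),
                     tmin = tmin(cube)[, 1], tmax = tmax(cube)[, 1])
    if (hasPrecip(cube)) df$precip <- precip(cube)[, 1]
  } else {
    nd <- length(dates(cube))
    df <- data.frame(date = rep(format(dates(cube)), nrow(co)),
                     lat = rep(co$lat, each = nd),
                     lon = rep(co$lon, each = nd),
                     tmin = as.vector(tmin(cube)),
                     tmax = as.vector(tmax(cube)))
    if (hasPrecip(cube)) df$precip <- as.vector(precip(cube))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an analytic raster
#'
#' `writeRaster` dumps a \linkS4class{SuitabilityRaster} as CSV
#' (`cell,lat,lon,value`) with the semantic tag, period and year count in
#' `#`-prefixed header lines; `readRaster` restores it. Writing an empty
#' (zero-cell) raster is an error.
#'
#' @param x a \linkS4class{SuitabilityRaster}.
#' @param path file path.
#' @return `writeRaster`: `path` invisibly; `readRaster`: the raster.
#' @export
writeRaster <- function(x, path) {
  stopifnot(is(x, "SuitabilityRaster"))
  if (!length(x@values)) stop("cannot write an empty raster")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# meaning: ", x@meaning),
               paste0("# period: ", paste(x@period, collapse = "..")),
               paste0("# n_years: ", x@nYears)), con)
  df <- cbind(x@coords, value = x@values)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- sub("^# [a-z_]+: ", "", hdr)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  per <- if (nzchar(meta[2])) strsplit(meta[2], "\\.\\.")[[1]] else character()
  SuitabilityRaster(df$value, df[c("cell", "lat", "lon")], meta[1],
                    period = per, nYears = suppressWarnings(as.integer(meta[3])))
}

#' Write a stage timeline as CSV
#'
#' Tabular dump of a \linkS4class{StageTimeline}:
#' `date,stage,dd_added,dd_in_stage,dd_cumulative`.
#'
#' @param timeline a \linkS4class{StageTimeline}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTimeline <- function(timeline, path) {
  stopifnot(is(timeline, "StageTimeline"))
  df <- timeline@days
  names(df) <- c("date", "stage", "dd_added", "dd_in_stage", "dd_cumulative")
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a multi-year cube into calendar years
#'
#' @param cube a \linkS4class{DailyWeatherCube}.
#' @return named list of single-year cubes.
#' @export
splitYears <- function(cube) {
  yr <- as.integer(format(dates(cube), "%Y"))
  lapply(stats::setNames(nm = sort(unique(yr))), function(y)
    subsetDays(cube, which(yr == y)))
}

# index-subset along the time axis
subsetDays <- function(cube, idx) {
  DailyWeatherCube(dates(cube)[idx],
                   tmin = tmin(cube)[idx, , drop = FALSE],
                   tmax = tmax(cube)[idx, , drop = FALSE],
                   precip = if (hasPrecip(cube))
                     precip(cube)[idx, , drop = FALSE] else NULL,
                   coords = cellCoords(cube))
}

#' Build a daily climatology from multiple years
#'
#' Per day of year (1..365), the pointwise mean of tmin and tmax over the
#' most recent `nYears` supplied years; Feb 29 observations are folded
#' into day 59. Missing days are skipped in the mean; a day of year with
#' no non-missing source value at some cell is an error naming the day.
#'
#' @param cubes a list of single-year \linkS4class{DailyWeatherCube}s, or
#'   one multi-year cube (split internally).
#' @param nYears number of most recent years to average (default: all).
#' @return A \linkS4class{DailyClimatology}.
#' @export
buildClimatology <- function(cubes, nYears = NULL) {
  if (is(cubes, "DailyWeatherCube")) cubes <- splitYears(cubes)
  stopifnot(length(cubes) >= 1)
  yrs <- vapply(cubes, function(cb) as.integer(format(dates(cb)[1], "%Y")),
                integer(1))
  cubes <- cubes[order(yrs)]
  if (is.null(nYears)) nYears <- length(cubes)
  if (nYears > length(cubes)) stop("nYears exceeds the years supplied")
  cubes <- cubes[seq.int(length(cubes) - nYears + 1, length(cubes))]
  co <- cellCoords(cubes[[1]])
  nc <- nrow(co)
  accN <- accTmin <- accTmax <- matrix(0, 365, nc)
  for (cb in cubes) {
    if (!identical(dim(tmin(cb))[2], nc))
      stop("cubes must share the same cells")
    doy <- .doy365(dates(cb))
    for (r in seq_along(doy)) {            # pooled: a leap year's Feb 28
      day <- doy[r]                        # and Feb 29 each count once
      tn <- tmin(cb)[r, ]; tx <- tmax(cb)[r, ]
      ok <- is.finite(tn) & is.finite(tx)
      accTmin[day, ok] <- accTmin[day, ok] + tn[ok]
      accTmax[day, ok] <- accTmax[day, ok] + tx[ok]
      accN[day, ok] <- accN[day, ok] + 1
    }
  }
  if (any(accN == 0)) {
    miss <- which(rowSums(accN == 0) > 0)
    stop("no source data for day(s) of year: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  new("DailyClimatology", doy = 1:365, tmin = accTmin / accN,
      tmax = accTmax / accN, coords = co,
      nYears = as.integer(nYears))
}

# per-cell fraction of missing temperature days; used by the coverage rule
.missingFraction <- function(cube) {
  bad <- is.na(tmin(cube)) | is.na(tmax(cube))
  colMeans(bad)
}

#' Per-cell usability under the missing-data coverage rule
#'
#' A cell-year is usable when at most 5% of its days are missing either
#' temperature; unusable cell-years are excluded from multi-year
#' denominators by the analytics and reported per cell.
#'
#' @param cube a single-year \linkS4class{DailyWeatherCube}.
#' @param maxMissing maximum tolerated missing-day fraction (default 0.05).
#' @return logical vector, one entry per cell.
#' @export
coverageOK <- function(cube, maxMissing = 0.05)
  .missingFraction(cube) <= maxMissing
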