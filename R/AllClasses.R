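#' DailyWeatherCube: daily Tmin/Tmax(/precip) over one or more cells
#'
#' The universal weather input: strictly daily minimum and maximum
#' temperature (degrees C) and optionally precipitation (mm), for a single
#' station or a lat/lon grid of cell centres. Cells are stored as the
#' columns of days-by-cells matrices; the coordinate table has one row per
#' cell with columns `cell`, `lat`, `lon` (lat/lon may be `NA` for a
#' station series). Missing observations are `NA`.
#'
#' Validity: time strictly increasing with a one-day step, `tmax >= tmin`
#' wherever both are present, `precip >= 0` where present, and matrix
#' dimensions consistent with the dates and coordinate table.
#'
#' @slot dates Date vector, one per row of the matrices.
#' @slot coords data.frame with columns cell, lat, lon.
#' @slot tmin,tmax numeric matrices (days x cells), degrees C.
#' @slot precip numeric matrix (days x cells), mm; a 0 x 0 matrix when the
#'   cube carries no precipitation.
#' @export
setClass("DailyWeatherCube",
  representation(dates = "Date", coords = "data.frame",
                 tmin = "matrix", tmax = "matrix", precip = "matrix"),
  validity = function(object) {
    msg <- character()
    nd <- length(object@dates)
    nc <- nrow(object@coords)
    if (!all(c("cell", "lat", "lon") %in% names(object@coords)))
      msg <- c(msg, "coords must have columns cell, lat, lon")
    if (nd > 1) {
      step <- diff(as.integer(object@dates))
      if (any(step != 1L))
        msg <- c(msg, "time must be strictly increasing with a daily step")
    }
    for (s in c("tmin", "tmax")) {
      m <- slot(object, s)
      if (!identical(dim(m), c(nd, nc)))
        msg <- c(msg, sprintf("%s must be a %d x %d matrix", s, nd, nc))
    }
    if (length(object@precip) && !identical(dim(object@precip), c(nd, nc)))
      msg <- c(msg, "precip must match the cube dimensions")
    if (identical(dim(object@tmin), dim(object@tmax))) {
      bad <- which(!is.na(object@tmin) & !is.na(object@tmax) &
                     object@tmax < object@tmin)
      if (length(bad)) {
        d <- object@dates[((bad - 1L) %% nd) + 1L]
        msg <- c(msg, paste0("tmax < tmin on: ",
                             paste(unique(format(d)), collapse = ", ")))
      }
    }
    if (length(object@precip) && any(object@precip < 0, na.rm = TRUE))
      msg <- c(msg, "precip must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a DailyWeatherCube
#'
#' @param dates Date vector (daily, strictly increasing).
#' @param tmin,tmax numeric matrices or vectors (coerced to one-column
#'   matrices), degrees C.
#' @param precip optional numeric matrix/vector, mm.
#' @param coords optional data.frame with columns cell, lat, lon; defaults
#'   to a single unnamed station.
#' @return A validated \linkS4class{DailyWeatherCube}.
#' @examples
#' d <- seq(as.Date("2020-01-01"), by = "day", length.out = 10)
#' DailyWeatherCube(d, tmin = rep(5, 10), tmax = rep(15, 10))
#' @export
DailyWeatherCube <- function(dates, tmin, tmax, precip = NULL, coords = NULL) {
  tmin <- as.matrix(tmin); tmax <- as.matrix(tmax)
  if (is.null(coords))
    coords <- data.frame(cell = paste0("cell", seq_len(ncol(tmin))),
                         lat = NA_real_, lon = NA_real_,
                         stringsAsFactors = FALSE)
  precip <- if (is.null(precip)) matrix(numeric(0), 0, 0) else as.matrix(precip)
  new("DailyWeatherCube", dates = as.Date(dates), coords = coords,
      tmin = tmin, tmax = tmax, precip = precip)
}

#' @rdname accessors
setMethod("dates", "DailyWeatherCube", function(x) x@dates)
#' @rdname accessors
setMethod("cellCoords", "DailyWeatherCube", function(x) x@coords)
#' @rdname accessors
setMethod("nCells", "DailyWeatherCube", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("tmin", "DailyWeatherCube", function(x) x@tmin)
#' @rdname accessors
setMethod("tmax", "DailyWeatherCube", function(x) x@tmax)
#' @rdname accessors
setMethod("precip", "DailyWeatherCube", function(x) x@precip)
#' @rdname accessors
setMethod("hasPrecip", "DailyWeatherCube", function(x) length(x@precip) > 0)

setMethod("show", "DailyWeatherCube", function(object) {
  cat("DailyWeatherCube:", length(object@dates), "days x",
      nrow(object@coords), "cell(s)\n")
  if (length(object@dates))
    cat("  ", format(object@dates[1]), "..",
        format(object@dates[length(object@dates)]), "\n")
  cat("  variables: tmin, tmax",
      if (hasPrecip(object)) ", precip" else "", "\n", sep = "")
})

#' DailyClimatology: per-day-of-year mean Tmin/Tmax
#'
#' A 365-row long-term daily normal: the pointwise mean of tmin and tmax
#' per day of year over a set of source years. Leap-day (Feb 29)
#' observations are folded into day 59 when the climatology is built, so
#' the table always has exactly 365 rows.
#'
#' @slot doy integer 1..365.
#' @slot tmin,tmax numeric matrices (365 x cells), degrees C.
#' @slot coords cell coordinate table as in \linkS4class{DailyWeatherCube}.
#' @slot nYears integer count of source years.
#' @export
setClass("DailyClimatology",
  representation(doy = "integer", tmin = "matrix", tmax = "matrix",
                 coords = "data.frame", nYears = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(object@doy, 1:365))
      msg <- c(msg, "doy must be exactly 1..365")
    if (nrow(object@tmin) != 365L || nrow(object@tmax) != 365L)
      msg <- c(msg, "climatology matrices must have 365 rows")
    bad <- !is.na(object@tmin) & !is.na(object@tmax) & object@tmax < object@tmin
    if (any(bad)) msg <- c(msg, "tmax_mean < tmin_mean")
    if (length(msg)) msg else TRUE
  })

#' @rdname accessors
setMethod("tmin", "DailyClimatology", function(x) x@tmin)
#' @rdname accessors
setMethod("tmax", "DailyClimatology", function(x) x@tmax)
#' @rdname accessors
setMethod("cellCoords", "DailyClimatology", function(x) x@coords)
#' @rdname accessors
setMethod("nCells", "DailyClimatology", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("nYears", "DailyClimatology", function(x) x@nYears)

setMethod("show", "DailyClimatology", function(object) {
  cat("DailyClimatology: 365 days x", nrow(object@coords),
      "cell(s), mean of", object@nYears, "year(s)\n")
})

#' ThermalThresholds: developmental thresholds and degree-day method
#'
#' Lower (and optionally upper) developmental threshold temperatures with
#' the degree-day calculation method and the upper-threshold cutoff rule
#' for one life stage. `method` is one of `"simple_average"`,
#' `"single_sine"`, `"single_triangle"`; `cutoff` is `"horizontal"`
#' (development capped at the upper threshold) or `"vertical"`
#' (development halts above it) and is ignored when `upper` is `NA`.
#'
#' @slot lower,upper numeric, degrees C (`upper` may be `NA`).
#' @slot method,cutoff character flags, see above.
#' @export
setClass("ThermalThresholds",
  representation(lower = "numeric", upper = "numeric",
                 method = "character", cutoff = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("simple_average", "single_sine", "single_triangle"))
      msg <- c(msg, "unknown method")
    if (!object@cutoff %in% c("horizontal", "vertical"))
      msg <- c(msg, "unknown cutoff")
    if (!is.na(object@upper) && object@upper <= object@lower)
      msg <- c(msg, "upper threshold must exceed lower threshold")
    if (length(msg)) msg else TRUE
  })

#' @rdname ThermalThresholds-class
#' @param lower,upper threshold temperatures in degrees C; `upper = NA`
#'   means no upper threshold.
#' @param method degree-day method.
#' @param cutoff upper-threshold cutoff rule.
#' @return A \linkS4class{ThermalThresholds} object.
#' @examples
#' thermalThresholds(11.1, 38)  # oak ambrosia beetle generation thresholds
#' @export
thermalThresholds <- function(lower, upper = NA_real_,
                              method = c("single_sine", "simple_average",
                                         "single_triangle"),
                              cutoff = c("horizontal", "vertical")) {
  new("ThermalThresholds", lower = as.numeric(lower),
      upper = as.numeric(upper), method = match.arg(method),
      cutoff = match.arg(cutoff))
}

setMethod("show", "ThermalThresholds", function(object) {
  cat(sprintf("ThermalThresholds: lower %g, upper %s C, %s/%s\n",
              object@lower,
              if (is.na(object@upper)) "none" else format(object@upper),
              object@method, object@cutoff))
})

#' LifeStage: one developmental stage of a pest
#'
#' @slot name stage label (e.g. "egg").
#' @slot thresholds \linkS4class{ThermalThresholds} active during the stage.
#' @slot ddRequirement degree-days (C day) needed to complete the stage; > 0.
#' @export
setClass("LifeStage",
  representation(name = "character", thresholds = "ThermalThresholds",
                 ddRequirement = "numeric"),
  validity = function(object) {
    if (!is.finite(object@ddRequirement) || object@ddRequirement <= 0)
      "ddRequirement must be > 0" else TRUE
  })

#' @rdname LifeStage-class
#' @param name stage label.
#' @param thresholds a \linkS4class{ThermalThresholds}.
#' @param ddRequirement degree-days to complete the stage.
#' @return A \linkS4class{LifeStage}.
#' @export
lifeStage <- function(name, thresholds, ddRequirement)
  new("LifeStage", name = name, thresholds = thresholds,
      ddRequirement = as.numeric(ddRequirement))

#' PestProfile: the thermal biology parameters of one pest
#'
#' Ordered life stages with per-stage thresholds and degree-day
#' requirements, cumulative-degree-day event markers on the staged track
#' (e.g. adult emergence, end of flight), voltinism parameters (one set of
#' thresholds plus degree-days per generation), and an optional lethal
#' minimum temperature. A profile is usable in staged mode (stages
#' non-empty) and/or voltinism mode (generation parameters present).
#'
#' @slot name pest label.
#' @slot stages list of \linkS4class{LifeStage}, in developmental order.
#' @slot startDate "MM-DD" at which degree-day accumulation resets.
#' @slot events named numeric vector of strictly increasing cumulative-DD
#'   markers.
#' @slot genThresholds \linkS4class{ThermalThresholds} for voltinism, or NULL.
#' @slot ddPerGeneration degree-days for one full generation (NA if unused).
#' @slot lethalTmin lethal minimum temperature, degrees C (NA if none).
#' @slot supercoolingPoint,insulation optional provenance of `lethalTmin`:
#'   lab supercooling point minus a habitat insulation constant.
#' @export
setClass("PestProfile",
  representation(name = "character", stages = "list", startDate = "character",
                 events = "numeric", genThresholds = "ANY",
                 ddPerGeneration = "numeric", lethalTmin = "numeric",
                 supercoolingPoint = "numeric", insulation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!grepl("^\\d{2}-\\d{2}$", object@startDate))
      msg <- c(msg, "startDate must be 'MM-DD'")
    if (length(object@stages) &&
        !all(vapply(object@stages, is, logical(1), "LifeStage")))
      msg <- c(msg, "stages must be LifeStage objects")
    if (length(object@events)) {
      if (is.null(names(object@events)) || any(names(object@events) == ""))
        msg <- c(msg, "events must be named")
      if (any(diff(object@events) <= 0))
        msg <- c(msg, "event markers must be strictly increasing")
    }
    hasGen <- !is.null(object@genThresholds) && !is.na(object@ddPerGeneration)
    if (!length(object@stages) && !hasGen)
      msg <- c(msg, "profile needs stages and/or generation parameters")
    if (length(msg)) msg else TRUE
  })

#' @rdname PestProfile-class
#' @param name pest label.
#' @param stages list of \linkS4class{LifeStage} (may be empty for a pure
#'   voltinism profile).
#' @param startDate accumulation start, "MM-DD".
#' @param events named numeric cumulative-DD markers.
#' @param genThresholds thresholds for voltinism, or NULL.
#' @param ddPerGeneration degree-days per generation.
#' @param lethalTmin lethal minimum temperature (degrees C) or NA. When NA
#'   and both `supercoolingPoint` and `insulation` are given, it is derived
#'   as `supercoolingPoint - insulation`.
#' @param supercoolingPoint,insulation optional origin of the lethal limit.
#' @return A validated \linkS4class{PestProfile}.
#' @export
pestProfile <- function(name, stages = list(), startDate = "01-01",
                        events = numeric(), genThresholds = NULL,
                        ddPerGeneration = NA_real_, lethalTmin = NA_real_,
                        supercoolingPoint = NA_real_, insulation = NA_real_) {
  if (is.na(lethalTmin) && !is.na(supercoolingPoint) && !is.na(insulation))
    lethalTmin <- supercoolingPoint - insulation
  new("PestProfile", name = name, stages = stages, startDate = startDate,
      events = events, genThresholds = genThresholds,
      ddPerGeneration = as.numeric(ddPerGeneration),
      lethalTmin = as.numeric(lethalTmin),
      supercoolingPoint = as.numeric(supercoolingPoint),
      insulation = as.numeric(insulation))
}

setMethod("show", "PestProfile", function(object) {
  cat("PestProfile:", object@name, "\n")
  for (s in object@stages)
    cat(sprintf("  stage %-8s lower %g upper %s, %g DD\n", s@name,
                s@thresholds@lower,
                if (is.na(s@thresholds@upper)) "none"
                else format(s@thresholds@upper), s@ddRequirement))
  if (length(object@events))
    cat("  events:", paste(names(object@events), object@events,
                           sep = "=", collapse = ", "), "\n")
  if (!is.null(object@genThresholds))
    cat(sprintf("  generation: %g/%s C, %g DD\n", object@genThresholds@lower,
                format(object@genThresholds@upper), object@ddPerGeneration))
  if (!is.na(object@lethalTmin))
    cat(sprintf("  lethal tmin: %g C\n", object@lethalTmin))
})

#' StageTimeline: per-day phenology state for one cell
#'
#' The day-by-day output of the staged phenology run: active stage
#' ("pre-season" before the start date, "complete" after the last stage),
#' degree-days added that day under the active stage's thresholds,
#' degree-days within the current stage, and the cumulative staged track,
#' plus the per-stage transition dates and the dates each cumulative event
#' marker was first reached (NA when never reached).
#'
#' @slot cell cell identifier.
#' @slot days data.frame: date, stage, ddAdded, ddInStage, ddCumulative.
#' @slot transitions data.frame: stage, completed (Date, NA if incomplete).
#' @slot eventDates named Date vector.
#' @slot profileName label of the profile that produced the timeline.
#' @export
setClass("StageTimeline",
  representation(cell = "character", days = "data.frame",
                 transitions = "data.frame", eventDates = "Date",
                 profileName = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("date", "stage", "ddAdded", "ddInStage", "ddCumulative")
    if (!all(need %in% names(object@days)))
      msg <- c(msg, "days must have date/stage/ddAdded/ddInStage/ddCumulative")
    cum <- object@days$ddCumulative
    cum <- cum[!is.na(cum)]
    if (length(cum) > 1 && any(diff(cum) < -1e-9))
      msg <- c(msg, "ddCumulative must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' @rdname accessors
setMethod("dates", "StageTimeline", function(x) x@days$date)

setMethod("show", "StageTimeline", function(object) {
  cat("StageTimeline:", object@profileName, "at", object@cell, "—",
      nrow(object@days), "days\n")
  done <- object@transitions[!is.na(object@transitions$completed), , drop = FALSE]
  if (nrow(done))
    cat("  completed:", paste(done$stage, format(done$completed),
                              sep = " on ", collapse = "; "), "\n")
  ev <- object@eventDates[!is.na(object@eventDates)]
  if (length(ev))
    cat("  events:", paste(names(ev), format(ev), sep = " on ",
                           collapse = "; "), "\n")
})

#' SuitabilityRaster: per-cell result of an analytic tool
#'
#' Holds one value per cell — an integer count (days or years), a binary
#' flag, a float (e.g. mean generations) or a zone label — together with a
#' semantic tag, the period covered and the number of source years for
#' multi-year products.
#'
#' @slot values per-cell vector (numeric or character).
#' @slot coords cell coordinate table.
#' @slot meaning semantic tag, e.g. "condition_day_count", "years_suitable".
#' @slot period character of length 2 (start, end) or length 0.
#' @slot nYears integer (NA when not a multi-year product).
#' @export
setClass("SuitabilityRaster",
  representation(values = "ANY", coords = "data.frame", meaning = "character",
                 period = "character", nYears = "integer"),
  validity = function(object) {
    if (length(object@values) != nrow(object@coords))
      "values must have one entry per cell" else TRUE
  })

SuitabilityRaster <- function(values, coords, meaning, period = character(),
                              nYears = NA_integer_)
  new("SuitabilityRaster", values = values, coords = coords,
      meaning = meaning, period = period, nYears = as.integer(nYears))

#' @rdname accessors
setMethod("rasterValues", "SuitabilityRaster", function(x) x@values)
#' @rdname accessors
setMethod("rasterMeaning", "SuitabilityRaster", function(x) x@meaning)
#' @rdname accessors
setMethod("cellCoords", "SuitabilityRaster", function(x) x@coords)
#' @rdname accessors
setMethod("nYears", "SuitabilityRaster", function(x) x@nYears)

setMethod("show", "SuitabilityRaster", function(object) {
  cat("SuitabilityRaster (", object@meaning, "): ",
      length(object@values), " cell(s)\n", sep = "")
  if (length(object@period) == 2)
    cat("  period:", object@period[1], "..", object@period[2], "\n")
  v <- object@values
  if (is.numeric(v))
    cat("  range:", paste(range(v, na.rm = TRUE), collapse = " .. "), "\n")
  else cat("  values:", paste(utils::head(unique(v), 6), collapse = ", "), "\n")
})

#' ConditionSpec: a day-level weather condition
#'
#' Defines the condition tested by the day-count analytic: a variable
#' (tmin, tmax, tmean, rhmin, rhmax, rhmean or precip), a comparator
#' (`lt`, `le`, `gt`, `ge`, `between`), bounds in the variable's units,
#' and the minimum consecutive-day run length a day must belong to in
#' order to count.
#'
#' @slot variable,comparator character flags.
#' @slot bounds numeric length 1 (or 2 for `between`).
#' @slot minConsecutive integer >= 1.
#' @export
setClass("ConditionSpec",
  representation(variable = "character", comparator = "character",
                 bounds = "numeric", minConsecutive = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@variable %in% c("tmin", "tmax", "tmean", "rhmin", "rhmax",
                                "rhmean", "precip"))
      msg <- c(msg, "unknown variable")
    if (!object@comparator %in% c("lt", "le", "gt", "ge", "between"))
      msg <- c(msg, "unknown comparator")
    if (object@comparator == "between") {
      if (length(object@bounds) != 2 || diff(object@bounds) < 0)
        msg <- c(msg, "between needs two ordered bounds")
    } else if (length(object@bounds) != 1)
      msg <- c(msg, "comparator needs exactly one bound")
    if (object@minConsecutive < 1L)
      msg <- c(msg, "minConsecutive must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname ConditionSpec-class
#' @param variable,comparator,bounds,minConsecutive see slots.
#' @return A \linkS4class{ConditionSpec}.
#' @examples
#' conditionSpec("tmax", "gt", 30, minConsecutive = 2)
#' @export
conditionSpec <- function(variable, comparator, bounds, minConsecutive = 1L)
  new("ConditionSpec", variable = variable, comparator = comparator,
      bounds = as.numeric(bounds), minConsecutive = as.integer(minConsecutive))

#' WeatherScenario: parameters of the synthetic daily weather generator
#'
#' Describes a multi-year synthetic climate: an annual-mean temperature
#' modulated by a seasonal sinusoid (coldest mid-January), a fixed diurnal
#' range split evenly around the daily mean, lag-1 autocorrelated Gaussian
#' noise shared by tmin and tmax, an optional north-south gradient,
#' scheduled cold-snap days that override tmin, and exponential daily
#' precipitation.
#'
#' @slot meanAnnual annual mean temperature, degrees C.
#' @slot seasonalAmplitude half peak-to-trough seasonal swing, degrees C.
#' @slot diurnalRange tmax - tmin, degrees C (>= 0).
#' @slot noiseSd stationary noise standard deviation, degrees C (>= 0).
#' @slot noiseAutocorr lag-1 coefficient in [0, 1).
#' @slot latGradient degrees C per degree latitude (relative to `lat0`).
#' @slot coldSnaps data.frame: year, doy, tmin (overrides on those days).
#' @slot precipRate mean daily precipitation, mm (0 disables precip).
#' @slot years integer vector of calendar years to simulate.
#' @slot gridShape integer c(rows, cols); c(1, 1) is a single station.
#' @slot lat0 reference latitude of the first grid row.
#' @slot seed RNG seed.
#' @export
setClass("WeatherScenario",
  representation(meanAnnual = "numeric", seasonalAmplitude = "numeric",
                 diurnalRange = "numeric", noiseSd = "numeric",
                 noiseAutocorr = "numeric", latGradient = "numeric",
                 coldSnaps = "data.frame", precipRate = "numeric",
                 years = "integer", gridShape = "integer", lat0 = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@diurnalRange < 0) msg <- c(msg, "diurnalRange must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@noiseAutocorr < 0 || object@noiseAutocorr >= 1)
      msg <- c(msg, "noiseAutocorr must be in [0, 1)")
    if (!length(object@years)) msg <- c(msg, "at least one year required")
    if (length(object@gridShape) != 2 || any(object@gridShape < 1))
      msg <- c(msg, "gridShape must be two positive integers")
    if (length(msg)) msg else TRUE
  })

#' @rdname WeatherScenario-class
#' @param meanAnnual,seasonalAmplitude,diurnalRange,noiseSd,noiseAutocorr
#'   temperature process parameters, degrees C (see slots).
#' @param latGradient degrees C per degree latitude.
#' @param coldSnaps data.frame with columns year, doy, tmin.
#' @param precipRate mean daily precipitation in mm; 0 omits precipitation.
#' @param years calendar years to simulate.
#' @param gridShape c(rows, cols) of the lat/lon grid; c(1, 1) = station.
#' @param lat0 latitude of the first grid row (1-degree spacing).
#' @param seed RNG seed.
#' @return A \linkS4class{WeatherScenario}.
#' @examples
#' weatherScenario(meanAnnual = 12, seasonalAmplitude = 10, years = 2020)
#' @export
weatherScenario <- function(meanAnnual = 12, seasonalAmplitude = 10,
                            diurnalRange = 8, noiseSd = 0,
                            noiseAutocorr = 0, latGradient = 0,
                            coldSnaps = data.frame(year = integer(),
                                                   doy = integer(),
                                                   tmin = numeric()),
                            precipRate = 0, years = 2020L,
                            gridShape = c(1L, 1L), lat0 = 40, seed = 1L)
  new("WeatherScenario", meanAnnual = meanAnnual,
      seasonalAmplitude = seasonalAmplitude, diurnalRange = diurnalRange,
      noiseSd = noiseSd, noiseAutocorr = noiseAutocorr,
      latGradient = latGradient, coldSnaps = coldSnaps,
      precipRate = precipRate, years = as.integer(years),
      gridShape = as.integer(gridShape), lat0 = lat0, seed = as.integer(seed))

#' ForecastAssembly: observed + 7-day forecast + climatology horizon
#'
#' A daily series running from January 1 of the anchor year to 30 days
#' past the anchor date, with each day labelled by its source: observed
#' weather up to the anchor, forecast for (at most) the next 7 days, and
#' daily climatology for the remainder of the 30-day horizon.
#'
#' @slot cube the stitched \linkS4class{DailyWeatherCube}.
#' @slot anchor the "today" of the forecast.
#' @slot source character per day: observed / forecast / climatology.
#' @export
setClass("ForecastAssembly",
  representation(cube = "DailyWeatherCube", anchor = "Date",
                 source = "character"),
  validity = function(object) {
    msg <- character()
    d <- dates(object@cube)
    if (length(object@source) != length(d))
      msg <- c(msg, "one source label per day required")
    if (!all(object@source %in% c("observed", "forecast", "climatology")))
      msg <- c(msg, "unknown source label")
    if (length(d) && d[length(d)] != object@anchor + 30)
      msg <- c(msg, "horizon must end exactly 30 days after the anchor")
    if (any(object@source[d <= object@anchor] != "observed"))
      msg <- c(msg, "days at or before the anchor must be observed")
    if (length(msg)) msg else TRUE
  })

#' @rdname accessors
setMethod("dates", "ForecastAssembly", function(x) dates(x@cube))

#' @rdname accessors
#' @export
setGeneric("sourceLabels", function(x) standardGeneric("sourceLabels"))
#' @rdname accessors
setMethod("sourceLabels", "ForecastAssembly", function(x) x@source)

setMethod("show", "ForecastAssembly", function(object) {
  tab <- table(object@source)
  cat("ForecastAssembly anchored", format(object@anchor), "—",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
})
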