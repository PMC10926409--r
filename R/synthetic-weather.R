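# Seeded synthetic daily weather.
#
# Daily mean temperature:
#   tmean(d) = meanAnnual - seasonalAmplitude * cos(2*pi*(doy - 15)/365)
#              + latGradient * (lat - lat0) + AR(1) noise
# so the coldest day falls in mid-January (northern-hemisphere phase).
# tmin/tmax sit diurnalRange/2 below/above tmean; the AR(1) noise is
# shared by tmin and tmax (it shifts the whole day, preserving
# tmax >= tmin by construction). Scheduled cold snaps override tmin on
# the given (year, day-of-year) at every cell. Precipitation, when
# enabled, is exponential with the given daily mean.

#' Generate synthetic daily weather
#'
#' Simulates a multi-year \linkS4class{DailyWeatherCube} from a
#' \linkS4class{WeatherScenario}: seasonal sinusoid plus optional
#' latitudinal gradient and lag-1 autocorrelated noise, a constant
#' diurnal range, scheduled cold-snap days, and optional exponential
#' precipitation. Identical scenarios (same seed) give bit-identical
#' cubes; the caller's RNG state is left untouched.
#'
#' @param scenario a \linkS4class{WeatherScenario}.
#' @return A \linkS4class{DailyWeatherCube} covering every calendar day of
#'   `scenario@years` for each grid cell.
#' @examples
#' cube <- generateWeather(weatherScenario(years = 2019:2020, seed = 42))
#' range(dates(cube))
#' @export
generateWeather <- function(scenario) {
  stopifnot(is(scenario, "WeatherScenario"))
  sc <- scenario
  yrs <- sort(sc@years)
  d <- seq(as.Date(paste0(yrs[1], "-01-01")),
           as.Date(paste0(yrs[length(yrs)], "-12-31")), by = "day")
  nd <- length(d)
  nr <- sc@gridShape[1]; ncl <- sc@gridShape[2]
  nc <- nr * ncl
  lat <- rep(sc@lat0 + seq_len(nr) - 1, times = ncl)
  lon <- rep(-100 + seq_len(ncl) - 1, each = nr)
  coords <- data.frame(cell = sprintf("r%dc%d", rep(seq_len(nr), ncl),
                                      rep(seq_len(ncl), each = nr)),
                       lat = lat, lon = lon, stringsAsFactors = FALSE)
  doy <- .doy365(d)
  seasonal <- sc@meanAnnual - sc@seasonalAmplitude *
    cos(2 * pi * (doy - 15) / 365)
  base <- outer(seasonal, sc@latGradient * (lat - sc@lat0), `+`)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(sc@seed)
  noise <- matrix(0, nd, nc)
  if (sc@noiseSd > 0) {
    z <- matrix(stats::rnorm(nd * nc, sd = sc@noiseSd), nd, nc)
    if (sc@noiseAutocorr > 0) {
      phi <- sc@noiseAutocorr
      innov <- z * sqrt(1 - phi^2)   # keeps the stationary sd at noiseSd
      noise[1, ] <- z[1, ]
      for (i in 2:nd) noise[i, ] <- phi * noise[i - 1, ] + innov[i, ]
    } else noise <- z
  }
  tmean <- base + noise
  tmn <- tmean - sc@diurnalRange / 2
  tmx <- tmean + sc@diurnalRange / 2
  if (nrow(sc@coldSnaps)) {
    yr <- as.integer(format(d, "%Y"))
    for (k in seq_len(nrow(sc@coldSnaps))) {
      i <- which(yr == sc@coldSnaps$year[k] & doy == sc@coldSnaps$doy[k])
      if (length(i)) {
        tmn[i, ] <- sc@coldSnaps$tmin[k]
        tmx[i, ] <- pmax(tmx[i, ], tmn[i, ])
      }
    }
  }
  pr <- if (sc@precipRate > 0)
    matrix(stats::rexp(nd * nc, rate = 1 / sc@precipRate), nd, nc)
  DailyWeatherCube(d, tmin = tmn, tmax = tmx,
                   precip = if (sc@precipRate > 0) pr else NULL,
                   coords = coords)
}

#' Generate a synthetic short-term forecast
#'
#' Produces a forecast cube for the days `anchor+1 .. anchor+ndays` by
#' perturbing the daily climatology with seeded Gaussian noise shared by
#' tmin and tmax — a stand-in for an external forecast feed in tests and
#' examples.
#'
#' @param clim a \linkS4class{DailyClimatology}.
#' @param anchor forecast issue date (Date or "YYYY-MM-DD").
#' @param ndays forecast length in days (default 7).
#' @param sd perturbation standard deviation, degrees C.
#' @param seed RNG seed.
#' @return A \linkS4class{DailyWeatherCube} of `ndays` days.
#' @export
syntheticForecast <- function(clim, anchor, ndays = 7, sd = 1, seed = 1L) {
  stopifnot(is(clim, "DailyClimatology"))
  anchor <- as.Date(anchor)
  d <- anchor + seq_len(ndays)
  doy <- .doy365(d)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  shift <- matrix(stats::rnorm(length(d) * nCells(clim), sd = sd),
                  length(d), nCells(clim))
  DailyWeatherCube(d, tmin = tmin(clim)[doy, , drop = FALSE] + shift,
                   tmax = tmax(clim)[doy, , drop = FALSE] + shift,
                   coords = cellCoords(clim))
}

#' Read a weather scenario from a YAML file
#'
#' Scenario files mirror the \linkS4class{WeatherScenario} fields
#' (snake_case keys, e.g. `mean_annual`, `cold_snaps` as a list of
#' `{year, doy, tmin}` entries). Unspecified fields take the constructor
#' defaults.
#'
#' @param path YAML file path.
#' @return A \linkS4class{WeatherScenario}.
#' @export
readScenario <- function(path) {
  y <- yaml::read_yaml(path)
  snaps <- if (!is.null(y$cold_snaps))
    do.call(rbind, lapply(y$cold_snaps, function(s)
      data.frame(year = as.integer(s$year), doy = as.integer(s$doy),
                 tmin = as.numeric(s$tmin))))
  else data.frame(year = integer(), doy = integer(), tmin = numeric())
  args <- list(coldSnaps = snaps)
  map <- c(mean_annual = "meanAnnual", seasonal_amplitude = "seasonalAmplitude",
           diurnal_range = "diurnalRange", noise_sd = "noiseSd",
           noise_autocorr = "noiseAutocorr", lat_gradient = "latGradient",
           precip_rate = "precipRate", years = "years",
           grid_shape = "gridShape", lat0 = "lat0", seed = "seed")
  for (k in names(map)) if (!is.null(y[[k]])) args[[map[[k]]]] <- y[[k]]
  do.call(weatherScenario, args)
}
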