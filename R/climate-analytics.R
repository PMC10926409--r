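# Climate analytic tools: condition day counts, lethal-cold suitability,
# precipitation accumulation, hardiness zones, mask combination.

.cubeVariable <- function(cube, variable) {
  switch(variable,
    tmin = tmin(cube),
    tmax = tmax(cube),
    tmean = (tmin(cube) + tmax(cube)) / 2,
    precip = {
      if (!hasPrecip(cube)) stop("variable 'precip' absent from cube")
      precip(cube)
    },
    stop("variable '", variable, "' absent from cube"))
}

.applyComparator <- function(x, comparator, bounds)
  switch(comparator,
    lt = x < bounds[1], le = x <= bounds[1],
    gt = x > bounds[1], ge = x >= bounds[1],
    between = x >= bounds[1] & x <= bounds[2])

# days that belong to a run of >= k consecutive satisfying days
.runFilter <- function(sat, k) {
  if (k <= 1L) return(sat & !is.na(sat))
  sat[is.na(sat)] <- FALSE
  r <- rle(sat)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(lengths = r$lengths, values = keep))
}

#' Condition day-count analytic
#'
#' Counts, per cell, the days in the cube satisfying a
#' \linkS4class{ConditionSpec}; a day counts only if it belongs to a run
#' of at least `minConsecutive` consecutive satisfying days, and the count
#' includes every day of each qualifying run. The companion binary raster
#' is 1 wherever the count is positive.
#'
#' @param cube a \linkS4class{DailyWeatherCube}.
#' @param spec a \linkS4class{ConditionSpec}.
#' @return list of two \linkS4class{SuitabilityRaster}s: `count` and
#'   `binary`.
#' @examples
#' d <- seq(as.Date("2020-07-01"), by = "day", length.out = 10)
#' tx <- c(25, 31, 25, 32, 25, 33, 25, 25, 25, 25)
#' cube <- DailyWeatherCube(d, tmin = tx - 10, tmax = tx)
#' conditionDays(cube, conditionSpec("tmax", "gt", 30))$count
#' @export
conditionDays <- function(cube, spec) {
  stopifnot(is(cube, "DailyWeatherCube"), is(spec, "ConditionSpec"))
  v <- .cubeVariable(cube, spec@variable)
  sat <- .applyComparator(v, spec@comparator, spec@bounds)
  counts <- vapply(seq_len(ncol(sat)), function(j)
    sum(.runFilter(sat[, j], spec@minConsecutive)), numeric(1))
  per <- format(range(dates(cube)))
  list(count = SuitabilityRaster(counts, cellCoords(cube),
                                 "condition_day_count", period = per),
       binary = SuitabilityRaster(as.integer(counts > 0), cellCoords(cube),
                                  "condition_met", period = per))
}

#' Lethal-cold climate suitability over years
#'
#' A cell-year is suitable when its daily minimum temperature never
#' reaches the lethal threshold — strictly, every day has
#' `tmin > lethalTmin` (a day at or below the threshold is lethal). The
#' returned raster counts suitable years per cell; cell-years failing the
#' coverage rule are excluded from that cell's denominator and reported.
#'
#' @param cubes a multi-year \linkS4class{DailyWeatherCube} or a list of
#'   single-year cubes.
#' @param lethalTmin lethal minimum temperature, degrees C.
#' @return list: `years` (\linkS4class{SuitabilityRaster}, count of
#'   suitable years), `perYear` (years x cells logical matrix),
#'   `yearsUsed` (per-cell denominator after coverage exclusions).
#' @export
lethalSuitability <- function(cubes, lethalTmin) {
  if (is(cubes, "DailyWeatherCube")) cubes <- splitYears(cubes)
  stopifnot(length(cubes) >= 1)
  co <- cellCoords(cubes[[1]])
  suit <- matrix(NA, length(cubes), nrow(co),
                 dimnames = list(names(cubes), co$cell))
  usable <- matrix(FALSE, length(cubes), nrow(co))
  for (k in seq_along(cubes)) {
    cb <- cubes[[k]]
    coldest <- suppressWarnings(apply(tmin(cb), 2, min, na.rm = TRUE))
    usable[k, ] <- coverageOK(cb) & is.finite(coldest)
    suit[k, ] <- coldest > lethalTmin
  }
  suit[!usable] <- NA
  counts <- colSums(suit, na.rm = TRUE)
  list(years = SuitabilityRaster(unname(counts), co, "years_suitable",
                                 nYears = length(cubes)),
       perYear = suit,
       yearsUsed = stats::setNames(colSums(usable), co$cell))
}

#' Precipitation accumulation analytic
#'
#' Sums daily precipitation per cell over a date window; when a threshold
#' and comparator are given, also returns the binary raster of cells whose
#' accumulated total satisfies them.
#'
#' @param cube a \linkS4class{DailyWeatherCube} with precipitation.
#' @param start,end window bounds (default: full range).
#' @param threshold accumulated-precipitation bound in mm, or NULL.
#' @param comparator one of "lt", "le", "gt", "ge" (applied to the total).
#' @return list: `accumulated` \linkS4class{SuitabilityRaster} (mm) and,
#'   when a threshold is given, `binary`.
#' @export
precipAccumulation <- function(cube, start = NULL, end = NULL,
                               threshold = NULL, comparator = "ge") {
  stopifnot(is(cube, "DailyWeatherCube"))
  if (!hasPrecip(cube)) stop("cube has no precipitation")
  d <- dates(cube)
  start <- if (is.null(start)) d[1] else as.Date(start)
  end <- if (is.null(end)) d[length(d)] else as.Date(end)
  idx <- which(d >= start & d <= end)
  if (!length(idx)) stop("empty precipitation window")
  tot <- colSums(precip(cube)[idx, , drop = FALSE])
  per <- format(c(start, end))
  out <- list(accumulated = SuitabilityRaster(unname(tot), cellCoords(cube),
                                              "accumulated_precip_mm",
                                              period = per))
  if (!is.null(threshold))
    out$binary <- SuitabilityRaster(
      as.integer(.applyComparator(tot, comparator, threshold)),
      cellCoords(cube), "precip_condition_met", period = per)
  out
}

#' Plant hardiness zone banding
#'
#' Converts a mean annual extreme minimum temperature to a hardiness zone
#' label. Zones follow the USDA convention: 10-degree-F full zones
#' anchored at -60 F (zone 1 covers [-60, -50) F), each split into a
#' lower `a` and upper `b` 5-degree-F half-zone, half-open on the right;
#' inputs below -60 F map to "1a" and at or above 70 F to "13b".
#'
#' @param meanExtremeMin mean annual extreme minimum temperature(s).
#' @param units units of the input, "C" (converted exactly) or "F".
#' @return character vector of zone labels ("1a".."13b").
#' @examples
#' hardinessZone(-10, units = "F")   # "6a"
#' hardinessZone(-24.7, units = "C") # -12.46 F -> "5b"
#' @export
hardinessZone <- function(meanExtremeMin, units = c("C", "F")) {
  units <- match.arg(units)
  f <- if (units == "C") meanExtremeMin * 9 / 5 + 32 else meanExtremeMin
  f <- pmin(pmax(f, -60), 70 - 1e-9)         # clamp into the banded range
  half <- floor((f + 60) / 5)                # 0..25 half-zone index
  zone <- half %/% 2 + 1
  sub <- ifelse(half %% 2 == 0, "a", "b")
  out <- paste0(zone, sub)
  out[is.na(meanExtremeMin)] <- NA_character_
  out
}

#' Hardiness zones from annual extreme minima
#'
#' Averages per-year extreme minimum temperatures per cell and bands the
#' mean with \code{\link{hardinessZone}}.
#'
#' @param annualExtremes years x cells matrix of annual extreme minimum
#'   temperatures.
#' @param coords cell coordinate table.
#' @param units temperature units of `annualExtremes`.
#' @return A \linkS4class{SuitabilityRaster} of zone labels.
#' @export
hardinessRaster <- function(annualExtremes, coords, units = c("C", "F")) {
  units <- match.arg(units)
  m <- colMeans(as.matrix(annualExtremes), na.rm = TRUE)
  SuitabilityRaster(hardinessZone(m, units = units), coords,
                    "hardiness_zone", nYears = nrow(as.matrix(annualExtremes)))
}

#' Combine binary suitability masks
#'
#' Elementwise AND/OR across co-registered binary rasters; missing values
#' propagate as missing.
#'
#' @param rasters list of binary \linkS4class{SuitabilityRaster}s on the
#'   same cells.
#' @param rule "and" or "or".
#' @return A binary \linkS4class{SuitabilityRaster}.
#' @export
combineMasks <- function(rasters, rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(length(rasters) >= 1)
  n <- length(rasters[[1]]@values)
  for (r in rasters)
    if (length(r@values) != n) stop("rasters are not co-registered")
  vals <- vapply(rasters, function(r) as.numeric(r@values), numeric(n))
  vals <- matrix(vals, nrow = n)
  comb <- if (rule == "and") apply(vals, 1, function(v) as.integer(all(v > 0)))
          else apply(vals, 1, function(v) as.integer(any(v > 0)))
  comb[rowSums(is.na(vals)) > 0] <- NA_integer_
  SuitabilityRaster(comb, rasters[[1]]@coords,
                    paste0("combined_", rule))
}
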