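# Closed-form degree-day engines.
#
# Each method models the within-day temperature curve T(t), t in [0, 1]:
#   simple_average : constant at (tmin + tmax) / 2
#   single_sine    : m + a * sin(2*pi*t), m = (tmin+tmax)/2, a = (tmax-tmin)/2
#   single_triangle: symmetric triangle tmin -> tmax -> tmin
# and integrates g(T) over the day, where g(T) = 0 below the lower
# threshold L, T - L between L and the upper threshold U, and above U
# either U - L (horizontal cutoff) or 0 (vertical cutoff).
#
# The closed forms are assembled from two primitives per curve:
#   A(th)    = integral of max(T - th, 0) dt   (area above a threshold)
#   frac(th) = measure of { t : T(t) > th }    (time above a threshold)
# giving, with L = lower, U = upper:
#   no upper   : DD = A(L)
#   horizontal : DD = A(L) - A(U)              (= integral of min((T-L)+, U-L))
#   vertical   : DD = A(L) - A(U) - (U-L) * frac(U)

# area above threshold for the sine curve; Baskerville-Emin form
.sineArea <- function(th, tmin, tmax) {
  m <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  out <- numeric(length(m))
  below <- tmax <= th          # whole day at or below the threshold
  above <- tmin >= th          # whole day at or above it
  out[above] <- (m - th)[above]
  mid <- !below & !above
  if (any(mid)) {
    phi <- asin(((th - m) / a)[mid])
    out[mid] <- ((m[mid] - th) * (pi / 2 - phi) + a[mid] * cos(phi)) / pi
  }
  out
}

.sineFracAbove <- function(th, tmin, tmax) {
  m <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  out <- numeric(length(m))
  out[tmin >= th & tmax > th] <- 1
  mid <- tmax > th & tmin < th
  if (any(mid)) {
    phi <- asin(((th - m) / a)[mid])
    out[mid] <- (pi / 2 - phi) / pi
  }
  out
}

.triArea <- function(th, tmin, tmax) {
  out <- numeric(length(tmin))
  above <- tmin >= th
  out[above] <- ((tmin + tmax) / 2 - th)[above]
  mid <- tmax > th & tmin < th
  if (any(mid))
    out[mid] <- ((tmax - th)^2 / (2 * (tmax - tmin)))[mid]
  out
}

.triFracAbove <- function(th, tmin, tmax) {
  out <- numeric(length(tmin))
  out[tmin >= th & tmax > th] <- 1
  mid <- tmax > th & tmin < th
  if (any(mid)) out[mid] <- ((tmax - th) / (tmax - tmin))[mid]
  out
}

#' Daily degree-days from Tmin/Tmax
#'
#' Computes the degree-days accrued in one day from its minimum and
#' maximum temperature under a \linkS4class{ThermalThresholds} object:
#' the day's temperature curve (constant mean, single sine, or single
#' triangle) is integrated above the lower developmental threshold, with
#' temperatures above the upper threshold either capped at it (horizontal
#' cutoff) or contributing nothing (vertical cutoff).
#'
#' Closed forms are used throughout; they agree with direct numerical
#' quadrature of the clipped curve. The result is always >= 0, at most
#' `upper - lower` under a horizontal cutoff, and exactly
#' `(tmin + tmax)/2 - lower` for every method when the whole day lies
#' within `[lower, upper]`.
#'
#' @param tmin,tmax daily minimum and maximum temperature, degrees C;
#'   vectors are recycled to a common length. `NA` yields `NA`.
#' @param th a \linkS4class{ThermalThresholds}.
#' @return numeric vector of degree-days (C day).
#' @examples
#' th <- thermalThresholds(10, 30, method = "simple_average")
#' ddDay(10, 20, th)  # mean 15 minus lower 10 = 5
#' @export
ddDay <- function(tmin, tmax, th) {
  stopifnot(is(th, "ThermalThresholds"))
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  ok <- is.finite(tmin) & is.finite(tmax)
  if (any(tmax[ok] < tmin[ok]))
    stop("tmax < tmin: degree-days undefined")
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)
  lo <- tmin[ok]; hi <- tmax[ok]
  L <- th@lower; U <- th@upper
  val <- switch(th@method,
    simple_average = {
      m <- (lo + hi) / 2
      if (is.na(U)) pmax(m - L, 0)
      else if (th@cutoff == "horizontal") pmin(pmax(m, L), U) - L
      else ifelse(m > U, 0, pmax(m - L, 0))
    },
    single_sine = {
      if (is.na(U)) .sineArea(L, lo, hi)
      else if (th@cutoff == "horizontal")
        .sineArea(L, lo, hi) - .sineArea(U, lo, hi)
      else .sineArea(L, lo, hi) - .sineArea(U, lo, hi) -
        (U - L) * .sineFracAbove(U, lo, hi)
    },
    single_triangle = {
      if (is.na(U)) .triArea(L, lo, hi)
      else if (th@cutoff == "horizontal")
        .triArea(L, lo, hi) - .triArea(U, lo, hi)
      else .triArea(L, lo, hi) - .triArea(U, lo, hi) -
        (U - L) * .triFracAbove(U, lo, hi)
    })
  out[ok] <- pmax(val, 0)   # guard tiny negative round-off
  out
}

#' Accumulated degree-days over a window
#'
#' Running (cumulative) degree-day sum per cell over an inclusive date
#' window, applying \code{\link{ddDay}} day by day. Missing temperature
#' days yield missing degree-days, and the cumulative series stays
#' missing from the first missing day onward.
#'
#' @param cube a \linkS4class{DailyWeatherCube}.
#' @param th a \linkS4class{ThermalThresholds}.
#' @param start,end window bounds (Date or "YYYY-MM-DD"); defaults to the
#'   cube's full range.
#' @return a days-by-cells matrix of cumulative degree-days, with the
#'   window dates as rownames.
#' @examples
#' d <- seq(as.Date("2020-06-01"), by = "day", length.out = 10)
#' cube <- DailyWeatherCube(d, tmin = rep(20, 10), tmax = rep(20, 10))
#' ddAccumulate(cube, thermalThresholds(3, 38))[, 1]  # 17, 34, ..., 170
#' @export
ddAccumulate <- function(cube, th, start = NULL, end = NULL) {
  stopifnot(is(cube, "DailyWeatherCube"))
  d <- dates(cube)
  start <- if (is.null(start)) d[1] else as.Date(start)
  end <- if (is.null(end)) d[length(d)] else as.Date(end)
  if (start > end) stop("empty accumulation window")
  if (start < d[1] || end > d[length(d)])
    stop("window outside the cube's time range")
  idx <- which(d >= start & d <= end)
  daily <- matrix(ddDay(as.vector(tmin(cube)[idx, , drop = FALSE]),
                        as.vector(tmax(cube)[idx, , drop = FALSE]), th),
                  nrow = length(idx))
  out <- apply(daily, 2, cumsum)
  out <- matrix(out, nrow = length(idx),
                dimnames = list(format(d[idx]), cellCoords(cube)$cell))
  out
}
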