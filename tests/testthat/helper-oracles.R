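# Independent oracles: numerical quadrature for daily degree-days and a
# flat scalar day-loop for the staged phenology model. These deliberately
# share no code with the package internals they check.

# within-day curves, evaluated at arbitrary times in [0, 1]
.curveAt <- function(t, tmin, tmax, method) {
  if (method == "single_sine")
    (tmin + tmax) / 2 + (tmax - tmin) / 2 * sin(2 * pi * t)
  else if (method == "single_triangle")
    tmin + (tmax - tmin) * (1 - abs(2 * t - 1))
  else rep((tmin + tmax) / 2, length(t))
}

.clipDD <- function(temp, L, U, cutoff) {
  g <- pmax(temp - L, 0)
  if (!is.na(U)) {
    if (cutoff == "horizontal") g <- pmin(g, U - L)
    else g[temp > U] <- 0
  }
  g
}

# midpoint quadrature on n uniform subintervals; cells containing the
# vertical-cutoff jump are refined with a fine midpoint rule so the
# oracle's own error stays well below 1e-6
ddQuad <- function(tmin, tmax, L, U, method, cutoff, n = 1e6) {
  mids <- (seq_len(n) - 0.5) / n
  temp <- .curveAt(mids, tmin, tmax, method)
  g <- .clipDD(temp, L, U, cutoff)
  total <- mean(g)
  if (!is.na(U) && cutoff == "vertical" && tmax > U && tmin < U) {
    s <- sign(temp - U)
    jump <- which(s[-1] != s[-n])        # jump lies between mids j and j+1
    cells <- sort(unique(pmin(pmax(c(jump, jump + 1), 1), n)))
    fine <- (seq_len(10000) - 0.5) / 10000
    for (j in cells) {
      tt <- (j - 1 + fine) / n
      gj <- mean(.clipDD(.curveAt(tt, tmin, tmax, method), L, U, cutoff))
      total <- total + (gj - g[j]) / n
    }
  }
  total
}

# scalar day loop over a temperature series: stage-switched accumulation
# with the no-carry transition rule; returns per-day stage index (0 =
# pre-start handled by caller), cumulative DD, and completion days
stagedOracle <- function(tmn, tmx, lowers, uppers, reqs, ddFun) {
  nst <- length(reqs)
  si <- 1; inStage <- 0; cum <- 0
  stageIdx <- integer(length(tmn)); cumOut <- numeric(length(tmn))
  doneDay <- rep(NA_integer_, nst)
  for (i in seq_along(tmn)) {
    k <- min(si, nst)
    dd <- ddFun(tmn[i], tmx[i], lowers[k], uppers[k])
    inStage <- inStage + dd; cum <- cum + dd
    stageIdx[i] <- si; cumOut[i] <- cum
    if (si <= nst && inStage >= reqs[si]) {
      doneDay[si] <- i
      si <- si + 1; inStage <- 0
    }
  }
  list(stageIdx = stageIdx, cum = cumOut, doneDay = doneDay)
}

# daily single-sine horizontal-cutoff degree-days, written directly from
# the Baskerville-Emin geometry (used only to drive stagedOracle)
sineHorizDD <- function(tmin, tmax, L, U) {
  area <- function(th) {
    if (tmax <= th) return(0)
    if (tmin >= th) return((tmin + tmax) / 2 - th)
    m <- (tmin + tmax) / 2; a <- (tmax - tmin) / 2
    phi <- asin((th - m) / a)
    ((m - th) * (pi / 2 - phi) + a * cos(phi)) / pi
  }
  if (is.na(U)) area(L) else area(L) - area(U)
}

constantCube <- function(temp, year = 2021, diurnal = 0, ncells = 1) {
  d <- seq(as.Date(paste0(year, "-01-01")), as.Date(paste0(year, "-12-31")),
           by = "day")
  DailyWeatherCube(d,
                   tmin = matrix(temp - diurnal / 2, length(d), ncells),
                   tmax = matrix(temp + diurnal / 2, length(d), ncells))
}
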