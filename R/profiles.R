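# Pest-profile files: plain-text key-value stanzas.
#
#   name: spongy_moth
#   start_date: 01-01
#   stage: egg lower=3 upper=38 dd=282 [method=single_sine cutoff=horizontal]
#   event: adult_emergence 1143
#   generation: lower=11.1 upper=38 dd=1486
#   lethal: tmin=-21.5            or    supercooling_point=-20.3 insulation=1.2
#
# The default degree-day method is single sine with horizontal cutoff.

.parseKV <- function(body) {
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  kv <- toks[grepl("=", toks)]
  vals <- sub("^[^=]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  as.list(vals)
}

.stanzaThresholds <- function(kv) {
  thermalThresholds(
    lower = as.numeric(kv$lower),
    upper = if (is.null(kv$upper)) NA_real_ else as.numeric(kv$upper),
    method = if (is.null(kv$method)) "single_sine" else kv$method,
    cutoff = if (is.null(kv$cutoff)) "horizontal" else kv$cutoff)
}

#' Read a pest-profile file
#'
#' Parses the plain-text stanza format (see the shipped
#' `spongy_moth.profile` and `oab.profile` under `extdata`) into a
#' validated \linkS4class{PestProfile}. Malformed stanzas, missing stage
#' parameters, an upper threshold at or below the lower, and
#' non-increasing event markers are rejected with specific messages.
#'
#' @param path profile file path.
#' @return A \linkS4class{PestProfile}.
#' @examples
#' readPestProfile(system.file("extdata", "spongy_moth.profile",
#'                             package = "phenoforge"))
#' @export
readPestProfile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  name <- NA_character_; startDate <- "01-01"
  stages <- list(); events <- numeric()
  genTh <- NULL; ddGen <- NA_real_
  lethal <- scp <- insul <- NA_real_
  for (ln in lines) {
    if (!grepl(":", ln)) stop("malformed profile line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    body <- trimws(sub("^[^:]+:", "", ln))
    switch(key,
      name = name <- body,
      start_date = startDate <- body,
      stage = {
        sname <- strsplit(body, "\\s+")[[1]][1]
        kv <- .parseKV(body)
        if (is.null(kv$lower) || is.null(kv$dd))
          stop("stage '", sname, "' needs lower= and dd=")
        stages[[length(stages) + 1]] <-
          lifeStage(sname, .stanzaThresholds(kv), as.numeric(kv$dd))
      },
      event = {
        toks <- strsplit(body, "\\s+")[[1]]
        if (length(toks) != 2) stop("event stanza needs: name value")
        events[toks[1]] <- as.numeric(toks[2])
      },
      generation = {
        kv <- .parseKV(body)
        if (is.null(kv$lower) || is.null(kv$dd))
          stop("generation stanza needs lower= and dd=")
        genTh <- .stanzaThresholds(kv)
        ddGen <- as.numeric(kv$dd)
      },
      lethal = {
        kv <- .parseKV(body)
        if (!is.null(kv$tmin)) lethal <- as.numeric(kv$tmin)
        if (!is.null(kv$supercooling_point))
          scp <- as.numeric(kv$supercooling_point)
        if (!is.null(kv$insulation)) insul <- as.numeric(kv$insulation)
        if (is.na(lethal) && (is.na(scp) || is.na(insul)))
          stop("lethal stanza needs tmin= or supercooling_point= + insulation=")
      },
      stop("unknown profile stanza: ", key))
  }
  if (is.na(name)) stop("profile is missing a name stanza")
  pestProfile(name, stages = stages, startDate = startDate, events = events,
              genThresholds = genTh, ddPerGeneration = ddGen,
              lethalTmin = lethal, supercoolingPoint = scp, insulation = insul)
}

#' Write a pest profile
#'
#' Serialises a \linkS4class{PestProfile} to the stanza text format
#' \code{\link{readPestProfile}} reads back.
#'
#' @param profile a \linkS4class{PestProfile}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePestProfile <- function(profile, path) {
  stopifnot(is(profile, "PestProfile"))
  fmtTh <- function(th)
    paste0("lower=", th@lower,
           if (!is.na(th@upper)) paste0(" upper=", th@upper),
           " method=", th@method, " cutoff=", th@cutoff)
  out <- c(paste0("name: ", profile@name),
           paste0("start_date: ", profile@startDate))
  for (s in profile@stages)
    out <- c(out, paste0("stage: ", s@name, " ", fmtTh(s@thresholds),
                         " dd=", s@ddRequirement))
  for (k in seq_along(profile@events))
    out <- c(out, paste0("event: ", names(profile@events)[k], " ",
                         profile@events[k]))
  if (!is.null(profile@genThresholds))
    out <- c(out, paste0("generation: ", fmtTh(profile@genThresholds),
                         " dd=", profile@ddPerGeneration))
  if (!is.na(profile@supercoolingPoint) && !is.na(profile@insulation))
    out <- c(out, paste0("lethal: supercooling_point=",
                         profile@supercoolingPoint, " insulation=",
                         profile@insulation))
  else if (!is.na(profile@lethalTmin))
    out <- c(out, paste0("lethal: tmin=", profile@lethalTmin))
  writeLines(out, path)
  invisible(path)
}

#' Built-in pest profiles
#'
#' `spongyMothProfile()` returns the spongy moth (*Lymantria dispar*)
#' adult-emergence profile: egg 3/38 C and 282 DD, larvae 7.2/41 C and
#' 583 DD, pupae 6.6/41 C and 277 DD, accumulation from January 1, with
#' cumulative event markers at 1,143 DD (first adult emergence) and
#' 1,528 DD (end of the flight period). `oabProfile()` returns the oak
#' ambrosia beetle (*Platypus quercivorus*) suitability profile:
#' generation thresholds 11.1/38 C with 1,486 DD per generation, and a
#' lethal minimum of -21.5 C derived from a -20.3 C supercooling point
#' minus a 1.2 C tree-interior insulation constant.
#'
#' Identical copies ship as text fixtures under `extdata`.
#'
#' @param method,cutoff degree-day method and cutoff applied to every
#'   threshold set (defaults: single sine, horizontal).
#' @return A \linkS4class{PestProfile}.
#' @export
spongyMothProfile <- function(method = "single_sine", cutoff = "horizontal") {
  pestProfile("spongy_moth",
    stages = list(
      lifeStage("egg", thermalThresholds(3, 38, method, cutoff), 282),
      lifeStage("larvae", thermalThresholds(7.2, 41, method, cutoff), 583),
      lifeStage("pupae", thermalThresholds(6.6, 41, method, cutoff), 277)),
    startDate = "01-01",
    events = c(adult_emergence = 1143, flight_end = 1528))
}

#' @rdname spongyMothProfile
#' @export
oabProfile <- function(method = "single_sine", cutoff = "horizontal") {
  pestProfile("oak_ambrosia_beetle",
    genThresholds = thermalThresholds(11.1, 38, method, cutoff),
    ddPerGeneration = 1486,
    supercoolingPoint = -20.3, insulation = 1.2)
}
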