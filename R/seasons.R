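# The Somali seasonal calendar: Jilaal (Dec-Mar, dry), Gu (Apr-Jun, wet),
# Hagaa (Jul-Sep, dry), Deyr (Oct-Nov, wet). December belongs to the Jilaal
# that spans the year boundary, labeled with the following calendar year.

#' Create a SeasonId
#'
#' @param name one of `"Jilaal"`, `"Gu"`, `"Hagaa"`, `"Deyr"`.
#' @param year season year label (a Jilaal spanning Dec Y-1 to Mar Y has
#'   label Y).
#' @return a [SeasonId-class].
#' @export
seasonId <- function(name, year) {
  new("SeasonId", name = as.character(name), year = as.integer(year))
}

#' @rdname SeasonId-class
#' @export
setMethod("isWet", "SeasonId", function(x) x@name %in% .WET_SEASONS)

#' @rdname SeasonId-class
#' @export
setMethod("seasonIndex", "SeasonId", function(x) {
  4L * x@year + match(x@name, .SEASON_NAMES) - 1L
})

setMethod("show", "SeasonId", function(object) {
  cat(sprintf("SeasonId: %s %d (%s)\n", object@name, object@year,
              if (isWet(object)) "wet" else "dry"))
  invisible(object)
})

#' Map a calendar month to its season
#'
#' @param month calendar month 1..12.
#' @param year calendar year.
#' @return a [SeasonId-class]. December attaches to the Jilaal labeled
#'   `year + 1`.
#' @export
seasonOfMonth <- function(month, year) {
  month <- as.integer(month); year <- as.integer(year)
  if (month < 1 || month > 12) stop("month must lie in 1..12")
  if (month == 12L) return(seasonId("Jilaal", year + 1L))
  if (month <= 3L) return(seasonId("Jilaal", year))
  if (month <= 6L) return(seasonId("Gu", year))
  if (month <= 9L) return(seasonId("Hagaa", year))
  seasonId("Deyr", year)
}

#' Calendar month and year of a simulation tick
#'
#' @param tick monthly tick, 1-based.
#' @param startMonth,startYear calendar anchor of tick 1.
#' @return list with `month` and `year`.
#' @export
tickDate <- function(tick, startMonth = 1L, startYear = 2008L) {
  if (any(tick < 1)) stop("tick must be >= 1")
  m0 <- (startMonth - 1L) + (as.integer(tick) - 1L)
  list(month = m0 %% 12L + 1L, year = as.integer(startYear + m0 %/% 12L))
}

#' Season of a simulation tick
#'
#' @inheritParams tickDate
#' @return a [SeasonId-class].
#' @examples
#' seasonOf(1)   # January 2008 -> Jilaal (dry)
#' seasonOf(5)   # May -> Gu (wet)
#' seasonOf(10)  # October -> Deyr (wet)
#' @export
seasonOf <- function(tick, startMonth = 1L, startYear = 2008L) {
  d <- tickDate(tick, startMonth, startYear)
  seasonOfMonth(d$month, d$year)
}

#' Ordered distinct seasons covering a run
#'
#' @param nTicks number of monthly ticks.
#' @inheritParams tickDate
#' @return list with `seasons` (list of [SeasonId-class] in time order) and
#'   `tickSeason` (integer vector mapping each tick to its season's position
#'   in `seasons`).
#' @export
seasonSequence <- function(nTicks, startMonth = 1L, startYear = 2008L) {
  idx <- vapply(seq_len(nTicks),
                function(t) seasonIndex(seasonOf(t, startMonth, startYear)),
                integer(1))
  uniq <- unique(idx)
  seasons <- lapply(uniq, function(i) {
    seasonId(.SEASON_NAMES[i %% 4L + 1L], i %/% 4L)
  })
  list(seasons = seasons, tickSeason = match(idx, uniq))
}
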