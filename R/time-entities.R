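# TEO time entities: partial dates, time instants, intervals, durations and
# periodic intervals.  Normalized times are calendar dates of day, month or
# year precision; the year may be unknown (narratives often state only a
# month and day, the year coming from the structured record).

#' Controlled vocabulary of time units / granularities
#'
#' The unit vocabulary shared by [duration()] values and [time_instant()]
#' granularities, ordered fine to coarse.
#'
#' @return Character vector of the seven recognized units.
#' @export
#' @examples
#' granularity_levels()
granularity_levels <- function() {
  c("second", "minute", "hour", "day", "week", "month", "year")
}

# Precision rank used when comparing / combining granularities.  A week is
# an exact multiple of days, so for date arithmetic it carries day precision.
.gran_rank <- function(g) {
  rank <- c(second = 1, minute = 2, hour = 3, day = 4, week = 4, month = 5, year = 6)
  unname(rank[g])
}

coarser_granularity <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  if (.gran_rank(g1) >= .gran_rank(g2)) g1 else g2
}

check_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% granularity_levels()) {
    abort_invalid_input(sprintf(
      "unit must be one of: %s", paste(granularity_levels(), collapse = ", ")
    ))
  }
  unit
}

# ---------------------------------------------------------------------------
# Partial calendar dates

#' Partial calendar date
#'
#' A calendar date whose precision may stop at the year or month, and whose
#' year may be unknown (`NA`) when a narrative gives only a month and day.
#'
#' @param year,month,day Integer components; `NA` for absent ones.
#' @return An object of class `teo_partial_date`.
#' @export
#' @examples
#' partial_date(2006, 7, 6)
#' partial_date(NA, 8, 8)   # year to be resolved from the structured record
partial_date <- function(year = NA_integer_, month = NA_integer_, day = NA_integer_) {
  year <- as.integer(year); month <- as.integer(month); day <- as.integer(day)
  if (!is.na(month) && (month < 1L || month > 12L)) {
    abort_invalid_input(sprintf("month out of range: %d", month))
  }
  if (!is.na(day)) {
    if (is.na(month)) abort_invalid_input("a day requires a month")
    max_day <- if (is.na(year)) 31L else days_in_month(year, month)
    if (day < 1L || day > max_day) {
      abort_invalid_input(sprintf("day out of range: %d", day))
    }
  }
  if (is.na(year) && is.na(month) && is.na(day)) {
    abort_invalid_input("partial date needs at least one component")
  }
  structure(list(year = year, month = month, day = day), class = "teo_partial_date")
}

is_partial_date <- function(x) inherits(x, "teo_partial_date")

days_in_month <- function(year, month) {
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- dim[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n[month == 2L & leap] <- 29L
  n
}

#' @export
format.teo_partial_date <- function(x, ...) {
  y <- if (is.na(x$year)) "-" else sprintf("%04d", x$year)
  if (is.na(x$month)) return(y)
  m <- sprintf("%02d", x$month)
  if (is.na(x$day)) return(paste(y, m, sep = "-"))
  paste(y, m, sprintf("%02d", x$day), sep = "-")
}

#' @export
print.teo_partial_date <- function(x, ...) {
  cat("<partial date>", format(x), sprintf("[%s]", date_granularity(x)), "\n")
  invisible(x)
}

# Parse the serialized form produced by format.teo_partial_date (and plain
# ISO dates): "2006-07-06", "2006-07", "2006", "--07-06", "--07".
parse_partial_date <- function(text) {
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", text)) {
    p <- as.integer(strsplit(text, "-", fixed = TRUE)[[1L]])
    return(partial_date(p[1L], p[2L], p[3L]))
  }
  if (grepl("^\\d{4}-\\d{2}$", text)) {
    p <- as.integer(strsplit(text, "-", fixed = TRUE)[[1L]])
    return(partial_date(p[1L], p[2L]))
  }
  if (grepl("^\\d{4}$", text)) return(partial_date(as.integer(text)))
  if (grepl("^--\\d{2}-\\d{2}$", text)) {
    p <- as.integer(strsplit(sub("^--", "", text), "-", fixed = TRUE)[[1L]])
    return(partial_date(NA, p[1L], p[2L]))
  }
  if (grepl("^--\\d{2}$", text)) {
    return(partial_date(NA, as.integer(sub("^--", "", text))))
  }
  abort_parse(sprintf("cannot parse partial date %s", dQuote(text)), token = text)
}

#' Granularity implied by a partial date
#'
#' @param pd A [partial_date()].
#' @return `"day"`, `"month"` or `"year"`.
#' @export
date_granularity <- function(pd) {
  stopifnot(is_partial_date(pd))
  if (!is.na(pd$day)) "day" else if (!is.na(pd$month)) "month" else "year"
}

date_is_complete <- function(pd) {
  is_partial_date(pd) && !is.na(pd$year) && !is.na(pd$month) && !is.na(pd$day)
}

pd_to_Date <- function(pd) {
  if (!date_is_complete(pd)) {
    abort_invalid_input("date is not resolved to a full calendar day")
  }
  as.Date(sprintf("%04d-%02d-%02d", pd$year, pd$month, pd$day))
}

pd_truncate <- function(pd, granularity) {
  switch(granularity,
    day   = pd,
    month = partial_date(pd$year, pd$month),
    year  = partial_date(pd$year),
    abort_invalid_input(sprintf("cannot truncate a date to granularity %s", dQuote(granularity)))
  )
}

#' Shift a partial date by a calendar duration
#'
#' Days and weeks move the date on the calendar exactly (a week is seven
#' days); months and years shift the month/year components, clamping the day
#' to the target month's length.  No 30- or 365-day approximations are used.
#'
#' @param pd A [partial_date()] with a known year.
#' @param dur A [duration()].
#' @param sign `+1` to move forward, `-1` backward.
#' @return A shifted `teo_partial_date`; its granularity is the coarser of the
#'   date's and the duration unit's precision.
#' @export
#' @examples
#' shift_date(partial_date(2006, 7, 6), duration(18, "day"))
shift_date <- function(pd, dur, sign = 1L) {
  stopifnot(is_partial_date(pd), is_duration(dur), sign %in% c(-1L, 1L))
  if (is.na(pd$year)) abort_invalid_input("cannot shift a date with an unknown year")
  amount <- sign * dur$value
  unit <- dur$unit
  if (unit %in% c("second", "minute", "hour")) {
    abort_invalid_input("sub-day offsets are not supported for date arithmetic")
  }
  if (unit %in% c("day", "week")) {
    if (is.na(pd$day)) {
      # day-level offset against a coarser date cannot land on a day
      return(pd_truncate(pd, date_granularity(pd)))
    }
    ndays <- if (unit == "week") amount * 7 else amount
    d <- pd_to_Date(pd) + ndays
    lt <- as.POSIXlt(d)
    return(partial_date(lt$year + 1900L, lt$mon + 1L, lt$mday))
  }
  # month / year arithmetic, calendar-aware
  nmonths <- if (unit == "year") amount * 12 else amount
  base_month <- if (is.na(pd$month)) 1L else pd$month
  total <- (pd$year * 12L + (base_month - 1L)) + nmonths
  new_year <- total %/% 12L
  new_month <- total %% 12L + 1L
  if (is.na(pd$month)) {
    if (unit == "year") return(partial_date(pd$year + amount))
    return(partial_date(new_year, new_month))
  }
  if (is.na(pd$day)) return(partial_date(new_year, new_month))
  new_day <- min(pd$day, days_in_month(new_year, new_month))
  out <- partial_date(new_year, new_month, new_day)
  # a month/year step is only month/year-precise
  if (unit %in% c("month", "year")) out else out
}

#' Compare two partial dates at their coarser common granularity
#'
#' Dates of different precision are compared after truncating both to the
#' coarser precision, so a day-granular date is never ordered against a
#' month-granular one by an invented day.
#'
#' @param a,b [partial_date()] objects with known years.
#' @return `-1L`, `0L` or `1L` (`0L` means equal *at the compared
#'   granularity*, not necessarily simultaneous).
#' @export
compare_dates <- function(a, b) {
  stopifnot(is_partial_date(a), is_partial_date(b))
  if (is.na(a$year) || is.na(b$year)) {
    abort_invalid_input("cannot compare dates with unresolved years")
  }
  g <- coarser_granularity(date_granularity(a), date_granularity(b))
  a <- pd_truncate(a, g); b <- pd_truncate(b, g)
  ka <- c(a$year, if (!is.na(a$month)) a$month else 0L, if (!is.na(a$day)) a$day else 0L)
  kb <- c(b$year, if (!is.na(b$month)) b$month else 0L, if (!is.na(b$day)) b$day else 0L)
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(-1L)
    if (ka[i] > kb[i]) return(1L)
  }
  0L
}

# ---------------------------------------------------------------------------
# Durations

#' Duration
#'
#' A non-negative quantity of time in a controlled unit, e.g. the "eighteen
#' days" separating a vaccination from a fever onset.
#'
#' @param value Non-negative number.
#' @param unit One of [granularity_levels()].
#' @return An object of class `teo_duration`.
#' @export
#' @examples
#' duration(18, "day")
#' duration(2, "week")
duration <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    abort_invalid_input("duration value must be a single non-negative number")
  }
  structure(list(value = as.numeric(value), unit = check_unit(unit)),
            class = "teo_duration")
}

is_duration <- function(x) inherits(x, "teo_duration")

#' @export
format.teo_duration <- function(x, ...) {
  sprintf("%s %s%s", format(x$value), x$unit, if (x$value == 1) "" else "s")
}

#' @export
print.teo_duration <- function(x, ...) {
  cat("<duration>", format(x), "\n")
  invisible(x)
}

#' Render a duration in the canonical textual form
#'
#' Inverse of [parse_duration_expression()] on the controlled vocabulary.
#'
#' @param dur A [duration()].
#' @return A string such as `"18 days"`.
#' @export
format_duration <- function(dur) {
  stopifnot(is_duration(dur))
  format(dur)
}

# ---------------------------------------------------------------------------
# Time instants and intervals

#' Time instant
#'
#' A time stamp as written in a narrative, optionally normalized to a partial
#' ISO date with an explicit granularity.  The original expression is kept
#' verbatim (`hasOrigTime` in the serialization); normalization never
#' overwrites it.
#'
#' @param orig_text The expression exactly as written, or `NA` for instants
#'   that exist only through inference.
#' @param normalized Optional [partial_date()].
#' @param granularity Optional granularity; defaults to the precision of
#'   `normalized` when that is given.
#' @param unresolved Logical flag: the normalized value still misses its year.
#' @return An object of class `teo_time_instant`.
#' @export
#' @examples
#' time_instant("July 6th", partial_date(2006, 7, 6))
time_instant <- function(orig_text = NA_character_, normalized = NULL,
                         granularity = NULL, unresolved = FALSE) {
  if (!is.null(normalized)) {
    stopifnot(is_partial_date(normalized))
    implied <- date_granularity(normalized)
    if (is.null(granularity)) granularity <- implied
    if (granularity != implied) {
      abort_invalid_input(sprintf(
        "granularity %s does not match the precision of %s",
        dQuote(granularity), format(normalized)
      ))
    }
    if (is.na(normalized$year)) unresolved <- TRUE
  }
  if (!is.null(granularity)) check_unit(granularity)
  structure(
    list(orig_text = orig_text, normalized = normalized,
         granularity = granularity, unresolved = isTRUE(unresolved)),
    class = "teo_time_instant"
  )
}

is_time_instant <- function(x) inherits(x, "teo_time_instant")

#' @export
format.teo_time_instant <- function(x, ...) {
  norm <- if (is.null(x$normalized)) "?" else format(x$normalized)
  orig <- if (is.na(x$orig_text)) "(inferred)" else dQuote(x$orig_text)
  sprintf("%s -> %s [%s]%s", orig, norm,
          if (is.null(x$granularity)) "?" else x$granularity,
          if (x$unresolved) " (year unresolved)" else "")
}

#' @export
print.teo_time_instant <- function(x, ...) {
  cat("<time instant>", format(x), "\n")
  invisible(x)
}

#' Time interval
#'
#' A span with any combination of a start instant, an end instant and a
#' duration; when all three are present they must agree on the calendar at
#' the instants' granularity.
#'
#' @param start,end Optional [time_instant()]s.
#' @param duration Optional [duration()].
#' @return An object of class `teo_time_interval`.
#' @export
time_interval <- function(start = NULL, end = NULL, duration = NULL) {
  if (is.null(start) && is.null(end) && is.null(duration)) {
    abort_invalid_input("a time interval needs a start, an end or a duration")
  }
  if (!is.null(start)) stopifnot(is_time_instant(start))
  if (!is.null(end)) stopifnot(is_time_instant(end))
  if (!is.null(duration)) stopifnot(is_duration(duration))
  if (!is.null(start) && !is.null(end) && !is.null(duration) &&
      !is.null(start$normalized) && !is.null(end$normalized) &&
      date_is_complete(start$normalized) && date_is_complete(end$normalized)) {
    implied <- shift_date(start$normalized, duration)
    if (compare_dates(implied, end$normalized) != 0L) {
      abort_invalid_input(sprintf(
        "interval start %s + %s does not reach end %s",
        format(start$normalized), format(duration), format(end$normalized)
      ))
    }
  }
  structure(list(start = start, end = end, duration = duration),
            class = "teo_time_interval")
}

is_time_interval <- function(x) inherits(x, "teo_time_interval")

#' Periodic time interval
#'
#' Models events that repeat, e.g. "Exercise 20 minutes 3 times/day starting
#' from July 21 for 2 weeks": each occurrence lasts `per_occurrence`,
#' repeated `frequency_count` times per `frequency_period`, optionally
#' anchored at `anchor_start` and bounded by a total `span`.
#'
#' @param per_occurrence Optional [duration()] of one occurrence.
#' @param frequency_count Positive integer repetitions per period.
#' @param frequency_period Unit from [granularity_levels()].
#' @param anchor_start Optional [time_instant()].
#' @param span Optional [duration()] covering the whole pattern.
#' @return An object of class `teo_periodic_interval`.
#' @export
periodic_interval <- function(per_occurrence = NULL, frequency_count,
                              frequency_period, anchor_start = NULL, span = NULL) {
  frequency_count <- as.integer(frequency_count)
  if (is.na(frequency_count) || frequency_count < 1L) {
    abort_invalid_input("frequency_count must be a positive integer")
  }
  check_unit(frequency_period)
  if (!is.null(per_occurrence)) stopifnot(is_duration(per_occurrence))
  if (!is.null(anchor_start)) stopifnot(is_time_instant(anchor_start))
  if (!is.null(span)) stopifnot(is_duration(span))
  structure(
    list(per_occurrence = per_occurrence, frequency_count = frequency_count,
         frequency_period = frequency_period, anchor_start = anchor_start,
         span = span),
    class = "teo_periodic_interval"
  )
}

is_periodic_interval <- function(x) inherits(x, "teo_periodic_interval")
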