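# Normalization of narrative time expressions: partial/full dates, duration
# words and abbreviations, and periodic patterns.  Narratives often omit the
# year ("July 6th", "08-08"); the structured record supplies it through a
# NormalizationContext.

#' Context for resolving time expressions
#'
#' Carries the structured-record anchors used to complete partial dates: the
#' year (or full date) of the vaccination field, the date component order
#' (month-day-year, as in US VAERS records) and the two-digit-year pivot.
#'
#' @param anchor_year Optional integer year.
#' @param anchor_date Optional full [partial_date()] (e.g. the structured
#'   "Vaccinated" field); its year is used when `anchor_year` is absent.
#' @param date_order Only `"mdy"` is supported (month-day-year).
#' @param two_digit_year_pivot Two-digit years >= pivot map to 19xx, below
#'   it to 20xx.  Default 30 suits the VAERS era.
#' @return An object of class `normalization_context`.
#' @export
#' @examples
#' normalization_context(anchor_year = 2006)
normalization_context <- function(anchor_year = NULL, anchor_date = NULL,
                                  date_order = "mdy", two_digit_year_pivot = 30L) {
  if (!identical(date_order, "mdy")) {
    abort_invalid_input("only month-day-year date order is supported")
  }
  two_digit_year_pivot <- as.integer(two_digit_year_pivot)
  if (is.na(two_digit_year_pivot) || two_digit_year_pivot < 0L ||
      two_digit_year_pivot > 99L) {
    abort_invalid_input("two_digit_year_pivot must lie in [0, 99]")
  }
  if (!is.null(anchor_date)) {
    stopifnot(is_partial_date(anchor_date))
    if (is.null(anchor_year) && !is.na(anchor_date$year)) {
      anchor_year <- anchor_date$year
    }
  }
  if (!is.null(anchor_year)) anchor_year <- as.integer(anchor_year)
  structure(
    list(anchor_year = anchor_year, anchor_date = anchor_date,
         date_order = date_order, two_digit_year_pivot = two_digit_year_pivot),
    class = "normalization_context"
  )
}

.expand_two_digit_year <- function(yy, ctx) {
  if (yy >= ctx$two_digit_year_pivot) 1900L + yy else 2000L + yy
}

.month_names <- c("january", "february", "march", "april", "may", "june",
                  "july", "august", "september", "october", "november",
                  "december")

.match_month_name <- function(token) {
  token <- tolower(token)
  hits <- which(startsWith(.month_names, token) & nchar(token) >= 3L)
  exact <- which(.month_names == token)
  if (length(exact) == 1L) return(exact)
  if (length(hits) == 1L) return(hits)
  NA_integer_
}

# strip ordinal markers: "6th", "6^th^", "21st" -> "6", "21"
.strip_ordinal <- function(token) {
  sub("(?i)^(\\d+)\\^?(st|nd|rd|th)\\^?$", "\\1", token, perl = TRUE)
}

.number_words <- local({
  units <- c(zero = 0, one = 1, two = 2, three = 3, four = 4, five = 5,
             six = 6, seven = 7, eight = 8, nine = 9, ten = 10,
             eleven = 11, twelve = 12, thirteen = 13, fourteen = 14,
             fifteen = 15, sixteen = 16, seventeen = 17, eighteen = 18,
             nineteen = 19, twenty = 20)
  tens <- c(thirty = 30, forty = 40, fifty = 50, sixty = 60, seventy = 70,
            eighty = 80, ninety = 90)
  c(units, tens)
})

.parse_quantity <- function(token) {
  token <- tolower(token)
  if (grepl("^\\d+(\\.\\d+)?$", token)) return(as.numeric(token))
  if (token %in% c("a", "an", "once")) return(1)
  if (token == "twice") return(2)
  if (!is.na(.number_words[token])) return(unname(.number_words[token]))
  NA_real_
}

.unit_synonyms <- c(
  s = "second", sec = "second", secs = "second", second = "second", seconds = "second",
  min = "minute", mins = "minute", minute = "minute", minutes = "minute",
  h = "hour", hr = "hour", hrs = "hour", hour = "hour", hours = "hour",
  d = "day", day = "day", days = "day",
  wk = "week", wks = "week", week = "week", weeks = "week",
  mo = "month", mos = "month", month = "month", months = "month",
  yr = "year", yrs = "year", year = "year", years = "year"
)

.parse_unit <- function(token) {
  u <- .unit_synonyms[tolower(token)]
  if (is.na(u)) NA_character_ else unname(u)
}

#' Parse a narrative time expression into a time instant
#'
#' Recognizes month-name dates ("July 6th", "July 21", "August 1990"),
#' numeric month-day-year dates ("3-29-90", "3/29/1990"), ISO dates
#' ("1990-03-29", "1990-03", "1990"), and year-less month-day forms
#' ("08-08"), completing the missing year from the context when available.
#' The original expression is preserved verbatim; the granularity equals the
#' precision of the normalized value.
#'
#' @param text The expression as written; non-empty.
#' @param ctx A [normalization_context()].
#' @param ordering_hint Passed to [resolve_partial_date()] when the year
#'   must be completed from the context.
#' @return A [time_instant()].
#' @export
#' @examples
#' parse_time_expression("July 6th", normalization_context(anchor_year = 2006))
#' parse_time_expression("3-29-90", normalization_context())
parse_time_expression <- function(text, ctx = normalization_context(),
                                  ordering_hint = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort_invalid_input("time expression must be a non-empty string")
  }
  stopifnot(inherits(ctx, "normalization_context"))
  orig <- text
  clean <- trimws(gsub(",", " ", text))
  clean <- gsub("\\s+", " ", clean)
  pd <- .parse_date_tokens(clean, ctx)
  inst <- time_instant(orig, pd)
  resolve_partial_date(inst, ctx, ordering_hint = ordering_hint)
}

.parse_date_tokens <- function(clean, ctx) {
  # ISO forms
  if (grepl("^\\d{4}(-\\d{2}){0,2}$", clean) || grepl("^--\\d{2}(-\\d{2})?$", clean)) {
    return(parse_partial_date(clean))
  }
  # numeric m-d-y / m/d/y / m-d
  m <- regmatches(clean, regexec("^(\\d{1,2})[-/](\\d{1,2})([-/](\\d{2,4}))?$", clean))[[1]]
  if (length(m)) {
    mo <- as.integer(m[2]); dy <- as.integer(m[3])
    if (mo > 12L) {
      abort_ambiguity(sprintf("cannot read %s as a month-day-year date", dQuote(clean)))
    }
    if (nzchar(m[5])) {
      yr <- as.integer(m[5])
      if (nchar(m[5]) == 2L) yr <- .expand_two_digit_year(yr, ctx)
      return(partial_date(yr, mo, dy))
    }
    return(partial_date(NA, mo, dy))
  }
  # month-name forms: "July 6th [1990]", "July 1990", "6 July 1990", "July"
  tokens <- strsplit(clean, " ", fixed = TRUE)[[1]]
  tokens <- vapply(tokens, .strip_ordinal, character(1))
  month_idx <- which(!is.na(vapply(tokens, .match_month_name, integer(1))))
  if (length(month_idx) == 1L) {
    mo <- .match_month_name(tokens[month_idx])
    rest <- tokens[-month_idx]
    yr <- NA_integer_; dy <- NA_integer_
    for (tk in rest) {
      if (grepl("^\\d{4}$", tk)) {
        yr <- as.integer(tk)
      } else if (grepl("^\\d{1,2}$", tk)) {
        dy <- as.integer(tk)
      } else {
        abort_parse(sprintf("unrecognized token %s in date expression", dQuote(tk)),
                    token = tk)
      }
    }
    return(partial_date(yr, mo, dy))
  }
  abort_parse(sprintf("cannot parse time expression %s", dQuote(clean)), token = clean)
}

#' Parse a duration expression
#'
#' Accepts digit and word quantities ("18", "Eighteen", "twice") with unit
#' names or their common abbreviations ("days", "wks", "min", "mo", "yr").
#'
#' @param text Non-empty duration expression.
#' @return A [duration()].
#' @export
#' @examples
#' parse_duration_expression("Eighteen days")
#' parse_duration_expression("2 wks")
parse_duration_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort_parse("duration expression must be a non-empty string", token = text)
  }
  clean <- tolower(trimws(gsub("\\s+", " ", text)))
  tokens <- strsplit(clean, " ", fixed = TRUE)[[1]]
  # compact forms like "20min"
  if (length(tokens) == 1L) {
    m <- regmatches(tokens, regexec("^(\\d+(?:\\.\\d+)?)([a-z]+)$", tokens))[[1]]
    if (length(m)) tokens <- c(m[2], m[3])
  }
  qty <- NA_real_; unit <- NA_character_
  for (tk in tokens) {
    if (is.na(qty)) {
      q <- .parse_quantity(tk)
      if (!is.na(q)) { qty <- q; next }
    }
    u <- .parse_unit(tk)
    if (!is.na(u)) unit <- u
  }
  if (is.na(qty)) abort_parse(sprintf("no recognizable quantity in %s", dQuote(text)), token = text)
  if (is.na(unit)) abort_parse(sprintf("no recognizable time unit in %s", dQuote(text)), token = text)
  duration(qty, unit)
}

#' Parse a periodic ("N times per unit") expression
#'
#' Handles the repeating-event pattern: an optional per-occurrence duration,
#' a frequency ("3 times/day", "once a week"), an optional anchor date
#' ("starting from July 21") and an optional overall span ("for 2 weeks").
#'
#' @param text Expression containing a frequency pattern.
#' @param ctx A [normalization_context()] for the anchor date.
#' @return A [periodic_interval()].
#' @export
#' @examples
#' parse_periodic_expression(
#'   "Exercise 20 minutes 3 times/day starting from July 21 for 2 weeks",
#'   normalization_context(anchor_year = 2006)
#' )
parse_periodic_expression <- function(text, ctx = normalization_context()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort_invalid_input("periodic expression must be a non-empty string")
  }
  clean <- gsub("\\s+", " ", trimws(text))
  low <- tolower(clean)

  freq_count <- NA_integer_; freq_period <- NA_character_
  # "N times/unit", "N times per unit", "N times a unit"
  m <- regmatches(low, regexec(
    "(\\d+|[a-z]+) ?times?(?:/| per | a | an )([a-z]+)", low))[[1]]
  if (length(m)) {
    q <- .parse_quantity(m[2]); u <- .parse_unit(m[3])
    if (!is.na(q) && !is.na(u)) { freq_count <- as.integer(q); freq_period <- u }
  }
  if (is.na(freq_count)) {
    # "once a week", "twice per day"
    m <- regmatches(low, regexec("\\b(once|twice)(?:/| per | a | an )([a-z]+)", low))[[1]]
    if (length(m)) {
      q <- .parse_quantity(m[2]); u <- .parse_unit(m[3])
      if (!is.na(u)) { freq_count <- as.integer(q); freq_period <- u }
    }
  }
  if (is.na(freq_count)) {
    abort_not_periodic(sprintf("no frequency pattern in %s", dQuote(text)))
  }

  # per-occurrence duration: quantity+unit before the frequency pattern
  per <- NULL
  pre <- sub("(\\d+|[a-z]+) ?times?.*$", "", low)
  pre <- sub("\\b(once|twice)\\b.*$", "", pre)
  dm <- regmatches(pre, regexec("(\\d+|[a-z]+) (seconds?|minutes?|mins?|hours?|hrs?|days?|weeks?|wks?|months?|years?|yrs?)\\b", pre))[[1]]
  if (length(dm)) {
    q <- .parse_quantity(dm[2]); u <- .parse_unit(dm[3])
    if (!is.na(q) && !is.na(u)) per <- duration(q, u)
  }

  # span: "for <duration>"
  span <- NULL
  sm <- regmatches(low, regexec("\\bfor (\\d+|[a-z]+) ([a-z]+)", low))[[1]]
  if (length(sm)) {
    q <- .parse_quantity(sm[2]); u <- .parse_unit(sm[3])
    if (!is.na(q) && !is.na(u)) span <- duration(q, u)
  }

  # anchor: "starting [from] <date>", "from <date>", "starting <date>"
  anchor <- NULL
  am <- regmatches(clean, regexec(
    "(?i)\\b(?:starting from|starting|beginning|from) ([A-Za-z0-9^/ -]+?)(?= for |$)",
    clean, perl = TRUE))[[1]]
  if (length(am)) {
    anchor <- tryCatch(parse_time_expression(trimws(am[2]), ctx),
                       teo_error = function(cnd) NULL)
  }

  periodic_interval(per_occurrence = per, frequency_count = freq_count,
                    frequency_period = freq_period, anchor_start = anchor,
                    span = span)
}

#' Complete a partial date's year from the structured record
#'
#' Fills a missing year from the context's anchor.  With
#' `ordering_hint = "after_anchor"` a completed date that would fall before
#' the anchor date rolls forward one year (an adverse event reported after a
#' late-December vaccination can carry a January month-day).  Instants that
#' cannot be completed are returned unchanged with their `unresolved` flag
#' set, not an error.
#'
#' @param instant A [time_instant()].
#' @param ctx A [normalization_context()].
#' @param ordering_hint Optional `"after_anchor"` or `"before_anchor"`.
#' @return A [time_instant()] with the same `orig_text` and granularity.
#' @export
resolve_partial_date <- function(instant, ctx = normalization_context(),
                                 ordering_hint = NULL) {
  stopifnot(is_time_instant(instant))
  if (!is.null(ordering_hint)) {
    ordering_hint <- match.arg(ordering_hint, c("after_anchor", "before_anchor"))
  }
  pd <- instant$normalized
  if (is.null(pd) || !is.na(pd$year)) return(instant)
  if (is.null(ctx$anchor_year)) {
    instant$unresolved <- TRUE
    return(instant)
  }
  completed <- partial_date(ctx$anchor_year, pd$month, pd$day)
  if (!is.null(ordering_hint) && !is.null(ctx$anchor_date) &&
      !is.na(ctx$anchor_date$year)) {
    cmp <- compare_dates(completed, ctx$anchor_date)
    if (ordering_hint == "after_anchor" && cmp < 0L) {
      completed <- partial_date(ctx$anchor_year + 1L, pd$month, pd$day)
    } else if (ordering_hint == "before_anchor" && cmp > 0L) {
      completed <- partial_date(ctx$anchor_year - 1L, pd$month, pd$day)
    }
  }
  out <- time_instant(instant$orig_text, completed)
  out
}
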