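test_that("time expressions normalize with context-completed years", {
  ctx06 <- normalization_context(anchor_year = 2006)
  cases <- list(
    list(text = "July 6^th^", ctx = ctx06, norm = "2006-07-06", gran = "day"),
    list(text = "July 6th", ctx = ctx06, norm = "2006-07-06", gran = "day"),
    list(text = "3-29-90", ctx = normalization_context(), norm = "1990-03-29", gran = "day"),
    list(text = "08-08", ctx = ctx06, norm = "2006-08-08", gran = "day"),
    list(text = "1990-03-29", ctx = normalization_context(), norm = "1990-03-29", gran = "day"),
    list(text = "August 1990", ctx = normalization_context(), norm = "1990-08", gran = "month"),
    list(text = "1990", ctx = normalization_context(), norm = "1990", gran = "year"),
    list(text = "July 21", ctx = ctx06, norm = "2006-07-21", gran = "day")
  )
  for (cs in cases) {
    inst <- parse_time_expression(cs$text, cs$ctx)
    expect_equal(inst$orig_text, cs$text)          # verbatim, byte for byte
    expect_equal(format(inst$normalized), cs$norm, label = cs$text)
    expect_equal(inst$granularity, cs$gran, label = cs$text)
    expect_equal(inst$granularity, date_granularity(inst$normalized))
  }
  expect_error(parse_time_expression("blorp"), class = "teo_parse_error")
  expect_error(parse_time_expression(""), class = "teo_invalid_input")
  expect_error(parse_time_expression("29-03-90"), class = "teo_ambiguity")
})

test_that("duration expressions cover words, digits and abbreviations", {
  d <- parse_duration_expression("Eighteen days")
  expect_equal(d$value, 18)
  expect_equal(d$unit, "day")
  expect_equal(parse_duration_expression("2 wks"), duration(2, "week"))
  expect_equal(parse_duration_expression("20 minutes"), duration(20, "minute"))
  expect_equal(parse_duration_expression("1 mo"), duration(1, "month"))
  expect_equal(parse_duration_expression("three yrs"), duration(3, "year"))
  expect_error(parse_duration_expression(""), class = "teo_parse_error")
  expect_error(parse_duration_expression("lots of time"), class = "teo_parse_error")

  # parse . format = identity over the controlled vocabulary
  for (unit in granularity_levels()) {
    for (value in c(1, 2, 18)) {
      d <- duration(value, unit)
      expect_equal(parse_duration_expression(format_duration(d)), d)
    }
  }
})

test_that("periodic expressions decompose into frequency, occurrence and span", {
  p <- parse_periodic_expression(
    "Exercise 20 minutes 3 times/day starting from July 21 for 2 weeks",
    normalization_context(anchor_year = 2006)
  )
  expect_equal(p$frequency_count, 3L)
  expect_equal(p$frequency_period, "day")
  expect_equal(p$per_occurrence, duration(20, "minute"))
  expect_equal(p$span, duration(2, "week"))
  expect_equal(format(p$anchor_start$normalized), "2006-07-21")

  p2 <- parse_periodic_expression("once a week for 1 month")
  expect_equal(p2$frequency_count, 1L)
  expect_equal(p2$frequency_period, "week")
  expect_equal(p2$span, duration(1, "month"))

  expect_error(parse_periodic_expression("fever for 3 days"),
               class = "teo_not_periodic")
})

test_that("partial dates resolve from the anchor, rolling over year ends", {
  ctx <- normalization_context(anchor_year = 2006)
  inst <- resolve_partial_date(parse_time_expression("07-06", normalization_context()), ctx)
  expect_equal(format(inst$normalized), "2006-07-06")
  expect_false(inst$unresolved)

  # already-complete dates pass through unchanged
  full <- parse_time_expression("1990-03-29", normalization_context())
  expect_identical(resolve_partial_date(full, ctx), full)

  # no context year: unchanged, flagged, not an error
  bare <- parse_time_expression("07-06", normalization_context())
  expect_true(bare$unresolved)
  expect_identical(format(resolve_partial_date(bare, normalization_context())$normalized),
                   "--07-06")

  # a January month-day after a December vaccination is next year's January
  decctx <- normalization_context(anchor_date = partial_date(1999, 12, 20))
  jan <- resolve_partial_date(parse_time_expression("01-05", normalization_context()),
                              decctx, ordering_hint = "after_anchor")
  expect_equal(format(jan$normalized), "2000-01-05")

  # completing then truncating to the original precision recovers the input
  p <- partial_date(NA, 7, 6)
  completed <- resolve_partial_date(time_instant("07-06", p), ctx)
  expect_equal(pd_truncate <- format(partial_date(NA, completed$normalized$month,
                                                  completed$normalized$day)),
               format(p))
})

test_that("two-digit years pivot at 30 and calendar arithmetic is exact", {
  expect_equal(format(parse_time_expression("3-29-90")$normalized), "1990-03-29")
  expect_equal(format(parse_time_expression("3-29-05")$normalized), "2005-03-29")

  # day/week arithmetic is calendar arithmetic, not approximation
  expect_equal(format(shift_date(partial_date(2006, 7, 6), duration(18, "day"))),
               "2006-07-24")
  expect_equal(format(shift_date(partial_date(2006, 7, 24), duration(2, "week"))),
               "2006-08-07")
  expect_equal(format(shift_date(partial_date(2000, 2, 28), duration(1, "day"))),
               "2000-02-29")  # leap year
  # month arithmetic clamps to month length
  expect_equal(format(shift_date(partial_date(2001, 1, 31), duration(1, "month"))),
               "2001-02-28")
})
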