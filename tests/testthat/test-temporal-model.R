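test_that("events are created with verbatim labels and fresh ids", {
  g <- temporal_graph()
  e1 <- add_event(g, "vaccinated w/MMR")
  expect_equal(e1$label, "vaccinated w/MMR")
  expect_null(e1$time)
  expect_equal(n_events(g), 1L)

  e2 <- add_event(g, "BRIEF GENERALIZED SEIZURE")
  expect_equal(n_events(g), 2L)
  expect_false(e1$id == e2$id)

  expect_error(add_event(g, ""), class = "teo_invalid_input")
  expect_error(add_event(g, "   "), class = "teo_invalid_input")
  expect_equal(n_events(g), 2L)
})

test_that("time attachment is single-assignment and checks the event", {
  g <- temporal_graph()
  e1 <- add_event(g, "vaccinated w/MMR")
  inst <- time_instant("July 6^th^", partial_date(2006, 7, 6))
  attach_time(g, e1$id, inst)
  stored <- get_event(g, e1$id)$time
  expect_equal(stored$orig_text, "July 6^th^")
  expect_equal(format(stored$normalized), "2006-07-06")
  expect_equal(stored$granularity, "day")

  expect_error(attach_time(g, e1$id, inst), class = "teo_conflict")
  expect_error(attach_time(g, "nope", inst), class = "teo_not_found")
})

test_that("relation assertion validates endpoints, strictness and offsets", {
  g <- temporal_graph()
  v <- add_event(g, "vaccination")
  f <- add_event(g, "she developed a fever")
  a <- assert_relation(g, f$id, "after", v$id, offset = duration(18, "day"))
  expect_equal(a$offset$value, 18)
  expect_equal(a$offset$unit, "day")
  expect_equal(a$provenance, "stated")

  s <- add_event(g, "BRIEF GENERALIZED SEIZURE")
  d <- add_event(g, "DTP")
  a2 <- assert_relation(g, s$id, "after", d$id)
  expect_null(a2$offset)

  expect_error(assert_relation(g, v$id, "before", v$id), class = "teo_invalid_input")
  expect_error(assert_relation(g, f$id, "during", v$id, offset = duration(1, "day")),
               class = "teo_invalid_input")
  expect_error(assert_relation(g, f$id, "after", "ghost"), class = "teo_not_found")
})

test_that("adding entities never mutates previously stored ones", {
  g <- temporal_graph()
  e1 <- add_event(g, "fever")
  snap_e1 <- get_event(g, e1$id)
  e2 <- add_event(g, "rash")
  assert_relation(g, e2$id, "after", e1$id)
  snap_a <- g$assertions[[1]]
  add_event(g, "vasculitis")
  assert_relation(g, e1$id, "before", e2$id)
  expect_identical(get_event(g, e1$id), snap_e1)
  expect_identical(g$assertions[[1]], snap_a)
})

test_that("graph validation reports contradictions and dangling references", {
  g <- temporal_graph()
  e1 <- add_event(g, "a")
  e2 <- add_event(g, "b")
  assert_relation(g, e1$id, "before", e2$id)
  assert_relation(g, e2$id, "before", e1$id)
  v <- validate_graph(g)
  expect_false(v$consistent)
  expect_gte(length(v$conflicts), 1L)
  expect_equal(g$consistency_status, "inconsistent")

  # an empty graph is vacuously consistent
  expect_true(validate_graph(temporal_graph())$consistent)

  # contradictory duplicate stated pair is rejected at assertion time
  g2 <- temporal_graph()
  a <- add_event(g2, "a"); b <- add_event(g2, "b")
  assert_relation(g2, a$id, "before", b$id)
  expect_error(assert_relation(g2, a$id, "during", b$id), class = "teo_conflict")

  # dangling reference (forged assertion) is a structural error
  g3 <- temporal_graph()
  x <- add_event(g3, "x")
  assert_relation(g3, x$id, "equals", x$id)
  g3$assertions[[1]]$target <- "ghost"
  expect_error(validate_graph(g3), class = "teo_structural_error")
})

test_that("the worked MMR case is a consistent five-event graph", {
  g <- mmr_case_graph()
  expect_equal(n_events(g), 5L)
  stated <- Filter(function(a) a$provenance == "stated", g$assertions)
  expect_gte(length(stated), 4L)
  v <- validate_graph(g)
  expect_true(v$consistent)
  expect_equal(n_events(g), 5L)  # validation does not add or drop events
})
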