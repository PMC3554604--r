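test_that("the worked case yields the expected vaccination-anchored timeline", {
  g <- mmr_case_graph()
  infer_dates(g)
  tl <- build_timeline(g, report_id = "MMR")
  expect_equal(tl$anchor, "event1")
  expect_equal(tl$entries$event_id,
               c("event1", "event2", "event3", "event4", "event5"))
  expect_equal(tl$entries$day_offset, c(0L, 18L, 18L, 32L, 33L))
  expect_equal(day_offset(tl, "event2"), 18L)
  expect_equal(day_offset(tl, "event1"), 0L)
  expect_equal(day_offset(tl, "event4"), 32L)
  expect_error(day_offset(tl, "ghost"), class = "teo_not_found")
})

test_that("degenerate graphs build degenerate timelines", {
  g <- temporal_graph()
  v <- add_event(g, "vaccinated w/MMR")
  attach_time(g, v$id, time_instant("July 6", partial_date(2006, 7, 6)))
  annotate_events(g)
  tl <- build_timeline(g)
  expect_equal(nrow(tl$entries), 1L)
  expect_equal(tl$entries$day_offset, 0L)

  # unresolvable extra event appears flagged, resolved order unchanged
  x <- add_event(g, "xyzzy")
  assert_relation(g, x$id, "after", v$id)
  tl2 <- build_timeline(g)
  expect_equal(tl2$entries$event_id, c(v$id, x$id))
  expect_false(tl2$entries$resolved[2])
  expect_true(is.na(tl2$entries$day_offset[2]))

  # no vaccine annotation and no hint: anchor selection fails
  g2 <- temporal_graph()
  add_event(g2, "fever")
  expect_error(build_timeline(g2), class = "teo_anchor_error")
  # ... but a hint rescues it
  tl3 <- build_timeline(g2, anchor_label_hint = "fever")
  expect_equal(nrow(tl3$entries), 1L)
})

test_that("timeline order is a linear extension of the propagated partial order", {
  g <- mmr_case_graph()
  infer_dates(g)
  tl <- build_timeline(g)
  net <- propagate_constraints(constraint_network(g))
  pos <- match(tl$entries$event_id, tl$entries$event_id)
  names(pos) <- tl$entries$event_id
  for (i in net$ids) for (j in net$ids) {
    if (i == j) next
    s <- allen_relations()[net$edges[match(i, net$ids), match(j, net$ids), ]]
    if (length(s) && all(s %in% c("before", "meets"))) {
      expect_lt(match(i, tl$entries$event_id), match(j, tl$entries$event_id))
    }
  }
})

test_that("the cohort comparison recovers the three planted patterns", {
  tls <- lapply(interpretation_cohort(), report_timeline)
  comp <- compare_timelines(tls)

  # (i) shared symptom at different day offsets: rash day 3 vs day 8
  rash <- comp$shared_symptom_offsets[
    comp$shared_symptom_offsets$term == "rash AE", ]
  expect_equal(rash$report_id, c("HEP-1", "HEP-2"))
  expect_equal(rash$day_offset, c(3L, 8L))

  # (ii) frequencies: nausea twice, once, never
  expect_equal(unname(comp$frequency_table["nausea AE", ]),
               c(2L, 1L, 0L))
  # frequencies sum to the number of annotated adverse events per report
  expect_equal(unname(colSums(comp$frequency_table)), c(6L, 5L, 2L))

  # (iii) order reversal: injection site reaction before arthralgia in the
  # first report, the opposite in the second
  rev <- Filter(function(d) {
    setequal(c(d$term_a, d$term_b), c("injection site reaction AE", "arthralgia AE"))
  }, comp$order_differences)
  expect_length(rev, 1L)
  d <- rev[[1]]
  isr_first <- if (d$term_a == "injection site reaction AE") d$a_first else d$b_first
  art_first <- if (d$term_a == "injection site reaction AE") d$b_first else d$a_first
  expect_equal(isr_first, "HEP-1")
  expect_equal(art_first, "HEP-2")
})

test_that("comparison is invariant under input permutation", {
  tls <- lapply(interpretation_cohort(), report_timeline)
  c1 <- compare_timelines(tls)
  c2 <- compare_timelines(rev(tls))
  expect_equal(c1$frequency_table[, sort(colnames(c1$frequency_table))],
               c2$frequency_table[, sort(colnames(c2$frequency_table))])
  norm_shared <- function(x) {
    s <- x$shared_symptom_offsets
    s[order(s$term_key, s$report_id, s$day_offset), ]
  }
  expect_equal(norm_shared(c1), norm_shared(c2), ignore_attr = TRUE)
  key <- function(d) paste(sort(c(d$term_key_a, d$term_key_b)), collapse = "|")
  expect_setequal(vapply(c1$order_differences, key, character(1)),
                  vapply(c2$order_differences, key, character(1)))
})

test_that("unannotated timelines are rejected with advice to annotate", {
  g <- temporal_graph()
  v <- add_event(g, "vaccinated w/MMR")
  attach_time(g, v$id, time_instant("July 6", partial_date(2006, 7, 6)))
  x <- add_event(g, "xyzzy")
  attach_time(g, x$id, time_instant("July 9", partial_date(2006, 7, 9)))
  annotate_events(g)
  tl <- build_timeline(g, report_id = "R1")
  expect_error(compare_timelines(list(tl)), class = "teo_annotation_error")
})

test_that("event sequences export as flat report/term/day tables", {
  g <- mmr_case_graph()
  infer_dates(g)
  tl <- build_timeline(g, report_id = "MMR")
  path <- tempfile(fileext = ".tsv")
  export_event_sequences(tl, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab), c("report_id", "term", "day_offset"))
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$day_offset, c(0L, 18L, 18L, 32L, 33L))
})
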