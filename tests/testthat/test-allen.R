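test_that("relation inversion pairs endpoints correctly", {
  expect_equal(invert_relation("before"), "after")
  expect_equal(invert_relation("meets"), "met_by")
  expect_equal(invert_relation("equals"), "equals")
  for (r in allen_relations()) {
    expect_equal(invert_relation(invert_relation(r)), r)
  }
  expect_error(invert_relation("sideways"), class = "teo_invalid_input")
})

test_that("composition has the identity element and known cells", {
  expect_equal(compose_relations("before", "before"), "before")
  expect_equal(compose_relations("equals", "during"), "during")
  for (r in allen_relations()) {
    expect_equal(compose_relations("equals", r), r)
    expect_equal(compose_relations(r, "equals"), r)
  }
})

test_that("composition respects the inversion symmetry", {
  # compose(inv(r2), inv(r1)) = inverses of compose(r1, r2), all 169 pairs
  for (r1 in allen_relations()) for (r2 in allen_relations()) {
    lhs <- sort(compose_relations(invert_relation(r2), invert_relation(r1)))
    rhs <- sort(unname(vapply(compose_relations(r1, r2), invert_relation,
                              character(1))))
    expect_equal(lhs, rhs)
  }
})

test_that("propagation derives the narrative's unstated ordering", {
  g <- temporal_graph()
  v <- add_event(g, "vaccination")
  f <- add_event(g, "fever")
  x <- add_event(g, "vasculitis")
  h <- add_event(g, "patient hospitalization")
  assert_relation(g, v$id, "before", f$id)
  assert_relation(g, f$id, "before", x$id)
  assert_relation(g, x$id, "before", h$id)
  net <- propagate_constraints(constraint_network(g))
  i <- match(v$id, net$ids); j <- match(h$id, net$ids)
  expect_equal(allen_relations()[net$edges[i, j, ]], "before")
})

test_that("propagation flags a direct cycle as inconsistent", {
  g <- temporal_graph()
  a <- add_event(g, "a"); b <- add_event(g, "b"); c <- add_event(g, "c")
  assert_relation(g, a$id, "before", b$id)
  assert_relation(g, b$id, "before", c$id)
  assert_relation(g, c$id, "before", a$id)
  err <- tryCatch(propagate_constraints(constraint_network(g)),
                  teo_inconsistency = function(cnd) cnd)
  expect_s3_class(err, "teo_inconsistency")
  expect_length(err$triangle, 3L)
})

test_that("propagation is monotone and idempotent", {
  set.seed(7)
  for (rep in 1:10) {
    rels <- random_scenario_network(4L)
    gi <- graph_from_network(rels)
    net0 <- constraint_network(gi$graph)
    net1 <- propagate_constraints(net0)
    expect_true(all(net1$edges <= net0$edges))        # subset of the input
    net2 <- propagate_constraints(net1)
    expect_identical(net2$edges, net1$edges)          # fixpoint
  }
})

test_that("path-consistency verdicts agree with concrete realizations", {
  set.seed(11)
  for (rep in 1:20) {
    rels <- random_scenario_network(5L)
    # scenario networks are realizable and PC leaves them atomic
    ends <- oracle_realize(rels)
    expect_false(is.null(ends))
    net <- pc_closure(rels)
    expect_false(is.null(net))
    for (i in 1:5) for (j in 1:5) {
      expect_equal(allen_relations()[net$edges[i, j, ]],
                   if (i == j) "equals" else rels[i, j])
    }
    # perturb one edge: verdicts must still agree with the oracle
    i <- sample(4, 1); j <- sample((i + 1):5, 1)
    rels2 <- rels
    rels2[i, j] <- sample(setdiff(allen_relations(), rels[i, j]), 1)
    rels2[j, i] <- invert_relation(rels2[i, j])
    expect_equal(is.null(pc_closure(rels2)), is.null(oracle_realize(rels2)))
  }
})

test_that("date inference accumulates calendar offsets along chains", {
  g <- mmr_case_graph()
  infer_dates(g)
  expect_equal(format(get_event(g, "event2")$time$normalized), "2006-07-24")
  expect_equal(format(get_event(g, "event3")$time$normalized), "2006-07-24")
  expect_equal(format(get_event(g, "event4")$time$normalized), "2006-08-07")
  expect_true(isTRUE(get_event(g, "event4")$time$inferred))
  # chains equal the single summed offset (associativity)
  expect_equal(
    format(shift_date(shift_date(partial_date(2006, 7, 6), duration(18, "day")),
                      duration(2, "week"))),
    format(shift_date(partial_date(2006, 7, 6), duration(32, "day")))
  )
  # a month-unit offset coarsens the inferred date to month granularity
  gm <- temporal_graph()
  a <- add_event(gm, "vaccination")
  b <- add_event(gm, "follow-up visit")
  attach_time(gm, a$id, time_instant("July 6", partial_date(2006, 7, 6)))
  assert_relation(gm, b$id, "after", a$id, offset = duration(1, "month"))
  infer_dates(gm)
  expect_equal(format(get_event(gm, b$id)$time$normalized), "2006-08")
  expect_equal(get_event(gm, b$id)$time$granularity, "month")
  # no anchor, no inference
  g2 <- temporal_graph()
  a <- add_event(g2, "a"); b <- add_event(g2, "b")
  assert_relation(g2, b$id, "after", a$id, offset = duration(3, "day"))
  infer_dates(g2)
  expect_null(get_event(g2, a$id)$time)
  expect_null(get_event(g2, b$id)$time)
})

test_that("conflicting chains surface both derivations", {
  g <- temporal_graph()
  a <- add_event(g, "vaccination")
  b <- add_event(g, "fever")
  attach_time(g, a$id, time_instant("d0", partial_date(2006, 7, 6)))
  attach_time(g, b$id, time_instant("d1", partial_date(2006, 7, 10)))
  assert_relation(g, b$id, "after", a$id, offset = duration(18, "day"))
  expect_error(infer_dates(g), class = "teo_conflict")
})

test_that("derived relations combine dates with qualitative constraints", {
  g <- mmr_case_graph()
  infer_dates(g)
  expect_equal(derive_relation(g, "event4", "event5"), "before")   # vasculitis < hosp
  expect_equal(derive_relation(g, "event5", "event4"), "after")
  expect_equal(derive_relation(g, "event2", "event2"), "equals")
  # same inferred day: order not determined at day granularity
  expect_setequal(derive_relation(g, "event2", "event3"),
                  c("before", "equals", "after"))
  # two unanchored events linked only through a third: propagated disjunction
  g2 <- temporal_graph()
  a <- add_event(g2, "a"); b <- add_event(g2, "b"); c <- add_event(g2, "c")
  assert_relation(g2, a$id, "before", b$id)
  assert_relation(g2, b$id, "during", c$id)
  got <- derive_relation(g2, a$id, c$id)
  expect_setequal(got, compose_relations("before", "during"))
})
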