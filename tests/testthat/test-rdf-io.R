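test_that("a dated event serializes with the seven-triple pattern", {
  g <- temporal_graph()
  e <- add_event(g, "vaccinated w/MMR ")
  attach_time(g, e$id, time_instant("July 6^th^", partial_date(2006, 7, 6)))
  ttl <- write_graph(g)
  expect_match(ttl, "a teo:Event", fixed = TRUE)
  expect_match(ttl, 'rdfs:label "vaccinated w/MMR "', fixed = TRUE)
  expect_match(ttl, "teo:hasTime :time_event1", fixed = TRUE)
  expect_match(ttl, "a teo:TimeInstant", fixed = TRUE)
  expect_match(ttl, 'teo:hasOrigTime "July 6\\^th\\^"')
  expect_match(ttl, 'teo:hasNormalizedTime "2006-07-06"\\^\\^xsd:date')
  expect_match(ttl, 'teo:hasGranularity "day"', fixed = TRUE)
})

test_that("offset assertions serialize as annotated axioms", {
  g <- temporal_graph()
  v <- add_event(g, "vaccination")
  f <- add_event(g, "she developed a fever")
  assert_relation(g, f$id, "after", v$id, offset = duration(18, "day"))
  ttl <- write_graph(g)
  expect_match(ttl, sprintf(":%s teo:after :%s .", f$id, v$id), fixed = TRUE)
  expect_match(ttl, "a owl:Axiom", fixed = TRUE)
  expect_match(ttl, sprintf("owl:annotatedSource :%s", f$id), fixed = TRUE)
  expect_match(ttl, "owl:annotatedProperty teo:after", fixed = TRUE)
  expect_match(ttl, sprintf("owl:annotatedTarget :%s", v$id), fixed = TRUE)
  expect_match(ttl, "teo:hasTimeOffset :durat_", fixed = TRUE)
  expect_match(ttl, 'teo:hasValue "18"', fixed = TRUE)
  expect_match(ttl, 'teo:hasUnit "day"', fixed = TRUE)
})

test_that("an empty graph is still a valid prefix-only document", {
  ttl <- write_graph(temporal_graph())
  expect_match(ttl, "@prefix teo:", fixed = TRUE)
  g <- read_graph(ttl)
  expect_equal(n_events(g), 0L)
  expect_error(write_graph(temporal_graph(), base_namespace = "not a namespace"),
               class = "teo_invalid_input")
})

test_that("fixtures and reasoned graphs round-trip structurally and byte-stably", {
  for (g in list(mmr_case_graph(),
                 { h <- mmr_case_graph(); infer_dates(h); h },
                 graph_from_report(read_report(teo_example("engerix_case_synthetic.json"))))) {
    ttl <- write_graph(g)
    g2 <- read_graph(ttl)
    expect_true(graph_identical(g, g2))
    expect_identical(write_graph(g2), ttl)
  }
})

test_that("random graphs round-trip, offsets intact", {
  set.seed(123)
  for (rep in 1:25) {
    g <- random_graph()
    ttl <- write_graph(g)
    g2 <- read_graph(ttl)
    expect_true(graph_identical(g, g2))
    expect_identical(write_graph(g2), ttl)
    n_off <- sum(vapply(g$assertions, function(a) !is.null(a$offset), logical(1)))
    n_ax <- length(gregexpr("a owl:Axiom", ttl, fixed = TRUE)[[1]])
    expect_gte(n_ax, n_off)  # every offset-bearing assertion has its axiom node
  }
})

test_that("malformed Turtle fails with parse or structural errors", {
  g <- mmr_case_graph()
  ttl <- write_graph(g)
  truncated <- substr(ttl, 1, nchar(ttl) - 40)
  expect_error(read_graph(truncated), class = "teo_parse_error")
  expect_error(read_graph("@prefix broken"), class = "teo_parse_error")
  # axiom node without annotatedTarget
  doc <- paste(
    "@prefix teo: <http://example.org/teo#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix : <http://example.org/report#> .",
    ':e1 a teo:Event ; rdfs:label "a" .',
    ":ax a owl:Axiom ; owl:annotatedSource :e1 .",
    sep = "\n")
  expect_error(read_graph(doc), class = "teo_structural_error")
})

test_that("the canonical output parses with an independent RDF library", {
  g <- mmr_case_graph()
  infer_dates(g)
  ttl_path <- tempfile(fileext = ".ttl")
  writeLines(write_graph(g), ttl_path)
  out <- system2(
    "python",
    c("-c", shQuote(paste0(
      "import rdflib; g = rdflib.Graph(); g.parse('", ttl_path,
      "', format='turtle'); print(len(g))"
    ))),
    stdout = TRUE, stderr = TRUE
  )
  n_external <- suppressWarnings(as.integer(utils::tail(out, 1)))
  expect_false(is.na(n_external))
  # our own restricted parser must see exactly the same number of triples
  triples <- teotimer:::.parse_turtle(write_graph(g))
  expect_equal(n_external, length(triples))
})

test_that("report records parse their structured block and keep annotations in order", {
  rec <- read_report(teo_example("engerix_case_synthetic.json"))
  expect_equal(rec$report_id, "25319")
  expect_equal(format(rec$structured_dates$onset), "1990-03-29")
  expect_equal(rec$vaccines, "ENGERIX-B")
  spans <- vapply(rec$narrative_annotations, `[[`, character(1), "span")
  expect_equal(spans[1:2], c("1ST ENGERIX-B DOSE", "3-29-90"))

  g <- graph_from_report(rec)
  dose <- get_event(g, event_ids(g)[1])
  expect_equal(dose$label, "1ST ENGERIX-B DOSE")
  expect_equal(format(dose$time$normalized), "1990-03-29")
  vo <- Filter(function(t) t$vocabulary == "VO", dose$annotations)
  expect_equal(vo[[1]]$identifier, "VO_0010711")

  # missing onset is fine; missing report_id is not
  ok <- read_report('{"report_id": "X1", "structured_dates": {"vaccinated": "2001-02-03"}}')
  expect_null(ok$structured_dates$onset)
  expect_error(read_report('{"sex": "F"}'), class = "teo_structural_error")
  # unknown vaccine codes are preserved and flagged, unknown fields warned
  expect_warning(
    rec2 <- read_report('{"report_id": "X2", "vaccines": ["ZZZVAX"], "oddball": 1}'),
    "oddball"
  )
  expect_equal(rec2$vaccines, "ZZZVAX")
  expect_true(rec2$vaccine_unmapped)
})
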