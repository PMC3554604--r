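test_that("surface forms normalize to one canonical label", {
  expect_equal(normalize_label("FLU-LIKE SYMPTOMS"), "influenza like illness")
  expect_equal(normalize_label("Influenza-like illness"), "influenza like illness")
  expect_equal(normalize_label("flu-like illness"), "influenza like illness")
  expect_equal(normalize_label("influenza like illness"), "influenza like illness")
  # unknown forms pass through folded, not dropped
  expect_equal(normalize_label("Xyzzy-Blorp!"), "xyzzy blorp")
  expect_error(normalize_label(""), class = "teo_invalid_input")
})

test_that("normalization is idempotent over the whole lexicon", {
  lex <- default_lexicon()
  for (s in unique(lex$table$surface)) {
    once <- normalize_label(s, lex)
    expect_equal(normalize_label(once, lex), once, label = s)
  }
})

test_that("terms printed for the worked cases resolve to their identifiers", {
  t1 <- lookup_term("influenza like illness", "MedDRA")
  expect_s3_class(t1, "term_ref")
  expect_equal(t1$identifier, "10022004")
  t2 <- lookup_term("influenza like illness AE", "OAE")
  expect_equal(t2$identifier, "OAE_0000100")
  t3 <- lookup_term("Engerix-B", "VO")
  expect_equal(t3$identifier, "VO_0010711")

  expect_s3_class(lookup_term("xyzzy", "OAE"), "unmapped_term")
  expect_equal(lookup_term("xyzzy", "OAE")$label, "xyzzy")
  expect_error(lookup_term("rash", "SNOMED"), class = "teo_invalid_input")
})

test_that("every synonym of a concept maps to the same term", {
  lex <- default_lexicon()
  tab <- lex$table
  for (key in unique(paste(tab$vocabulary, tab$identifier))) {
    rows <- tab[paste(tab$vocabulary, tab$identifier) == key, ]
    hits <- lapply(rows$surface, lookup_term, vocabulary = rows$vocabulary[1],
                   lexicon = lex)
    ids <- vapply(hits, function(t) t$identifier, character(1))
    expect_equal(unique(ids), rows$identifier[1], label = key)
  }
})

test_that("term_ref enforces each vocabulary's id pattern", {
  expect_error(term_ref("OAE", "12345", "x"), class = "teo_invalid_input")
  expect_error(term_ref("MedDRA", "OAE_0000100", "x"), class = "teo_invalid_input")
  expect_error(term_ref("GO", "GO_0000001", "x"), class = "teo_invalid_input")
  expect_silent(term_ref("VO", "VO_0010711", "Engerix-B"))
})

test_that("annotating a graph attaches terms without touching events", {
  g <- mmr_case_graph(annotate = FALSE)
  labels <- vapply(event_ids(g), function(id) get_event(g, id)$label, character(1))
  annotate_events(g)
  expect_equal(n_events(g), 5L)
  expect_equal(vapply(event_ids(g), function(id) get_event(g, id)$label, character(1)),
               labels)
  vocabs <- lapply(event_ids(g), function(id) {
    vapply(get_event(g, id)$annotations, function(t) t$vocabulary, character(1))
  })
  names(vocabs) <- event_ids(g)
  expect_true("VO" %in% vocabs$event1)               # vaccination
  for (id in c("event2", "event3", "event4", "event5")) {
    expect_true("OAE" %in% vocabs[[id]], label = id) # symptoms / outcome
  }

  g2 <- temporal_graph()
  x <- add_event(g2, "xyzzy")
  n <- add_event(g2, "nausea")
  annotate_events(g2)
  expect_true(get_event(g2, x$id)$unmapped)
  expect_equal(get_event(g2, x$id)$label, "xyzzy")
  oae <- Filter(function(t) t$vocabulary == "OAE", get_event(g2, n$id)$annotations)
  expect_equal(oae[[1]]$preferred_label, "nausea AE")
  # both codings kept when OAE and MedDRA both match
  expect_setequal(
    vapply(get_event(g2, n$id)$annotations, function(t) t$vocabulary, character(1)),
    c("OAE", "MedDRA")
  )
})
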