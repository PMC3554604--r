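# Turtle serialization of temporal graphs and parsing of semi-structured
# report files.
#
# The serialization follows the triple vocabulary used for clinical
# temporal annotation: events are typed teo:Event with rdfs:label; a time
# stamp hangs off teo:hasTime as a teo:TimeInstant carrying hasOrigTime /
# hasNormalizedTime / hasGranularity; durations carry hasValue / hasUnit;
# a quantified relation ("fever 18 days after vaccination") adds the OWL
# annotated-axiom block (owl:Axiom + annotatedSource / annotatedProperty /
# annotatedTarget + teo:hasTimeOffset).  Output is deterministic: nodes are
# written in narrative order with skolem IRIs, never blank nodes, so
# write -> read -> write is byte-identical.

.NS <- list(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  teo  = "http://example.org/teo#"
)

.local_name <- function(iri) {
  if (grepl("#", iri, fixed = TRUE)) return(sub("^.*#", "", iri))
  sub("^.*/", "", iri)
}

.esc_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

.check_node_id <- function(id) {
  if (!grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", id)) {
    abort_invalid_input(sprintf(
      "id %s cannot be used as an IRI local name; use letters, digits, _ . -",
      dQuote(id)
    ))
  }
  id
}

# normalized partial date -> (lexical form, xsd datatype or NULL)
.pd_literal <- function(pd) {
  if (is.na(pd$year)) return(list(text = format(pd), dt = NULL))
  switch(date_granularity(pd),
    day   = list(text = format(pd), dt = "xsd:date"),
    month = list(text = format(pd), dt = "xsd:gYearMonth"),
    year  = list(text = format(pd), dt = "xsd:gYear")
  )
}

.lit <- function(value, dt = NULL) {
  out <- sprintf('"%s"', .esc_literal(value))
  if (!is.null(dt)) out <- paste0(out, "^^", dt)
  out
}

#' Serialize a temporal graph to Turtle
#'
#' @param graph A [temporal_graph()].
#' @param base_namespace Absolute IRI (ending in `#` or `/`) under which the
#'   graph's individuals are minted; the ontology vocabulary itself uses a
#'   fixed placeholder namespace.
#' @return A single string: a valid Turtle document.
#' @export
#' @examples
#' g <- temporal_graph()
#' e <- add_event(g, "vaccinated w/MMR")
#' attach_time(g, e$id, time_instant("July 6th", partial_date(2006, 7, 6)))
#' cat(write_graph(g))
write_graph <- function(graph, base_namespace = "http://example.org/report#") {
  stopifnot(is_temporal_graph(graph))
  if (!is.character(base_namespace) || length(base_namespace) != 1L ||
      !grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^ ]+[#/]$", base_namespace)) {
    abort_invalid_input("base_namespace must be an absolute IRI ending in '#' or '/'")
  }
  out <- c(
    sprintf("@prefix rdf: <%s> .", .NS$rdf),
    sprintf("@prefix rdfs: <%s> .", .NS$rdfs),
    sprintf("@prefix owl: <%s> .", .NS$owl),
    sprintf("@prefix xsd: <%s> .", .NS$xsd),
    sprintf("@prefix teo: <%s> .", .NS$teo),
    sprintf("@prefix : <%s> .", base_namespace),
    ""
  )
  emit_block <- function(subject, lines) {
    body <- paste0(subject, " ", lines[1])
    if (length(lines) > 1L) {
      body <- c(paste0(body, " ;"),
                paste0("    ", lines[-1], c(rep(" ;", length(lines) - 2L), " .")))
    } else {
      body <- paste0(body, " .")
    }
    out <<- c(out, body, "")
  }
  emit_instant <- function(node, inst) {
    lines <- "a teo:TimeInstant"
    if (!is.na(inst$orig_text)) {
      lines <- c(lines, sprintf("teo:hasOrigTime %s", .lit(inst$orig_text)))
    }
    if (!is.null(inst$normalized)) {
      pl <- .pd_literal(inst$normalized)
      lines <- c(lines, sprintf("teo:hasNormalizedTime %s", .lit(pl$text, pl$dt)))
    }
    if (!is.null(inst$granularity)) {
      lines <- c(lines, sprintf("teo:hasGranularity %s", .lit(inst$granularity)))
    }
    if (isTRUE(inst$unresolved)) lines <- c(lines, 'teo:unresolved "true"')
    if (isTRUE(inst$inferred)) lines <- c(lines, 'teo:inferred "true"')
    emit_block(paste0(":", node), lines)
  }
  emit_duration <- function(node, dur) {
    emit_block(paste0(":", node), c(
      "a teo:Duration",
      sprintf("teo:hasValue %s", .lit(format(dur$value))),
      sprintf("teo:hasUnit %s", .lit(dur$unit))
    ))
  }

  for (id in graph$order) {
    .check_node_id(id)
    ev <- graph$events[[id]]
    lines <- c("a teo:Event", sprintf("rdfs:label %s", .lit(ev$label)))
    time_node <- NULL
    if (!is.null(ev$time)) {
      time_node <- paste0("time_", id)
      lines <- c(lines, sprintf("teo:hasTime :%s", time_node))
    }
    if (length(ev$annotations)) {
      refs <- vapply(ev$annotations, function(t) {
        sprintf(":ann_%s_%s_%s", id, t$vocabulary, t$identifier)
      }, character(1))
      lines <- c(lines, sprintf("teo:hasAnnotation %s", paste(refs, collapse = " , ")))
    }
    if (isTRUE(ev$unmapped)) lines <- c(lines, 'teo:unmapped "true"')
    if (!is.null(ev$extra$derivation)) {
      lines <- c(lines, sprintf("teo:derivation %s", .lit(ev$extra$derivation)))
    }
    for (x in ev$extra[setdiff(names(ev$extra), "derivation")]) {
      obj <- if (isTRUE(x$is_iri)) sprintf("<%s>", x$value) else .lit(x$value, x$datatype)
      lines <- c(lines, sprintf("<%s> %s", x$predicate, obj))
    }
    emit_block(paste0(":", id), lines)

    if (!is.null(ev$time)) {
      if (is_time_instant(ev$time)) {
        emit_instant(time_node, ev$time)
      } else {
        iv <- ev$time
        lines <- "a teo:TimeInterval"
        if (!is.null(iv$start)) lines <- c(lines, sprintf("teo:hasStartTime :%s_start", time_node))
        if (!is.null(iv$end)) lines <- c(lines, sprintf("teo:hasEndTime :%s_end", time_node))
        if (!is.null(iv$duration)) lines <- c(lines, sprintf("teo:hasDuration :durat_%s", time_node))
        emit_block(paste0(":", time_node), lines)
        if (!is.null(iv$start)) emit_instant(paste0(time_node, "_start"), iv$start)
        if (!is.null(iv$end)) emit_instant(paste0(time_node, "_end"), iv$end)
        if (!is.null(iv$duration)) emit_duration(paste0("durat_", time_node), iv$duration)
      }
    }
    for (t in ev$annotations) {
      emit_block(sprintf(":ann_%s_%s_%s", id, t$vocabulary, t$identifier), c(
        "a teo:TermRef",
        sprintf("teo:vocabulary %s", .lit(t$vocabulary)),
        sprintf("teo:identifier %s", .lit(t$identifier)),
        sprintf("teo:preferredLabel %s", .lit(t$preferred_label))
      ))
    }
  }

  seen_ax <- character()
  for (a in graph$assertions) {
    out <- c(out, sprintf(":%s teo:%s :%s .", a$source, a$relation, a$target), "")
    if (!is.null(a$offset) || a$provenance != "stated") {
      ax <- sprintf("ax_%s_%s_%s", a$source, a$relation, a$target)
      while (ax %in% seen_ax) ax <- paste0(ax, "_x")
      seen_ax <- c(seen_ax, ax)
      lines <- c(
        "a owl:Axiom",
        sprintf("owl:annotatedSource :%s", a$source),
        sprintf("owl:annotatedProperty teo:%s", a$relation),
        sprintf("owl:annotatedTarget :%s", a$target)
      )
      if (!is.null(a$offset)) {
        lines <- c(lines, sprintf("teo:hasTimeOffset :durat_%s", ax))
      }
      lines <- c(lines, sprintf("teo:provenance %s", .lit(a$provenance)))
      emit_block(paste0(":", ax), lines)
      if (!is.null(a$offset)) emit_duration(paste0("durat_", ax), a$offset)
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---------------------------------------------------------------------------
# Turtle tokenizer / parser (restricted Turtle 1.1 subset: prefixed names,
# IRIs, string literals with ^^ datatypes, ';' and ',' continuations)

.tokenize_turtle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  line <- 1L
  tokens <- vector("list", 0L)
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, line = line)
  }
  while (i <= n) {
    c0 <- chars[i]
    if (c0 == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (c0 %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (c0 == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (c0 == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") {
        if (chars[j] == "\n") abort_parse(sprintf("unterminated IRI at line %d", line), line = line)
        j <- j + 1L
      }
      if (j > n) abort_parse(sprintf("unterminated IRI at line %d", line), line = line)
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
      next
    }
    if (c0 == "\"") {
      j <- i + 1L
      buf <- character()
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\") {
          if (j + 1L > n) abort_parse(sprintf("dangling escape at line %d", line), line = line)
          esc <- chars[j + 1L]
          buf <- c(buf, switch(esc, n = "\n", t = "\t", r = "\r", esc))
          j <- j + 2L
        } else {
          if (chars[j] == "\n") line <- line + 1L
          buf <- c(buf, chars[j])
          j <- j + 1L
        }
      }
      if (j > n) abort_parse(sprintf("unterminated string literal at line %d", line), line = line)
      value <- paste(buf, collapse = "")
      i <- j + 1L
      dt <- NULL
      if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        i <- i + 2L
        if (i <= n && chars[i] == "<") {
          j <- i + 1L
          while (j <= n && chars[j] != ">") j <- j + 1L
          dt <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
          i <- j + 1L
        } else {
          j <- i
          while (j <= n && !chars[j] %in% c(" ", "\t", "\r", "\n", ";", ",", "<", "\"")) j <- j + 1L
          tok <- paste(chars[i:(j - 1L)], collapse = "")
          if (grepl("\\.$", tok)) { tok <- sub("\\.$", "", tok); chars[j - 1L] <- "." ; j <- j - 1L }
          dt <- tok
          i <- j
        }
      }
      push("literal", list(value = value, datatype = dt))
      next
    }
    if (c0 == ";") { push("semi", ";"); i <- i + 1L; next }
    if (c0 == ",") { push("comma", ","); i <- i + 1L; next }
    if (c0 == "." && (i == n || chars[i + 1L] %in% c(" ", "\t", "\r", "\n"))) {
      push("dot", "."); i <- i + 1L; next
    }
    # bare word: pname, keyword 'a', or '@prefix'
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\r", "\n", ";", ",", "<", "\"", "#")) j <- j + 1L
    tok <- paste(chars[i:(j - 1L)], collapse = "")
    trailing_dot <- FALSE
    if (grepl("\\.$", tok) && tok != ".") { tok <- sub("\\.$", "", tok); trailing_dot <- TRUE }
    if (tok == "@prefix") push("atprefix", tok)
    else if (tok == "a") push("a", tok)
    else push("pname", tok)
    if (trailing_dot) push("dot", ".")
    i <- j
  }
  tokens
}

.parse_turtle <- function(text) {
  tokens <- .tokenize_turtle(text)
  prefixes <- list()
  triples <- list()
  k <- 1L
  n <- length(tokens)
  peek <- function() if (k <= n) tokens[[k]] else NULL
  take <- function(type = NULL) {
    if (k > n) abort_parse("unexpected end of document", line = if (n) tokens[[n]]$line else 1L)
    t <- tokens[[k]]
    if (!is.null(type) && !t$type %in% type) {
      abort_parse(sprintf("unexpected token %s at line %d",
                          dQuote(paste(t$value, collapse = "")), t$line),
                  line = t$line)
    }
    k <<- k + 1L
    t
  }
  expand <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type == "a") return(paste0(.NS$rdf, "type"))
    pn <- tok$value
    colon <- regexpr(":", pn, fixed = TRUE)
    if (colon < 0) abort_parse(sprintf("not a prefixed name: %s (line %d)", dQuote(pn), tok$line), line = tok$line)
    prefix <- substr(pn, 1L, colon - 1L)
    local <- substr(pn, colon + 1L, nchar(pn))
    ns <- prefixes[[if (nzchar(prefix)) prefix else "."]]
    if (is.null(ns)) abort_parse(sprintf("unknown prefix %s at line %d", dQuote(prefix), tok$line), line = tok$line)
    paste0(ns, local)
  }
  expand_dt <- function(dt) {
    if (is.null(dt)) return(NULL)
    if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", dt)) return(dt)
    colon <- regexpr(":", dt, fixed = TRUE)
    prefix <- substr(dt, 1L, colon - 1L)
    local <- substr(dt, colon + 1L, nchar(dt))
    ns <- prefixes[[if (nzchar(prefix)) prefix else "."]]
    if (is.null(ns)) return(dt)
    paste0(ns, local)
  }
  while (!is.null(peek())) {
    if (peek()$type == "atprefix") {
      take()
      pn <- take(c("pname"))$value
      prefix <- sub(":$", "", pn)
      iri <- take("iri")$value
      take("dot")
      prefixes[[if (nzchar(prefix)) prefix else "."]] <- iri
      next
    }
    subj <- expand(take(c("iri", "pname")))
    repeat {
      pred <- expand(take(c("iri", "pname", "a")))
      repeat {
        obj_tok <- take(c("iri", "pname", "literal"))
        if (obj_tok$type == "literal") {
          triples[[length(triples) + 1L]] <- list(
            s = subj, p = pred, o = obj_tok$value$value, is_iri = FALSE,
            datatype = expand_dt(obj_tok$value$datatype)
          )
        } else {
          triples[[length(triples) + 1L]] <- list(
            s = subj, p = pred, o = expand(obj_tok), is_iri = TRUE, datatype = NULL
          )
        }
        if (!is.null(peek()) && peek()$type == "comma") { take(); next }
        break
      }
      nxt <- take(c("semi", "dot"))
      if (nxt$type == "dot") break
      if (!is.null(peek()) && peek()$type == "dot") { take(); break }
    }
  }
  triples
}

#' Parse a Turtle document into a temporal graph
#'
#' Inverse of [write_graph()]: `read_graph(write_graph(g))` is structurally
#' identical to `g`.  Predicates are matched by their local names for the
#' temporal vocabulary (the published namespace differs between
#' deployments), and unrecognized predicates on events are preserved as
#' opaque annotations and re-emitted on the next write.
#'
#' @param doc Turtle text (a single string), or a path to a `.ttl` file.
#' @return A [temporal_graph()].
#' @export
read_graph <- function(doc) {
  if (length(doc) == 1L && !grepl("\n", doc) && file.exists(doc)) {
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  }
  triples <- .parse_turtle(doc)
  rdf_type <- paste0(.NS$rdf, "type")
  types <- list(); po <- list(); subj_order <- character()
  for (tr in triples) {
    if (is.null(po[[tr$s]])) { po[[tr$s]] <- list(); subj_order <- c(subj_order, tr$s) }
    po[[tr$s]][[length(po[[tr$s]]) + 1L]] <- tr
    if (tr$p == rdf_type && tr$is_iri) types[[tr$s]] <- c(types[[tr$s]], .local_name(tr$o))
  }
  get_po <- function(s, local) {
    if (is.null(po[[s]])) return(list())
    Filter(function(tr) .local_name(tr$p) == local, po[[s]])
  }
  first_lit <- function(s, local) {
    hits <- get_po(s, local)
    if (!length(hits)) return(NULL)
    hits[[1]]$o
  }
  has_type <- function(s, t) !is.null(types[[s]]) && t %in% types[[s]]

  read_duration_node <- function(s) {
    v <- first_lit(s, "hasValue"); u <- first_lit(s, "hasUnit")
    if (is.null(v) || is.null(u)) {
      abort_structural(sprintf("duration node <%s> missing hasValue/hasUnit", s))
    }
    duration(as.numeric(v), u)
  }
  read_instant_node <- function(s) {
    orig <- first_lit(s, "hasOrigTime")
    normtxt <- first_lit(s, "hasNormalizedTime")
    gran <- first_lit(s, "hasGranularity")
    norm <- if (is.null(normtxt)) NULL else parse_partial_date(normtxt)
    inst <- time_instant(if (is.null(orig)) NA_character_ else orig, norm, gran)
    if (identical(first_lit(s, "unresolved"), "true")) inst$unresolved <- TRUE
    if (identical(first_lit(s, "inferred"), "true")) inst$inferred <- TRUE
    inst
  }
  read_time_node <- function(s) {
    if (has_type(s, "TimeInterval")) {
      st <- get_po(s, "hasStartTime"); en <- get_po(s, "hasEndTime")
      du <- get_po(s, "hasDuration")
      time_interval(
        start = if (length(st)) read_instant_node(st[[1]]$o) else NULL,
        end = if (length(en)) read_instant_node(en[[1]]$o) else NULL,
        duration = if (length(du)) read_duration_node(du[[1]]$o) else NULL
      )
    } else {
      read_instant_node(s)
    }
  }

  event_subjects <- Filter(function(s) has_type(s, "Event"), subj_order)
  graph <- temporal_graph()
  known_ev_preds <- c("type", "label", "hasTime", "hasAnnotation", "unmapped",
                      "derivation")
  for (s in event_subjects) {
    id <- .local_name(s)
    label <- first_lit(s, "label")
    if (is.null(label)) abort_structural(sprintf("event <%s> has no rdfs:label", s))
    ev <- add_event(graph, label, id = id)
    anns <- get_po(s, "hasAnnotation")
    for (atr in anns) {
      node <- atr$o
      voc <- first_lit(node, "vocabulary"); ident <- first_lit(node, "identifier")
      plab <- first_lit(node, "preferredLabel")
      if (is.null(voc) || is.null(ident)) {
        abort_structural(sprintf("annotation node <%s> missing vocabulary/identifier", node))
      }
      ev <- graph$events[[id]]
      ev$annotations[[length(ev$annotations) + 1L]] <-
        term_ref(voc, ident, if (is.null(plab)) NA_character_ else plab)
      graph$events[[id]] <- ev
    }
    tt <- get_po(s, "hasTime")
    if (length(tt)) attach_time(graph, id, read_time_node(tt[[1]]$o))
    ev <- graph$events[[id]]
    if (identical(first_lit(s, "unmapped"), "true")) ev$unmapped <- TRUE
    der <- first_lit(s, "derivation")
    if (!is.null(der)) ev$extra$derivation <- der
    for (tr in po[[s]]) {
      if (!.local_name(tr$p) %in% c(known_ev_preds, allen_relations())) {
        ev$extra[[length(ev$extra) + 1L]] <- list(
          predicate = tr$p, value = tr$o, is_iri = tr$is_iri, datatype = tr$datatype
        )
      }
    }
    graph$events[[id]] <- ev
  }
  # restore fresh-id counter past any numeric event ids
  nums <- suppressWarnings(as.integer(sub("^event", "", grep("^event\\d+$", graph$order, value = TRUE))))
  if (length(nums) && any(!is.na(nums))) graph$next_id <- max(nums, na.rm = TRUE) + 1L

  # axiom metadata keyed by source|relation|target
  ax_meta <- list()
  for (s in subj_order) {
    if (!has_type(s, "Axiom")) next
    src <- get_po(s, "annotatedSource"); prp <- get_po(s, "annotatedProperty")
    tgt <- get_po(s, "annotatedTarget")
    if (!length(src) || !length(tgt) || !length(prp)) {
      abort_structural(sprintf(
        "axiom node <%s> is missing annotatedSource/annotatedProperty/annotatedTarget", s))
    }
    rel <- .local_name(prp[[1]]$o)
    key <- paste(.local_name(src[[1]]$o), rel, .local_name(tgt[[1]]$o), sep = "|")
    off <- get_po(s, "hasTimeOffset")
    prov <- first_lit(s, "provenance")
    meta <- list(offset = if (length(off)) read_duration_node(off[[1]]$o) else NULL,
                 provenance = if (is.null(prov)) "stated" else prov)
    if (is.null(ax_meta[[key]])) ax_meta[[key]] <- list()
    ax_meta[[key]][[length(ax_meta[[key]]) + 1L]] <- meta
  }
  # relation triples, in document order
  ax_used <- list()
  for (tr in triples) {
    rel <- .local_name(tr$p)
    if (!tr$is_iri || !rel %in% allen_relations()) next
    sid <- .local_name(tr$s); tid <- .local_name(tr$o)
    if (is.null(graph$events[[sid]]) || is.null(graph$events[[tid]])) next
    key <- paste(sid, rel, tid, sep = "|")
    idx <- (ax_used[[key]] %||% 0L) + 1L
    ax_used[[key]] <- idx
    meta <- if (!is.null(ax_meta[[key]]) && idx <= length(ax_meta[[key]])) {
      ax_meta[[key]][[idx]]
    } else {
      list(offset = NULL, provenance = "stated")
    }
    assert_relation(graph, sid, rel, tid, offset = meta$offset,
                    provenance = meta$provenance)
  }
  graph
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Structural equality of two temporal graphs
#'
#' Field-for-field comparison of events (id, label, annotations, time,
#' unmapped flag, extras) and assertions (endpoints, relation, offset,
#' provenance); bookkeeping such as the fresh-id counter and the cached
#' consistency verdict is ignored.
#'
#' @param g1,g2 [temporal_graph()]s.
#' @return `TRUE` or `FALSE`.
#' @export
graph_identical <- function(g1, g2) {
  strip_ev <- function(e) e[c("id", "label", "annotations", "time", "unmapped", "extra")]
  strip_as <- function(a) a[c("source", "relation", "target", "offset", "provenance")]
  identical(g1$order, g2$order) &&
    identical(lapply(g1$order, function(id) strip_ev(g1$events[[id]])),
              lapply(g2$order, function(id) strip_ev(g2$events[[id]]))) &&
    identical(lapply(g1$assertions, strip_as), lapply(g2$assertions, strip_as))
}

# ---------------------------------------------------------------------------
# Semi-structured report files (JSON dialect)

#' Read a semi-structured adverse-event report
#'
#' The JSON dialect mirrors how surveillance records present themselves:
#' structured fields (`report_id`, `age`, `sex`, `structured_dates` with
#' `vaccinated` / `onset` / `submitted` / `entered`, `vaccines`, `symptoms`)
#' plus a `narrative_annotations` list of spans marked up from the write-up,
#' each with a `kind` (`event`, `time`, `duration`, `relation`) and
#' attributes linking it to events.
#'
#' @param file Path to a report JSON file, or a JSON string.
#' @return An object of class `report_record`.
#' @export
read_report <- function(file) {
  txt <- if (length(file) == 1L && !grepl("[{\n]", file) && file.exists(file)) {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  } else {
    file
  }
  rec <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(cnd) abort_parse(conditionMessage(cnd)))
  if (is.null(rec$report_id) || !nzchar(as.character(rec$report_id))) {
    abort_structural("report is missing its report_id")
  }
  known <- c("report_id", "age", "sex", "structured_dates", "vaccines",
             "symptoms", "narrative_annotations")
  unknown <- setdiff(names(rec), known)
  if (length(unknown)) {
    warning(sprintf("unknown report fields kept as-is: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sd <- rec$structured_dates %||% list()
  parsed_dates <- list()
  for (nm in names(sd)) {
    parsed_dates[[nm]] <- tryCatch(parse_partial_date(as.character(sd[[nm]])),
      teo_error = function(cnd) abort_structural(sprintf(
        "structured date %s = %s does not parse as a date", nm, dQuote(as.character(sd[[nm]]))
      )))
  }
  vaccines <- as.character(unlist(rec$vaccines %||% list()))
  lex <- default_lexicon()
  vaccine_unmapped <- vapply(vaccines, function(v) {
    inherits(lookup_term(v, "VO", lex), "unmapped_term")
  }, logical(1))
  anns <- lapply(rec$narrative_annotations %||% list(), function(a) {
    list(span = as.character(a$span %||% ""),
         kind = as.character(a$kind %||% "event"),
         attributes = a$attributes %||% list())
  })
  structure(
    list(report_id = as.character(rec$report_id),
         age = rec$age,
         sex = if (is.null(rec$sex)) NULL else as.character(rec$sex),
         structured_dates = parsed_dates,
         vaccines = vaccines,
         vaccine_unmapped = unname(vaccine_unmapped),
         symptoms = as.character(unlist(rec$symptoms %||% list())),
         narrative_annotations = anns,
         extra = rec[unknown]),
    class = "report_record"
  )
}

#' @export
print.report_record <- function(x, ...) {
  cat(sprintf("<report %s> %d vaccine(s), %d symptom(s), %d annotation(s)\n",
              x$report_id, length(x$vaccines), length(x$symptoms),
              length(x$narrative_annotations)))
  invisible(x)
}

#' Write a report record to the JSON dialect
#'
#' @param record A `report_record` (or the raw list a generator produced).
#' @param path Output file; omit to get the JSON text back.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_report <- function(record, path = NULL) {
  out <- list(report_id = record$report_id)
  if (!is.null(record$age)) out$age <- record$age
  if (!is.null(record$sex)) out$sex <- record$sex
  if (length(record$structured_dates)) {
    out$structured_dates <- lapply(record$structured_dates, function(d) {
      if (is_partial_date(d)) format(d) else as.character(d)
    })
  }
  if (length(record$vaccines)) out$vaccines <- as.list(record$vaccines)
  if (length(record$symptoms)) out$symptoms <- as.list(record$symptoms)
  out$narrative_annotations <- record$narrative_annotations %||% list()
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}
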