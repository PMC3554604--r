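# The temporal graph: events plus qualitative assertions between them.
# The graph is environment-backed so that add_event() can both return the
# new event and make it visible through the graph handle, mirroring how an
# annotation tool accretes a document's triples.

#' The 13 Allen interval relations
#'
#' @return Character vector of the base relation names.
#' @export
#' @examples
#' allen_relations()
allen_relations <- function() {
  c("before", "meets", "overlaps", "finished_by", "contains", "starts",
    "equals", "started_by", "during", "finishes", "overlapped_by",
    "met_by", "after")
}

check_relation <- function(relation) {
  if (!is.character(relation) || length(relation) != 1L ||
      !relation %in% allen_relations()) {
    abort_invalid_input(sprintf(
      "relation must be one of the 13 Allen base relations, got %s",
      dQuote(as.character(relation)[1])
    ))
  }
  relation
}

# Relations that may carry a quantitative time offset
offset_relations <- function() c("before", "after", "meets", "met_by")

#' Create an empty temporal graph
#'
#' The container for one report's events, time entities and temporal
#' assertions; the unit of reasoning and of serialization.
#'
#' @return An object of class `temporal_graph`.
#' @export
#' @examples
#' g <- temporal_graph()
#' e <- add_event(g, "vaccinated w/MMR")
#' n_events(g)
temporal_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$events <- list()           # id -> event
  g$assertions <- list()       # list of teo_assertion
  g$order <- character()       # narrative (insertion) order of event ids
  g$consistency_status <- "unknown"
  g$next_id <- 1L
  class(g) <- "temporal_graph"
  g
}

is_temporal_graph <- function(x) inherits(x, "temporal_graph")

#' @export
print.temporal_graph <- function(x, ...) {
  cat(sprintf("<temporal graph> %d events, %d assertions (%s)\n",
              n_events(x), length(x$assertions), x$consistency_status))
  for (id in x$order) {
    e <- x$events[[id]]
    t <- if (is.null(e$time)) "" else paste0(" @ ", format(e$time))
    cat(sprintf("  %s: %s%s\n", id, dQuote(e$label), t))
  }
  for (a in x$assertions) {
    off <- if (is.null(a$offset)) "" else sprintf(" [offset %s]", format(a$offset))
    cat(sprintf("  %s %s %s%s (%s)\n", a$source, a$relation, a$target, off,
                a$provenance))
  }
  invisible(x)
}

#' Number of events in a temporal graph
#' @param graph A [temporal_graph()].
#' @return Integer count.
#' @export
n_events <- function(graph) length(graph$events)

#' Fetch one event by id
#' @param graph A [temporal_graph()].
#' @param id Event id.
#' @return The event record.
#' @export
get_event <- function(graph, id) {
  e <- graph$events[[id]]
  if (is.null(e)) abort_not_found(sprintf("no event with id %s", dQuote(id)), id = id)
  e
}

#' List event ids in narrative order
#' @param graph A [temporal_graph()].
#' @return Character vector of ids.
#' @export
event_ids <- function(graph) graph$order

#' Add an event to a temporal graph
#'
#' @param graph A [temporal_graph()].
#' @param label Non-empty free-text label, stored verbatim.
#' @param annotations Optional list of [term_ref()] ontology annotations.
#' @param id Optional explicit id (must be unused); a fresh `event<k>` id is
#'   minted otherwise.
#' @return The new event (a list with `id`, `label`, `annotations`, `time`).
#' @export
#' @examples
#' g <- temporal_graph()
#' add_event(g, "vaccinated w/MMR")
add_event <- function(graph, label, annotations = list(), id = NULL) {
  stopifnot(is_temporal_graph(graph))
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(trimws(label))) {
    abort_invalid_input("event label must be a non-empty string")
  }
  if (is.null(id)) {
    id <- sprintf("event%d", graph$next_id)
    while (!is.null(graph$events[[id]])) {
      graph$next_id <- graph$next_id + 1L
      id <- sprintf("event%d", graph$next_id)
    }
  } else if (!is.null(graph$events[[id]])) {
    abort_invalid_input(sprintf("event id %s already in use", dQuote(id)))
  }
  ev <- structure(
    list(id = id, label = label, annotations = annotations, time = NULL,
         unmapped = FALSE, extra = list()),
    class = "teo_event"
  )
  graph$events[[id]] <- ev
  graph$order <- c(graph$order, id)
  graph$next_id <- graph$next_id + 1L
  invisible(ev)
}

#' @export
format.teo_event <- function(x, ...) sprintf("%s %s", x$id, dQuote(x$label))

#' @export
print.teo_event <- function(x, ...) {
  cat("<event>", format(x), "\n")
  if (!is.null(x$time)) cat("  time:", format(x$time), "\n")
  for (a in x$annotations) cat("  ", format(a), "\n")
  invisible(x)
}

#' Attach a time stamp to an event
#'
#' Each event carries at most one time assignment; annotations are
#' source-of-truth records, so re-attachment is a conflict rather than a
#' replacement.
#'
#' @param graph A [temporal_graph()].
#' @param id Event id.
#' @param time A [time_instant()] or [time_interval()].
#' @return The updated event, invisibly.
#' @export
attach_time <- function(graph, id, time) {
  stopifnot(is_temporal_graph(graph))
  ev <- get_event(graph, id)
  if (!is.null(ev$time)) {
    abort_conflict(sprintf("event %s already has a time assigned", dQuote(id)), id = id)
  }
  if (!is_time_instant(time) && !is_time_interval(time)) {
    abort_invalid_input("time must be a time_instant or time_interval")
  }
  ev$time <- time
  graph$events[[id]] <- ev
  invisible(ev)
}

#' Assert an Allen relation between two events
#'
#' @param graph A [temporal_graph()].
#' @param source,target Event ids; the statement reads "`source` `relation`
#'   `target`", e.g. fever `after` vaccination.
#' @param relation One of [allen_relations()].
#' @param offset Optional [duration()] quantifying the gap; only meaningful
#'   with `before`, `after`, `meets` and `met_by`.  For "X after A offset d"
#'   the offset runs from the end of A to the start of X.
#' @param provenance `"stated"` for annotated assertions, `"inferred"` for
#'   reasoner output.
#' @return The stored assertion, invisibly.
#' @export
#' @examples
#' g <- temporal_graph()
#' v <- add_event(g, "vaccination")
#' f <- add_event(g, "she developed a fever")
#' assert_relation(g, f$id, "after", v$id, offset = duration(18, "day"))
assert_relation <- function(graph, source, relation, target, offset = NULL,
                            provenance = c("stated", "inferred")) {
  stopifnot(is_temporal_graph(graph))
  provenance <- match.arg(provenance)
  check_relation(relation)
  get_event(graph, source)
  get_event(graph, target)
  if (source == target && relation != "equals") {
    abort_invalid_input(sprintf(
      "an event cannot be %s itself", dQuote(relation)
    ))
  }
  if (!is.null(offset)) {
    if (!is_duration(offset)) abort_invalid_input("offset must be a duration")
    if (!relation %in% offset_relations()) {
      abort_invalid_input(sprintf(
        "a time offset is only meaningful with %s",
        paste(offset_relations(), collapse = "/")
      ))
    }
  }
  if (provenance == "stated") {
    for (a in graph$assertions) {
      if (a$provenance == "stated" && a$source == source && a$target == target &&
          a$relation != relation) {
        abort_conflict(sprintf(
          "contradictory stated assertions between %s and %s: %s vs %s",
          source, target, a$relation, relation
        ))
      }
    }
  }
  a <- structure(
    list(source = source, relation = relation, target = target,
         offset = offset, provenance = provenance),
    class = "teo_assertion"
  )
  graph$assertions[[length(graph$assertions) + 1L]] <- a
  graph$consistency_status <- "unknown"
  invisible(a)
}

#' @export
format.teo_assertion <- function(x, ...) {
  off <- if (is.null(x$offset)) "" else sprintf(" [offset %s]", format(x$offset))
  sprintf("%s %s %s%s (%s)", x$source, x$relation, x$target, off, x$provenance)
}

#' @export
print.teo_assertion <- function(x, ...) {
  cat("<assertion>", format(x), "\n")
  invisible(x)
}

#' Check a temporal graph for structural and temporal consistency
#'
#' Runs the qualitative reasoner over the stated assertions.  For graphs of
#' up to twelve events a full scenario search backs up path consistency, so
#' the verdict is exact at desk scale; larger graphs get the
#' path-consistency verdict.
#'
#' @param graph A [temporal_graph()].
#' @return A list with `consistent` (logical) and, when inconsistent,
#'   `conflicts`: the offending assertion pairs/triangles.  Also records the
#'   verdict in `graph$consistency_status`.
#' @export
validate_graph <- function(graph) {
  stopifnot(is_temporal_graph(graph))
  missing <- character()
  for (a in graph$assertions) {
    if (is.null(graph$events[[a$source]])) missing <- c(missing, a$source)
    if (is.null(graph$events[[a$target]])) missing <- c(missing, a$target)
  }
  if (length(missing)) {
    abort_structural(sprintf(
      "assertions reference missing events: %s",
      paste(unique(missing), collapse = ", ")
    ), missing_ids = unique(missing))
  }
  conflicts <- list()
  # direct contradictions between stated singleton assertions
  stated <- Filter(function(a) a$provenance == "stated", graph$assertions)
  if (length(stated) > 1L) {
    for (i in seq_len(length(stated) - 1L)) {
      for (j in seq(i + 1L, length(stated))) {
        ai <- stated[[i]]; aj <- stated[[j]]
        same_pair <- ai$source == aj$source && ai$target == aj$target
        flipped <- ai$source == aj$target && ai$target == aj$source
        if (same_pair && ai$relation != aj$relation) {
          conflicts[[length(conflicts) + 1L]] <- list(ai, aj)
        } else if (flipped && aj$relation != invert_relation(ai$relation)) {
          conflicts[[length(conflicts) + 1L]] <- list(ai, aj)
        }
      }
    }
  }
  consistent <- length(conflicts) == 0L
  if (consistent && n_events(graph) > 0L) {
    net <- constraint_network(graph)
    res <- tryCatch(propagate_constraints(net), teo_inconsistency = function(cnd) cnd)
    if (inherits(res, "teo_inconsistency")) {
      consistent <- FALSE
      conflicts[[length(conflicts) + 1L]] <- list(
        triangle = res$triangle,
        assertions = assertions_between(graph, res$triangle)
      )
    } else if (n_events(graph) <= 12L) {
      # exact check: does some atomic scenario realize the network?
      if (is.null(find_scenario(res))) {
        consistent <- FALSE
        conflicts[[length(conflicts) + 1L]] <- list(
          triangle = NULL, assertions = stated
        )
      }
    }
  }
  graph$consistency_status <- if (consistent) "consistent" else "inconsistent"
  list(consistent = consistent, conflicts = conflicts)
}

assertions_between <- function(graph, ids) {
  if (is.null(ids)) return(list())
  Filter(function(a) a$source %in% ids && a$target %in% ids, graph$assertions)
}

# Deep-copy a temporal graph (environments are reference objects).
clone_graph <- function(graph) {
  g2 <- temporal_graph()
  g2$events <- graph$events
  g2$assertions <- graph$assertions
  g2$order <- graph$order
  g2$consistency_status <- graph$consistency_status
  g2$next_id <- graph$next_id
  g2
}
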