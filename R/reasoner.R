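# Quantitative reasoning: calendar date inference along offset chains, and
# relation derivation that combines resolved dates with qualitative
# propagation.

# The calendar date an event is resolved to, or NULL.  Interval-timed events
# contribute their start instant.
resolved_date <- function(event) {
  t <- event$time
  if (is.null(t)) return(NULL)
  inst <- if (is_time_interval(t)) t$start else t
  if (is.null(inst) || is.null(inst$normalized)) return(NULL)
  if (is.na(inst$normalized$year)) return(NULL)
  inst$normalized
}

#' Infer calendar dates along duration-offset chains
#'
#' Every event reachable from a date-anchored event through offset-bearing
#' `before`/`after` assertions receives a normalized date equal to the
#' anchor shifted by the accumulated calendar offsets ("18 days after the
#' vaccination on July 6 puts the fever on July 24").  Inference runs in
#' both directions along each assertion and iterates, so multi-hop chains
#' (vaccination -> fever -> vasculitis) resolve.  An inferred date's
#' granularity is the coarsest granularity met along its chain.
#'
#' @param graph A validated [temporal_graph()]; it is updated in place.
#' @return The graph, with inferred [time_instant()]s attached to newly
#'   dated events (marked `inferred`), invisibly.
#' @export
#' @examples
#' g <- temporal_graph()
#' v <- add_event(g, "vaccination")
#' f <- add_event(g, "fever")
#' attach_time(g, v$id, time_instant("July 6th", partial_date(2006, 7, 6)))
#' assert_relation(g, f$id, "after", v$id, offset = duration(18, "day"))
#' infer_dates(g)
#' get_event(g, f$id)$time
infer_dates <- function(graph) {
  stopifnot(is_temporal_graph(graph))
  dates <- list()        # id -> partial_date
  gran  <- list()        # id -> granularity of the derivation chain
  deriv <- list()        # id -> human-readable derivation
  for (id in event_ids(graph)) {
    d <- resolved_date(graph$events[[id]])
    if (!is.null(d)) {
      dates[[id]] <- d
      gran[[id]] <- date_granularity(d)
      deriv[[id]] <- sprintf("stated date %s", format(d))
    }
  }
  # offset edges: for "S after T offset d", date(S) = date(T) + d
  steps <- list()
  for (a in graph$assertions) {
    if (is.null(a$offset) || !a$relation %in% c("before", "after")) next
    sgn <- if (a$relation == "after") 1L else -1L
    steps[[length(steps) + 1L]] <- list(from = a$target, to = a$source,
                                        dur = a$offset, sign = sgn)
    steps[[length(steps) + 1L]] <- list(from = a$source, to = a$target,
                                        dur = a$offset, sign = -sgn)
  }
  repeat {
    progressed <- FALSE
    for (st in steps) {
      from_d <- dates[[st$from]]
      if (is.null(from_d)) next
      g_new <- coarser_granularity(gran[[st$from]],
                                   if (st$dur$unit == "week") "day" else st$dur$unit)
      new_d <- pd_truncate(shift_date(from_d, st$dur, st$sign), g_new)
      prev <- dates[[st$to]]
      if (is.null(prev)) {
        dates[[st$to]] <- new_d
        gran[[st$to]] <- g_new
        deriv[[st$to]] <- sprintf("%s %s %s %s (via %s)",
                                  format(from_d),
                                  if (st$sign > 0) "+" else "-",
                                  format(st$dur), format(new_d), st$from)
        progressed <- TRUE
      } else if (compare_dates(prev, new_d) != 0L) {
        abort_conflict(sprintf(
          "conflicting dates derived for %s: %s [%s] vs %s [%s]",
          st$to, format(prev), deriv[[st$to]], format(new_d),
          sprintf("%s via %s", format(st$dur), st$from)
        ), derivations = list(deriv[[st$to]],
                              sprintf("%s via offset from %s", format(new_d), st$from)))
      }
    }
    if (!progressed) break
  }
  for (id in names(dates)) {
    ev <- graph$events[[id]]
    if (is.null(resolved_date(ev))) {
      inst <- time_instant(NA_character_, dates[[id]])
      inst$inferred <- TRUE
      if (is.null(ev$time)) {
        ev$time <- inst
      } else if (is_time_instant(ev$time) && !is.null(ev$time$normalized) &&
                 is.na(ev$time$normalized$year)) {
        # a year-unresolved stated instant completed by inference: keep the
        # original expression, fill the date
        cand <- dates[[id]]
        stated <- ev$time$normalized
        ok <- (is.na(stated$month) || is.na(cand$month) || stated$month == cand$month) &&
              (is.na(stated$day) || is.na(cand$day) || stated$day == cand$day)
        if (!ok) {
          abort_conflict(sprintf(
            "inferred date %s contradicts stated partial date %s for %s",
            format(cand), format(stated), id
          ))
        }
        ev$time <- time_instant(ev$time$orig_text, cand)
        ev$time$inferred <- TRUE
      }
      ev$extra$derivation <- deriv[[id]]
      graph$events[[id]] <- ev
    }
  }
  invisible(graph)
}

#' Derive the temporal relation between two events
#'
#' When both events carry resolved dates the relation follows from calendar
#' comparison at the coarser of the two granularities (events whose dates
#' tie at that granularity cannot be ordered, yielding
#' `{before, equals, after}`).  Otherwise the answer is the propagated
#' qualitative constraint set.
#'
#' @param graph A consistent [temporal_graph()] (run [infer_dates()] first
#'   to get date-based answers).
#' @param e1,e2 Event ids; the returned relations read "`e1` (relation)
#'   `e2`".
#' @return Character vector of possible base relations.
#' @export
derive_relation <- function(graph, e1, e2) {
  stopifnot(is_temporal_graph(graph))
  ev1 <- get_event(graph, e1)
  ev2 <- get_event(graph, e2)
  if (e1 == e2) return("equals")
  d1 <- resolved_date(ev1)
  d2 <- resolved_date(ev2)
  net <- propagate_constraints(constraint_network(graph))
  qual <- .set_names(net$edges[match(e1, net$ids), match(e2, net$ids), ])
  if (!is.null(d1) && !is.null(d2)) {
    cmp <- compare_dates(d1, d2)
    if (cmp < 0L) return("before")
    if (cmp > 0L) return("after")
    out <- intersect(c("before", "equals", "after"), qual)
    if (length(out)) return(out)
    return(c("before", "equals", "after"))
  }
  qual
}
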