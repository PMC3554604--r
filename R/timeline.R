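# Timelines: the resolved, ordered event sequence of one report, with each
# event's calendar-day distance from the vaccination anchor; and the
# cross-report comparison of such sequences.

#' Build a vaccination-anchored timeline from a reasoned graph
#'
#' The anchor is the earliest event carrying a vaccine (VO) annotation, ties
#' broken by narrative order; an `anchor_label_hint` can name the anchor
#' when no event is vaccine-annotated.  Date-resolved events are ordered by
#' date (same-day events keep narrative order); events without a resolved
#' date are placed after the latest resolved event the qualitative
#' constraints force before them, and flagged unresolved.
#'
#' @param graph A consistent [temporal_graph()], after [infer_dates()].
#' @param anchor_label_hint Optional label (normalized before matching).
#' @param report_id Optional report id carried on the timeline.
#' @return An object of class `teo_timeline`; its `entries` data frame has
#'   columns `event_id`, `label`, `term`, `term_key`, `date`, `day_offset`,
#'   `resolved`.
#' @export
build_timeline <- function(graph, anchor_label_hint = NULL, report_id = NA_character_) {
  stopifnot(is_temporal_graph(graph))
  ids <- event_ids(graph)
  if (!length(ids)) abort_anchor("cannot build a timeline from an empty graph")

  vo_annotated <- vapply(ids, function(id) {
    any(vapply(graph$events[[id]]$annotations,
               function(t) t$vocabulary == "VO", logical(1)))
  }, logical(1))
  dates <- lapply(ids, function(id) resolved_date(graph$events[[id]]))
  names(dates) <- ids

  pick_earliest <- function(cand) {
    dated <- cand[!vapply(dates[cand], is.null, logical(1))]
    if (length(dated)) {
      best <- dated[1]
      for (id in dated[-1]) if (compare_dates(dates[[id]], dates[[best]]) < 0L) best <- id
      best
    } else {
      cand[1]   # narrative order
    }
  }
  anchor <- NULL
  if (any(vo_annotated)) {
    anchor <- pick_earliest(ids[vo_annotated])
  } else if (!is.null(anchor_label_hint)) {
    hint <- .fold_label(anchor_label_hint)
    hit <- ids[vapply(ids, function(id) .fold_label(graph$events[[id]]$label) == hint,
                      logical(1))]
    if (length(hit)) anchor <- hit[1]
  }
  if (is.null(anchor)) {
    abort_anchor("no vaccination-annotated event and no usable anchor_label_hint")
  }

  term_of <- function(ev) {
    for (v in c("OAE", "MedDRA", "VO")) {
      for (t in ev$annotations) {
        if (t$vocabulary == v) {
          return(list(term = t$preferred_label,
                      key = paste(t$vocabulary, t$identifier, sep = ":")))
        }
      }
    }
    list(term = NA_character_, key = NA_character_)
  }

  resolved <- !vapply(dates, is.null, logical(1))
  # order resolved events by calendar position (missing finer components
  # sort first: a month-granular stamp precedes that month's day-granular
  # ones), ties broken by narrative order
  res_ids <- ids[resolved[ids]]
  if (length(res_ids) > 1L) {
    key <- vapply(res_ids, function(id) {
      d <- dates[[id]]
      d$year * 10000 + (if (is.na(d$month)) 0 else d$month * 100) +
        (if (is.na(d$day)) 0 else d$day)
    }, numeric(1))
    res_ids <- res_ids[order(key, match(res_ids, ids))]
  }
  ordered <- res_ids
  unres_ids <- ids[!resolved[ids]]
  if (length(unres_ids)) {
    net <- tryCatch(propagate_constraints(constraint_network(graph)),
                    teo_inconsistency = function(cnd) NULL)
    before_set <- c("before", "meets", "overlaps", "starts", "during",
                    "finishes", "equals", "finished_by", "started_by", "contains")
    for (u in unres_ids) {
      pos <- 0L
      if (!is.null(net)) {
        for (r in ordered) {
          s <- net$edges[match(r, net$ids), match(u, net$ids), ]
          forced_before <- all(.set_names(s) %in% setdiff(before_set, "equals")) ||
            all(.set_names(s) %in% c("before", "meets"))
          if (forced_before) pos <- match(r, ordered)
        }
      }
      ordered <- append(ordered, u, after = if (pos > 0L) pos else length(ordered))
    }
  }

  anchor_date <- dates[[anchor]]
  day_off <- function(id) {
    d <- dates[[id]]
    if (is.null(d) || is.null(anchor_date)) return(NA_integer_)
    if (date_granularity(d) != "day" || date_granularity(anchor_date) != "day") {
      return(NA_integer_)
    }
    as.integer(pd_to_Date(d) - pd_to_Date(anchor_date))
  }
  rows <- lapply(ordered, function(id) {
    ev <- graph$events[[id]]
    tm <- term_of(ev)
    data.frame(event_id = id, label = ev$label, term = tm$term,
               term_key = tm$key,
               date = if (is.null(dates[[id]])) NA_character_ else format(dates[[id]]),
               day_offset = day_off(id), resolved = resolved[[id]],
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  structure(list(report_id = report_id, anchor = anchor, entries = entries),
            class = "teo_timeline")
}

#' @export
print.teo_timeline <- function(x, ...) {
  cat(sprintf("<timeline %s> anchor: %s\n", x$report_id, x$anchor))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Day offset of one event from the timeline anchor
#'
#' @param timeline A `teo_timeline`.
#' @param event Event id.
#' @return Integer days from the anchor, or `NA` when the event's date is
#'   unresolved (or coarser than a day).
#' @export
day_offset <- function(timeline, event) {
  stopifnot(inherits(timeline, "teo_timeline"))
  row <- which(timeline$entries$event_id == event)
  if (!length(row)) abort_not_found(sprintf("no event %s in timeline", dQuote(event)))
  timeline$entries$day_offset[row[1]]
}

#' Compare timelines across reports
#'
#' Computes the three cohort views used in adverse-event time-trend reading:
#' shared symptoms with their per-report day offsets, per-report symptom
#' frequencies, and symptom pairs whose strict order reverses between
#' reports.  Symptoms are matched by their ontology term, never by surface
#' string, so "FLU-LIKE SYMPTOMS" and "Influenza-like illness" count as one
#' symptom.
#'
#' @param timelines A list of `teo_timeline` objects (at least one).
#' @return An object of class `cohort_comparison` with fields
#'   `shared_symptom_offsets` (data frame term/report_id/day_offset, terms
#'   present in two or more reports), `frequency_table` (term x report
#'   count matrix including zeroes) and `order_differences` (list of pairs
#'   with the report ids showing each order).
#' @export
compare_timelines <- function(timelines) {
  if (!is.list(timelines) || !length(timelines) ||
      !all(vapply(timelines, inherits, logical(1), "teo_timeline"))) {
    abort_invalid_input("compare_timelines needs a non-empty list of timelines")
  }
  rows <- list()
  for (tl in timelines) {
    e <- tl$entries
    sympt <- e[e$event_id != tl$anchor & !startsWith(ifelse(is.na(e$term_key), "", e$term_key), "VO:"), , drop = FALSE]
    if (nrow(sympt) && anyNA(sympt$term_key)) {
      abort_annotation(sprintf(
        "timeline %s has events without ontology annotations; run annotate_events() first",
        tl$report_id
      ))
    }
    if (nrow(sympt)) {
      rows[[length(rows) + 1L]] <- data.frame(
        report_id = tl$report_id, term = sympt$term, term_key = sympt$term_key,
        day_offset = sympt$day_offset, stringsAsFactors = FALSE
      )
    }
  }
  report_ids <- vapply(timelines, function(tl) tl$report_id, character(1))
  if (anyDuplicated(report_ids)) {
    abort_invalid_input("timelines must carry distinct report ids")
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(report_id = character(), term = character(),
               term_key = character(), day_offset = integer(),
               stringsAsFactors = FALSE)
  terms <- sort(unique(all_rows$term_key))
  term_label <- vapply(terms, function(k) all_rows$term[match(k, all_rows$term_key)],
                       character(1))

  # frequency table: term x report, zeroes included
  freq <- matrix(0L, nrow = length(terms), ncol = length(report_ids),
                 dimnames = list(unname(term_label), report_ids))
  for (r in seq_len(nrow(all_rows))) {
    freq[match(all_rows$term_key[r], terms), all_rows$report_id[r]] <-
      freq[match(all_rows$term_key[r], terms), all_rows$report_id[r]] + 1L
  }

  shared_keys <- terms[vapply(terms, function(k) {
    length(unique(all_rows$report_id[all_rows$term_key == k])) >= 2L
  }, logical(1))]
  shared <- all_rows[all_rows$term_key %in% shared_keys,
                     c("term", "term_key", "report_id", "day_offset")]
  shared <- shared[order(shared$term_key, match(shared$report_id, report_ids)), ,
                   drop = FALSE]
  rownames(shared) <- NULL

  # strict first-occurrence order per report, pairwise reversals
  first_occ <- function(rid, key) {
    v <- all_rows$day_offset[all_rows$report_id == rid & all_rows$term_key == key]
    v <- v[!is.na(v)]
    if (length(v)) min(v) else NA_integer_
  }
  order_differences <- list()
  if (length(terms) >= 2L) {
    for (i in seq_len(length(terms) - 1L)) for (j in seq(i + 1L, length(terms))) {
      a <- terms[i]; b <- terms[j]
      a_first <- character(); b_first <- character()
      for (rid in report_ids) {
        oa <- first_occ(rid, a); ob <- first_occ(rid, b)
        if (is.na(oa) || is.na(ob) || oa == ob) next
        if (oa < ob) a_first <- c(a_first, rid) else b_first <- c(b_first, rid)
      }
      if (length(a_first) && length(b_first)) {
        order_differences[[length(order_differences) + 1L]] <- list(
          term_a = unname(term_label[match(a, terms)]),
          term_b = unname(term_label[match(b, terms)]),
          term_key_a = a, term_key_b = b,
          a_first = a_first, b_first = b_first
        )
      }
    }
  }
  structure(
    list(shared_symptom_offsets = shared, frequency_table = freq,
         order_differences = order_differences, report_ids = report_ids),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort comparison> %d report(s)\n", length(x$report_ids)))
  cat("shared symptom offsets:\n")
  print(x$shared_symptom_offsets, row.names = FALSE)
  cat("frequencies:\n")
  print(x$frequency_table)
  if (length(x$order_differences)) {
    cat("order differences:\n")
    for (d in x$order_differences) {
      cat(sprintf("  %s before %s in %s; opposite in %s\n", d$term_a, d$term_b,
                  paste(d$a_first, collapse = ","), paste(d$b_first, collapse = ",")))
    }
  }
  invisible(x)
}

#' Export timelines as a flat event-sequence TSV
#'
#' One row per event: `report_id`, `term`, `day_offset` — the flat form
#' event-sequence visualization tools consume.
#'
#' @param timelines A `teo_timeline` or list of them.
#' @param path Output TSV path; omit to get a data frame back.
#' @return The data frame, invisibly when written.
#' @export
export_event_sequences <- function(timelines, path = NULL) {
  if (inherits(timelines, "teo_timeline")) timelines <- list(timelines)
  rows <- lapply(timelines, function(tl) {
    e <- tl$entries
    data.frame(report_id = tl$report_id,
               term = ifelse(is.na(e$term), e$label, e$term),
               day_offset = e$day_offset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
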