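# Bridge from a parsed report record to a temporal graph: narrative
# annotations become events, time stamps and relation assertions; the
# structured "Vaccinated" field anchors year completion for partial dates.

#' Build a temporal graph from a report record
#'
#' Annotation kinds are interpreted as follows: `event` spans create events
#' (optionally with an explicit `attributes$id`); `time` spans attach a
#' parsed time instant to `attributes$event`, completing a missing year from
#' the structured vaccination date (rolling forward when the completed date
#' would precede it — adverse events follow the vaccination); `relation`
#' spans assert `attributes$source` (relation) `attributes$target`;
#' `duration` spans do the same with the span parsed as the relation's time
#' offset.
#'
#' @param record A `report_record` from [read_report()].
#' @param lexicon A `teo_lexicon` used by [annotate_events()]; `NULL` skips
#'   annotation.
#' @return A [temporal_graph()].
#' @export
graph_from_report <- function(record, lexicon = default_lexicon()) {
  stopifnot(inherits(record, "report_record"))
  anchor_date <- record$structured_dates$vaccinated
  ctx <- if (!is.null(anchor_date) && date_is_complete(anchor_date)) {
    normalization_context(anchor_date = anchor_date)
  } else {
    normalization_context()
  }
  g <- temporal_graph()
  alias <- list()   # annotation-local id -> graph event id
  resolve_id <- function(ref) {
    ref <- as.character(ref)
    out <- alias[[ref]] %||% ref
    get_event(g, out)
    out
  }
  for (ann in record$narrative_annotations) {
    kind <- ann$kind
    at <- ann$attributes
    if (kind == "event") {
      ev <- add_event(g, ann$span)
      if (!is.null(at$id)) alias[[as.character(at$id)]] <- ev$id
    } else if (kind == "time") {
      id <- resolve_id(at$event)
      inst <- parse_time_expression(ann$span, ctx, ordering_hint = "after_anchor")
      attach_time(g, id, inst)
    } else if (kind %in% c("relation", "duration")) {
      src <- resolve_id(at$source)
      tgt <- resolve_id(at$target)
      rel <- as.character(at$relation %||% "after")
      off <- if (kind == "duration") parse_duration_expression(ann$span) else NULL
      assert_relation(g, src, rel, tgt, offset = off)
    } else {
      abort_invalid_input(sprintf("unknown annotation kind %s", dQuote(kind)))
    }
  }
  if (!is.null(lexicon)) annotate_events(g, lexicon)
  g
}

#' Run the full reasoning pipeline on one report
#'
#' Convenience wrapper: [read_report()] (when given a path),
#' [graph_from_report()], [validate_graph()], [infer_dates()],
#' [build_timeline()].
#'
#' @param report A path/JSON string or a `report_record`.
#' @param lexicon A `teo_lexicon`.
#' @param anchor_label_hint Passed to [build_timeline()].
#' @return A `teo_timeline`.
#' @export
report_timeline <- function(report, lexicon = default_lexicon(),
                            anchor_label_hint = NULL) {
  record <- if (inherits(report, "report_record")) report else read_report(report)
  g <- graph_from_report(record, lexicon)
  v <- validate_graph(g)
  if (!v$consistent) {
    abort_inconsistency(sprintf("report %s is temporally inconsistent", record$report_id))
  }
  infer_dates(g)
  build_timeline(g, anchor_label_hint = anchor_label_hint,
                 report_id = record$report_id)
}
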