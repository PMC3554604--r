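# Worked cases packaged as in-code fixtures: the five-event MMR narrative,
# the Engerix-B record excerpt, and a three-report hepatitis-B cohort whose
# planted facts exercise the three cross-report comparison patterns.

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; omit to list them.
#' @return Full path, or the available file names.
#' @export
#' @examples
#' teo_example()
teo_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "teotimer")))
  }
  system.file("extdata", file, package = "teotimer", mustWork = TRUE)
}

#' The worked five-event MMR case
#'
#' Encodes the narrative "18 month-old vaccinated w/MMR on July 6th.
#' Eighteen days after vaccination she developed a fever of 104 and macular
#' rash of the face, torso & legs. Dx: vasculitis 2 wks later. Patient
#' hospitalized 08-08": five events — the vaccination (dated July 6, year
#' 2006 from the structured record), fever and rash 18 days after it,
#' vasculitis 2 weeks after those, and the hospitalization dated 08-08.
#' Only the vaccination and hospitalization carry explicit dates; the rest
#' is left for [infer_dates()].
#'
#' @param annotate Attach lexicon annotations ([annotate_events()]).
#' @param context_year Year supplied by the structured record.
#' @return A [temporal_graph()] with events `event1` (vaccination) through
#'   `event5` (hospitalization).
#' @export
#' @examples
#' g <- mmr_case_graph()
#' infer_dates(g)
#' get_event(g, "event4")$time   # vasculitis, 2006-08-07
mmr_case_graph <- function(annotate = TRUE, context_year = 2006L) {
  ctx <- normalization_context(
    anchor_year = context_year,
    anchor_date = partial_date(context_year, 7L, 6L)
  )
  g <- temporal_graph()
  v <- add_event(g, "vaccinated w/MMR")
  fe <- add_event(g, "fever")
  ra <- add_event(g, "macular rash")
  va <- add_event(g, "vasculitis")
  ho <- add_event(g, "patient hospitalization")

  attach_time(g, v$id, parse_time_expression("July 6^th^", ctx))
  hosp <- resolve_partial_date(parse_time_expression("08-08", ctx), ctx,
                               ordering_hint = "after_anchor")
  attach_time(g, ho$id, hosp)

  d18 <- parse_duration_expression("Eighteen days")
  d2w <- parse_duration_expression("2 wks")
  assert_relation(g, fe$id, "after", v$id, offset = d18)
  assert_relation(g, ra$id, "after", v$id, offset = d18)
  assert_relation(g, va$id, "after", fe$id, offset = d2w)
  assert_relation(g, va$id, "after", ra$id, offset = d2w)

  if (annotate) annotate_events(g)
  g
}

#' Three-report cohort illustrating the comparison patterns
#'
#' A constructed hepatitis-B cohort whose planted facts mirror the three
#' ways adverse-event timelines differ across reports: a shared symptom at
#' different day offsets (rash at day 3 vs day 8), different symptom
#' frequencies (nausea twice, once, absent) and an order reversal
#' (injection site reaction then arthralgia vs the opposite).
#'
#' @return List of three `report_record`s.
#' @export
#' @examples
#' tls <- lapply(interpretation_cohort(), report_timeline)
#' compare_timelines(tls)
interpretation_cohort <- function() {
  mk <- function(report_id, vaccinated, events) {
    anns <- list(
      list(span = "vaccinated w/HEP B", kind = "event", attributes = list(id = "v")),
      list(span = vaccinated, kind = "time", attributes = list(event = "v"))
    )
    for (i in seq_along(events)) {
      e <- events[[i]]
      eid <- sprintf("e%d", i)
      anns[[length(anns) + 1L]] <- list(span = e$label, kind = "event",
                                        attributes = list(id = eid))
      anns[[length(anns) + 1L]] <- if (e$day == 0L) {
        list(span = vaccinated, kind = "time", attributes = list(event = eid))
      } else {
        list(span = sprintf("%d days", e$day), kind = "duration",
             attributes = list(source = eid, relation = "after", target = "v"))
      }
    }
    read_report(jsonlite::toJSON(list(
      report_id = report_id,
      structured_dates = list(vaccinated = vaccinated),
      vaccines = list("HEP B"),
      symptoms = as.list(unique(vapply(events, `[[`, character(1), "label"))),
      narrative_annotations = anns
    ), auto_unbox = TRUE))
  }
  ev <- function(label, day) list(label = label, day = as.integer(day))
  list(
    mk("HEP-1", "1998-05-04", list(
      ev("injection site reaction", 1), ev("nausea", 2), ev("rash", 3),
      ev("flu-like illness", 4), ev("arthralgia", 5), ev("nausea", 6)
    )),
    mk("HEP-2", "1999-02-10", list(
      ev("arthralgia", 0), ev("injection site reaction", 1), ev("nausea", 5),
      ev("rash", 8), ev("flu-like illness", 9)
    )),
    mk("HEP-3", "2000-11-20", list(
      ev("injection site reaction", 2), ev("headache", 4)
    ))
  )
}
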