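# Seeded generator of VAERS-like report fixtures with known ground-truth
# timelines.  Each report has a vaccination anchor with an absolute date and
# k adverse events whose times are expressed either as duration offsets from
# a prior event (exercising multi-hop date inference) or as absolute,
# possibly year-less, date expressions (exercising partial-date resolution).

#' Parameters for the synthetic report generator
#'
#' @param seed Integer master seed; the whole cohort is a pure function of
#'   it (per-report substreams are derived from `(seed, index)`).
#' @param n_reports Number of reports.
#' @param n_events_range Integer `(min, max)` adverse events per report.
#' @param offsets Either `list(kind = "uniform", lo, hi)` — day offsets from
#'   the anchor drawn uniformly — or `list(kind = "fixed", values = c(...))`
#'   taking offsets positionally.
#' @param fraction_relative Proportion of events timed by a duration offset
#'   relation rather than an absolute date expression.
#' @param granularity_mix Named weights over `day` and `month` for absolute
#'   date expressions; month-granular stamps leave the day offset
#'   unresolved, as real narratives do.
#' @param symptom_pool Surface forms sampled for adverse events; defaults to
#'   the packaged lexicon's adverse-event synonyms.
#' @param anchor_date_range Character `(start, end)` ISO dates for the
#'   vaccination date.
#' @param vaccines Vaccine names sampled for the anchor.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(seed = 1L,
                             n_reports = 10L,
                             n_events_range = c(1L, 5L),
                             offsets = list(kind = "uniform", lo = 1L, hi = 30L),
                             fraction_relative = 0.5,
                             granularity_mix = c(day = 0.85, month = 0.15),
                             symptom_pool = NULL,
                             anchor_date_range = c("1990-01-01", "2009-12-01"),
                             vaccines = c("MMR", "Engerix-B", "DTP")) {
  seed <- as.integer(seed)
  n_reports <- as.integer(n_reports)
  n_events_range <- as.integer(n_events_range)
  if (n_reports < 0L) abort_invalid_input("n_reports must be >= 0")
  if (length(n_events_range) != 2L || n_events_range[1] > n_events_range[2] ||
      n_events_range[1] < 0L) {
    abort_invalid_input("n_events_range must be (min, max) with 0 <= min <= max")
  }
  if (!is.numeric(fraction_relative) || fraction_relative < 0 || fraction_relative > 1) {
    abort_invalid_input("fraction_relative must lie in [0, 1]")
  }
  if (!all(names(granularity_mix) %in% c("day", "month")) ||
      any(granularity_mix < 0) || sum(granularity_mix) <= 0) {
    abort_invalid_input("granularity_mix must be non-negative weights over day/month")
  }
  if (identical(offsets$kind, "uniform")) {
    if (offsets$lo < 1L || offsets$lo > offsets$hi) {
      abort_invalid_input("uniform offsets need 1 <= lo <= hi")
    }
  } else if (identical(offsets$kind, "fixed")) {
    if (!length(offsets$values) || any(offsets$values < 1L)) {
      abort_invalid_input("fixed offsets must be a non-empty vector of days >= 1")
    }
  } else {
    abort_invalid_input("offsets$kind must be 'uniform' or 'fixed'")
  }
  if (is.null(symptom_pool)) {
    symptom_pool <- c("rash", "nausea", "fever", "arthralgia",
                      "injection site reaction", "headache", "vomiting",
                      "FLU-LIKE SYMPTOMS", "dizziness", "urticaria")
  }
  if (!length(symptom_pool)) abort_invalid_input("symptom_pool must not be empty")
  structure(
    list(seed = seed, n_reports = n_reports, n_events_range = n_events_range,
         offsets = offsets, fraction_relative = fraction_relative,
         granularity_mix = granularity_mix / sum(granularity_mix),
         symptom_pool = symptom_pool,
         anchor_date_range = anchor_date_range, vaccines = vaccines),
    class = "generator_params"
  )
}

# run fn under a derived, restorable RNG substream
.with_substream <- function(seed, index, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((abs(seed) * 100003L + index * 7919L) %% 2147483629L)
  fn()
}

#' Generate one synthetic report with its ground-truth timeline
#'
#' The record mirrors the semi-structured shape of surveillance reports:
#' structured fields carry the vaccination/onset dates, while event times
#' live in narrative annotations (duration-offset relations chain off the
#' previous event with probability 0.5, else off the anchor).  The returned
#' truth is what full pipeline processing — [read_report()],
#' [graph_from_report()], [infer_dates()], [build_timeline()] — must
#' recover.
#'
#' @param params A [generator_params()].
#' @param index Report index (1-based); `(seed, index)` determines the
#'   report completely.
#' @return A list with `record` (a `report_record`) and `truth` (a data
#'   frame `label`, `term_key`, `date`, `day_offset` in timeline order,
#'   anchor first).
#' @export
generate_report <- function(params, index = 1L) {
  stopifnot(inherits(params, "generator_params"))
  .with_substream(params$seed, as.integer(index), function() {
    lex <- default_lexicon()
    range_start <- as.Date(params$anchor_date_range[1])
    range_end <- as.Date(params$anchor_date_range[2])
    anchor_day <- range_start + sample.int(as.integer(range_end - range_start) + 1L, 1L) - 1L
    vaccine <- params$vaccines[sample.int(length(params$vaccines), 1L)]
    k_rng <- seq(params$n_events_range[1], params$n_events_range[2])
    k <- if (length(k_rng) == 1L) k_rng else sample(k_rng, 1L)

    offs <- if (params$offsets$kind == "fixed") {
      v <- as.integer(params$offsets$values)
      v[((seq_len(k) - 1L) %% length(v)) + 1L]
    } else {
      params$offsets$lo + sample.int(params$offsets$hi - params$offsets$lo + 1L, k,
                                     replace = TRUE) - 1L
    }
    symptoms <- if (k > 0L) sample(params$symptom_pool, k, replace = TRUE) else character()

    anns <- list(
      list(span = sprintf("vaccinated w/%s", vaccine), kind = "event",
           attributes = list(id = "anchor")),
      list(span = format(anchor_day, "%m-%d-%Y"), kind = "time",
           attributes = list(event = "anchor"))
    )
    truth_rows <- list(data.frame(
      label = sprintf("vaccinated w/%s", vaccine),
      term_key = {
        t <- lookup_term(vaccine, "VO", lex)
        if (is_term_ref(t)) paste0("VO:", t$identifier) else NA_character_
      },
      date = format(partial_date(as.integer(format(anchor_day, "%Y")),
                                 as.integer(format(anchor_day, "%m")),
                                 as.integer(format(anchor_day, "%d")))),
      day_offset = 0L, stringsAsFactors = FALSE
    ))

    prev_id <- NULL; prev_off <- NA_integer_
    for (e in seq_len(k)) {
      eid <- sprintf("e%d", e)
      day <- anchor_day + offs[e]
      anns[[length(anns) + 1L]] <- list(span = symptoms[e], kind = "event",
                                        attributes = list(id = eid))
      relative <- stats::runif(1) < params$fraction_relative
      gran <- sample(names(params$granularity_mix), 1L,
                     prob = params$granularity_mix)
      term <- {
        t <- lookup_term(symptoms[e], "OAE", lex)
        if (is_term_ref(t)) paste0("OAE:", t$identifier) else NA_character_
      }
      if (relative || gran == "day") {
        # day-resolvable timing
        if (relative) {
          chain_prev <- !is.null(prev_id) && !is.na(prev_off) &&
            offs[e] > prev_off && stats::runif(1) < 0.5
          base_id <- if (chain_prev) prev_id else "anchor"
          delta <- if (chain_prev) offs[e] - prev_off else offs[e]
          span <- if (delta %% 7L == 0L && stats::runif(1) < 0.5) {
            sprintf("%d %s", delta %/% 7L, if (delta == 7L) "wk" else "wks")
          } else {
            sprintf("%d days", delta)
          }
          anns[[length(anns) + 1L]] <- list(
            span = span, kind = "duration",
            attributes = list(source = eid, relation = "after", target = base_id)
          )
        } else {
          style <- sample(3L, 1L)
          span <- switch(style,
            format(day, "%m-%d"),                      # year from the record
            format(day, "%m-%d-%y"),                   # two-digit year
            format(day, "%Y-%m-%d")                    # ISO
          )
          anns[[length(anns) + 1L]] <- list(span = span, kind = "time",
                                            attributes = list(event = eid))
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          label = symptoms[e], term_key = term,
          date = format(day, "%Y-%m-%d"), day_offset = offs[e],
          stringsAsFactors = FALSE
        )
        prev_id <- eid; prev_off <- offs[e]
      } else {
        # month-granular stamp: the day offset stays unresolved
        span <- if (stats::runif(1) < 0.5) format(day, "%B %Y") else format(day, "%Y-%m")
        anns[[length(anns) + 1L]] <- list(span = span, kind = "time",
                                          attributes = list(event = eid))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          label = symptoms[e], term_key = term,
          date = format(day, "%Y-%m"), day_offset = NA_integer_,
          stringsAsFactors = FALSE
        )
        # month-granular events cannot anchor a later chain
      }
    }

    truth <- do.call(rbind, truth_rows)
    # timeline order: the calendar-key order build_timeline defines —
    # year/month/day with missing finer components sorting first, ties by
    # narrative order
    key <- vapply(truth$date, function(d) {
      p <- as.integer(strsplit(d, "-", fixed = TRUE)[[1L]])
      p[1L] * 10000 + (if (length(p) > 1L) p[2L] * 100 else 0) +
        (if (length(p) > 2L) p[3L] else 0)
    }, numeric(1))
    truth <- truth[order(key, seq_len(nrow(truth))), , drop = FALSE]
    rownames(truth) <- NULL

    onset <- if (any(!is.na(truth$day_offset[-1]))) {
      format(anchor_day + min(truth$day_offset[-1], na.rm = TRUE), "%Y-%m-%d")
    } else {
      NULL
    }
    rec_json <- list(
      report_id = sprintf("SYN-%d-%d", params$seed, as.integer(index)),
      age = list(value = sample(1:80, 1L), unit = "year"),
      sex = sample(c("F", "M"), 1L),
      structured_dates = c(
        list(vaccinated = format(anchor_day, "%Y-%m-%d")),
        if (!is.null(onset)) list(onset = onset)
      ),
      vaccines = list(vaccine),
      symptoms = as.list(unique(symptoms)),
      narrative_annotations = anns
    )
    record <- read_report(jsonlite::toJSON(rec_json, auto_unbox = TRUE))
    list(record = record, truth = truth)
  })
}

#' Generate a cohort of synthetic reports
#'
#' All reports share `params$symptom_pool`, so [compare_timelines()] has
#' non-trivial overlap across reports.
#'
#' @param params A [generator_params()].
#' @return List of `list(record, truth)` of length `params$n_reports`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  lapply(seq_len(params$n_reports), function(i) generate_report(params, i))
}
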