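---
title: "Temporal reasoning over vaccine adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal reasoning over vaccine adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teotimer)
```

## The problem

Post-vaccination adverse-event (AE) surveillance records, such as VAERS
reports, carry two layers of temporal information. The structured fields
give a handful of dates — vaccinated, onset, submitted — while the
free-text narrative holds the clinically interesting sequence: *"18
month-old vaccinated w/MMR on July 6th. Eighteen days after vaccination she
developed a fever of 104 and macular rash. Dx: vasculitis 2 wks later.
Patient hospitalized 08-08."* Nothing in the structured block says that the
hospitalization followed the vasculitis diagnosis, or on which day the
fever started; a reader infers it. This package makes that inference
mechanical: it represents events, time stamps, durations and qualitative
temporal relations as a graph, reasons over the graph, and reduces each
report to a vaccination-anchored timeline that can be compared across
reports.

The model has four ingredients:

* **Events** — processual entities (a vaccination, a fever, a
  hospitalization) with a free-text label and optional ontology
  annotations.
* **Time entities** — instants with an original expression, a normalized
  (possibly partial) calendar date and an explicit granularity; intervals
  with start/end/duration; durations with a value and a controlled unit;
  periodic intervals for repeating events ("20 minutes 3 times/day … for 2
  weeks").
* **Temporal assertions** — one of the 13 Allen interval relations between
  two events, optionally quantified by a duration offset ("fever *after*
  vaccination, offset 18 days"), with recorded provenance (stated vs
  inferred).
* **Ontology annotations** — adverse-event (OAE), MedDRA and vaccine (VO)
  identifiers attached to events through a packaged lexicon, so that
  "FLU-LIKE SYMPTOMS" and "Influenza-like illness" are the same symptom to
  the machine.

## Qualitative reasoning

Events are modeled as intervals; an event carrying a single time instant is
a zero-width interval, so instant-to-instant comparisons degenerate to the
point relations before/equals/after. Between intervals the 13 Allen base
relations apply, closed under inversion and composition. The composition
table is not hard-coded: each relation is characterized by the ordering of
the four interval endpoints, and a cell `compose(r1, r2)` contains every
relation `r3` whose endpoint constraints are jointly satisfiable with those
of `r1` and `r2` over six endpoints. Satisfiability is decided by closing
the point-order constraints under transitivity. The test suite checks all
169 cells against an independent brute-force oracle that enumerates
concrete integer endpoint assignments.

Inference runs path consistency (PC-1 iteration to fixpoint): every edge of
the constraint network is intersected with the composition of its
two-legged detours until nothing changes. Every output edge is a subset of
its input edge (monotone), a second run changes nothing (idempotent), and
an edge that empties raises an inconsistency error citing the offending
triangle. Path consistency is the right level for report graphs, which are
short chains; it is also complete for atomic (singleton-labeled) networks.
For exact consistency verdicts `validate_graph()` additionally runs a
backtracking scenario search, bounded to graphs of at most 12 events so the
desk-scale guarantee stays cheap; larger graphs get the path-consistency
verdict.

## Quantitative reasoning: dates from offsets

A report usually anchors one event absolutely (the vaccination date) and
times the rest relatively. `infer_dates()` walks offset-bearing
before/after assertions in both directions from every dated event,
shifting calendar dates by the stated durations: July 6 + 18 days =
July 24; + 2 weeks = August 7. Chains compose associatively — a chain of
offsets equals the single summed offset — and two chains that imply
different dates for one event raise a conflict error that lists both
derivations rather than silently picking one (narrative-vs-structured-field
contradictions are surfaced, not auto-resolved).

Granularity is tracked through arithmetic. Days and weeks are
calendar-exact (a week is seven days); month and year steps move the
month/year components and clamp the day to the target month's length —
never 30- or 365-day approximations. An inferred date is only as precise as
the coarsest granularity met along its chain, and date comparison happens
at the coarser of the two granularities: two events inferred onto the same
day cannot be ordered, so their derived relation is the honest disjunction
{before, equals, after} rather than a fabricated `equals`.

Offset semantics: for "X after A offset d", d runs from the end of A to the
start of X; for the point events of these reports this is date arithmetic
on the two stamps. Whether such an offset measures start-to-start or
end-to-start is genuinely open in the annotation style we target; the
end-to-start reading matches how onset-date arithmetic is written in
narratives ("eighteen days after vaccination she developed a fever") and is
applied uniformly. "after" is implemented as strict — simultaneity is
expressed by `equals`, not by a zero-day `after`.

## Time-expression normalization

`parse_time_expression()` covers the forms that occur in these records:
month-name dates with ordinal suffixes ("July 6^th^"), numeric
month-day-year ("3-29-90"), ISO dates, and year-less month-day forms
("08-08"). The original text is preserved byte-for-byte; the normalized
value records only the precision the text supports, and the granularity
field always equals that precision. Date order is fixed to month-day-year
(these are US records; the context object makes this explicit), and
two-digit years pivot at 30 — values ≥ 30 map to 19xx — because the report
era spans the 1990s. A missing year is completed from the structured
record's vaccination date; with the `after_anchor` hint, a completed date
that would precede the anchor rolls forward one year, so a January
month-day reported after a late-December vaccination lands in the next
year. Duration parsing accepts number words (zero–twenty and the tens) and
the common unit abbreviations (wk/wks, d, min, mo, yr). Out of scope, by
design: full TIMEX3 coverage, times of day with zones, and
document-creation-time expressions ("yesterday") beyond anchor completion.

## Ontology annotation

The packaged lexicon is a flat, versioned TSV (surface, vocabulary,
identifier, preferred label), about ninety synonym rows over ~20 concepts —
not a live ontology import. Matching is exact-after-normalization
(lowercase, punctuation and hyphens collapsed, synonym-mapped); fuzzy
matching is deliberately absent so annotations stay deterministic and
auditable. When both an OAE and a MedDRA entry match, both codings are
attached rather than adjudicated — surveillance records themselves
sometimes carry the less accurate alignment (e.g. MedDRA "influenza" where
"influenza like illness" is meant), and keeping both preserves the
evidence. Only three identifiers in the lexicon are authoritative
(MedDRA 10022004 and OAE_0000100 for influenza like illness, VO_0010711 for
Engerix-B); the rest are synthetic placeholders in the correct lexical
shape, which is why the file is named `teo_lexicon_synthetic.tsv`.

## Serialization

Graphs serialize to Turtle with the annotation vocabulary (hasTime,
hasOrigTime, hasNormalizedTime, hasGranularity, hasValue, hasUnit) under a
placeholder namespace — the vocabulary's published IRIs vary between
deployments, so the namespace is configurable and predicates are matched by
local name on read. Normalized times serialize as `xsd:date`,
`xsd:gYearMonth` or `xsd:gYear` according to granularity, so partial dates
never fabricate precision. A quantified relation becomes the OWL
annotated-axiom block (an `owl:Axiom` node with
annotatedSource/annotatedProperty/annotatedTarget and a `hasTimeOffset`
duration); following the OWL convention, `annotatedSource` is the subject
of the annotated triple. Blank nodes are avoided entirely — axiom and time
nodes get skolem IRIs derived from their owners — which makes the canonical
serialization deterministic and byte-stable under write → read → write, a
property the suite tests on fixtures and random graphs. Disjunctive
relation sets live only inside the reasoner's working network; assertions
stored in a graph are always singletons, which keeps serialization total.

## Timelines and cohort comparison

`build_timeline()` anchors at the earliest vaccine-annotated (VO) event,
ties broken by narrative order, and orders entries by calendar position —
a month-granular stamp sorts at the head of its month, ties keep narrative
order — flagging events whose dates stay unresolved. Day offsets are
calendar-day differences from the anchor, `NA` when either date is coarser
than a day. `compare_timelines()` then produces the three views used in
time-trend reading: shared symptoms with per-report day offsets, per-report
symptom frequencies (zeroes included), and symptom pairs whose strict
first-occurrence order reverses between reports. Order differences only
count pairs strictly ordered (different days) in both reports — day-granular
data cannot witness intra-day reversals. Matching is by ontology term,
never by surface string.

## The synthetic generator

Real report narratives are not redistributable, so the package ships a
generator whose output has known ground truth. Each report gets a
vaccination anchor (absolute date, uniform over 1990–2009), one to five
adverse events drawn from the lexicon's symptom synonyms, and day offsets
from the anchor uniform on 1–30 days — the first weeks after vaccination
are where AE reporting concentrates. Half the events (`fraction_relative
= 0.5`) are timed by a duration relation, which chains off the previous
event with probability 0.5 (exercising multi-hop inference) and off the
anchor otherwise; the rest carry absolute expressions in mixed styles
(year-less month-day, two-digit-year, ISO). Absolute stamps are
day-granular with weight 0.85 and month-granular with weight 0.15,
reflecting that narratives occasionally date an event only to a month;
month-granular events have unresolved day offsets in the ground truth, and
the pipeline must reproduce exactly that. A single master seed determines
the whole cohort; per-report substreams are derived from `(seed, index)` so
a report is reproducible independently of generation order.

What the generator does *not* emulate: free natural-language narrative
(annotations are pre-structured spans, since NLP extraction is outside this
package's scope), epidemiologically realistic incidence rates, and
contradictory or erroneous annotations. Passing recovery tests therefore
shows the representation and reasoning are faithful to correctly annotated
input, not that the package is robust to extraction noise.

## Worked example

```{r mmr}
g <- mmr_case_graph()
validate_graph(g)$consistent
infer_dates(g)
tl <- build_timeline(g, report_id = "MMR")
tl
derive_relation(g, "event4", "event5")   # vasculitis vs hospitalization
```

The five events resolve to July 6 (vaccination), July 24 (fever and rash,
18 days later), August 7 (vasculitis, 2 weeks after that) and August 8
(hospitalization, from the narrative's "08-08" with the year completed from
the record) — whence the derived `before`: the hospitalization followed the
vasculitis diagnosis, which no single stated triple says.

```{r cohort}
tls <- lapply(interpretation_cohort(), report_timeline)
comp <- compare_timelines(tls)
comp$frequency_table
```

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale: the
full 169-cell composition check against a brute-force oracle on a 1–6
integer endpoint grid, 200 random 5-node atomic networks against a
concrete-realization oracle, round-trips over 100 random graphs, and a
20-report synthetic cohort — together well under two minutes on one CPU.
Determinism is enforced throughout: propagation iterates nodes in sorted-id
order so inferred provenance traces are reproducible, serialization order
is narrative order, and every random draw flows from an explicit seed.

Known limitations: no OWL-DL classification or external description-logic
reasoner integration; no metric constraint networks beyond single-chain
offset arithmetic (mixed-direction offset chains fall back to qualitative
reasoning); no statistical significance testing of cohort differences —
the comparison tables are descriptive, intended as input to such analyses.
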