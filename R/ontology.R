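# Ontology-based event-name normalization: surface forms are folded to a
# canonical label and mapped to adverse-event (OAE), MedDRA and vaccine (VO)
# identifiers through a packaged lexicon excerpt.  Matching is
# exact-after-normalization; no fuzzy matching, so annotations are
# deterministic and auditable.

.vocabularies <- c("OAE", "MedDRA", "VO")

.id_patterns <- c(OAE = "^OAE_\\d{7}$", MedDRA = "^\\d{8}$", VO = "^VO_\\d{7}$")

#' Reference to an ontology term
#'
#' @param vocabulary `"OAE"`, `"MedDRA"` or `"VO"`.
#' @param identifier Vocabulary-scoped id: `OAE_`-prefixed, an 8-digit
#'   MedDRA code, or `VO_`-prefixed.
#' @param preferred_label The term's canonical text.
#' @return An object of class `term_ref`.
#' @export
#' @examples
#' term_ref("MedDRA", "10022004", "influenza like illness")
term_ref <- function(vocabulary, identifier, preferred_label) {
  if (!vocabulary %in% .vocabularies) {
    abort_invalid_input(sprintf(
      "unknown vocabulary %s; expected one of %s",
      dQuote(vocabulary), paste(.vocabularies, collapse = ", ")
    ))
  }
  identifier <- as.character(identifier)
  if (!nzchar(identifier) || !grepl(.id_patterns[[vocabulary]], identifier)) {
    abort_invalid_input(sprintf(
      "identifier %s does not match the %s id pattern",
      dQuote(identifier), vocabulary
    ))
  }
  structure(list(vocabulary = vocabulary, identifier = identifier,
                 preferred_label = preferred_label),
            class = "term_ref")
}

is_term_ref <- function(x) inherits(x, "term_ref")

#' @export
format.term_ref <- function(x, ...) {
  sprintf("%s:%s (%s)", x$vocabulary, x$identifier, x$preferred_label)
}

#' @export
print.term_ref <- function(x, ...) {
  cat("<term>", format(x), "\n")
  invisible(x)
}

#' Marker for a surface form with no lexicon entry
#' @param label The normalized label that failed to map.
#' @param vocabulary The vocabulary that was searched.
#' @return An object of class `unmapped_term`.
#' @export
unmapped_term <- function(label, vocabulary) {
  structure(list(label = label, vocabulary = vocabulary), class = "unmapped_term")
}

#' @export
format.unmapped_term <- function(x, ...) {
  sprintf("unmapped in %s: %s", x$vocabulary, dQuote(x$label))
}

#' @export
print.unmapped_term <- function(x, ...) {
  cat("<unmapped>", format(x), "\n")
  invisible(x)
}

#' Load a term lexicon from TSV
#'
#' The file has columns `surface`, `vocabulary`, `identifier`,
#' `preferred_label`; one row per surface-form-to-term mapping, with synonym
#' surfaces repeated across rows.  The same surface may map into several
#' vocabularies (an adverse event keeps both its OAE and MedDRA codings).
#'
#' @param path Path to the TSV; defaults to the packaged lexicon excerpt
#'   (see [default_lexicon()]).
#' @return An object of class `teo_lexicon`.
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  need <- c("surface", "vocabulary", "identifier", "preferred_label")
  if (!all(need %in% names(tab))) {
    abort_structural(sprintf("lexicon must have columns: %s",
                             paste(need, collapse = ", ")))
  }
  tab$surface_norm <- vapply(tab$surface, .fold_label, character(1))
  # every preferred label must resolve to its own term
  for (k in seq_len(nrow(tab))) {
    pl <- .fold_label(tab$preferred_label[k])
    hit <- tab$surface_norm == pl & tab$vocabulary == tab$vocabulary[k]
    if (!any(hit)) {
      abort_structural(sprintf(
        "preferred label %s has no surface row in vocabulary %s",
        dQuote(tab$preferred_label[k]), tab$vocabulary[k]
      ))
    }
  }
  # canonical label per surface: the MedDRA preferred label when the concept
  # has one, else the first row's
  canon <- new.env(parent = emptyenv())
  for (s in unique(tab$surface_norm)) {
    rows <- tab[tab$surface_norm == s, , drop = FALSE]
    pick <- if (any(rows$vocabulary == "MedDRA")) {
      rows$preferred_label[rows$vocabulary == "MedDRA"][1]
    } else {
      rows$preferred_label[1]
    }
    assign(s, .fold_label(pick), envir = canon)
  }
  structure(list(table = tab, canonical = canon), class = "teo_lexicon")
}

#' @export
print.teo_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d surface rows, %d concepts\n",
              nrow(x$table), length(unique(x$table$identifier))))
  invisible(x)
}

#' The packaged lexicon excerpt
#'
#' A small, versioned excerpt covering the adverse-event, MedDRA and vaccine
#' terms this package's examples and fixtures use.  Only the identifiers for
#' influenza like illness (MedDRA 10022004, OAE_0000100) and Engerix-B
#' (VO_0010711) are authoritative; all other identifiers are synthetic
#' placeholders in the correct lexical shape, standing in for the full
#' ontologies, which are not shipped.
#'
#' @return A `teo_lexicon`.
#' @export
default_lexicon <- function() {
  if (is.null(.teo_cache$lexicon)) {
    path <- system.file("extdata", "teo_lexicon_synthetic.tsv",
                        package = "teotimer", mustWork = TRUE)
    .teo_cache$lexicon <- read_lexicon(path)
  }
  .teo_cache$lexicon
}

# case folding + punctuation/hyphen collapse
.fold_label <- function(surface) {
  s <- tolower(surface)
  s <- gsub("[^a-z0-9]+", " ", s)
  trimws(gsub(" +", " ", s))
}

#' Normalize an event surface form to its canonical label
#'
#' Lowercases, collapses punctuation and hyphens to spaces, and maps known
#' synonyms onto their canonical label, so that "FLU-LIKE SYMPTOMS",
#' "Influenza-like illness" and "flu-like illness" all become
#' "influenza like illness".  Idempotent; unknown forms pass through folded
#' but unmapped.
#'
#' @param surface Non-empty text.
#' @param lexicon A `teo_lexicon`; the packaged excerpt by default.
#' @return The canonical label.
#' @export
#' @examples
#' normalize_label("FLU-LIKE SYMPTOMS")
normalize_label <- function(surface, lexicon = default_lexicon()) {
  if (!is.character(surface) || length(surface) != 1L || is.na(surface) ||
      !nzchar(trimws(surface))) {
    abort_invalid_input("surface form must be a non-empty string")
  }
  s <- .fold_label(surface)
  if (exists(s, envir = lexicon$canonical, inherits = FALSE)) {
    get(s, envir = lexicon$canonical, inherits = FALSE)
  } else {
    s
  }
}

#' Look a label up in one vocabulary
#'
#' Normalization is applied before lookup; the result is deterministic.
#'
#' @param label Non-empty text.
#' @param vocabulary `"OAE"`, `"MedDRA"` or `"VO"`.
#' @param lexicon A `teo_lexicon`.
#' @return A [term_ref()], or an [unmapped_term()] marker carrying the
#'   normalized label.
#' @export
#' @examples
#' lookup_term("influenza like illness", "MedDRA")
#' lookup_term("Engerix-B", "VO")
lookup_term <- function(label, vocabulary, lexicon = default_lexicon()) {
  if (!vocabulary %in% .vocabularies) {
    abort_invalid_input(sprintf("unknown vocabulary %s", dQuote(vocabulary)))
  }
  norm <- normalize_label(label, lexicon)
  tab <- lexicon$table
  hit <- tab[tab$surface_norm == norm & tab$vocabulary == vocabulary, , drop = FALSE]
  if (nrow(hit) == 0L) {
    # the canonical label may itself be a surface
    folded <- .fold_label(label)
    hit <- tab[tab$surface_norm == folded & tab$vocabulary == vocabulary, , drop = FALSE]
  }
  if (nrow(hit) == 0L) return(unmapped_term(norm, vocabulary))
  term_ref(vocabulary, hit$identifier[1], hit$preferred_label[1])
}

# all term_refs (every vocabulary) for one surface
.lookup_all <- function(label, lexicon) {
  norm <- normalize_label(label, lexicon)
  tab <- lexicon$table
  hit <- tab[tab$surface_norm == norm | tab$surface_norm == .fold_label(label), , drop = FALSE]
  hit <- hit[!duplicated(paste(hit$vocabulary, hit$identifier)), , drop = FALSE]
  lapply(seq_len(nrow(hit)), function(k) {
    term_ref(hit$vocabulary[k], hit$identifier[k], hit$preferred_label[k])
  })
}

#' Annotate a temporal graph's events against a lexicon
#'
#' Each event's annotation list is extended with every lexicon match for its
#' label (an adverse event keeps both its OAE and MedDRA codings when both
#' exist).  Unmatched labels are flagged `unmapped` and kept verbatim; no
#' event is removed or relabeled.
#'
#' @param graph A [temporal_graph()]; updated in place.
#' @param lexicon A `teo_lexicon`.
#' @return The graph, invisibly.
#' @export
annotate_events <- function(graph, lexicon = default_lexicon()) {
  stopifnot(is_temporal_graph(graph))
  for (id in event_ids(graph)) {
    ev <- graph$events[[id]]
    terms <- .lookup_all(ev$label, lexicon)
    have <- vapply(ev$annotations, function(t) paste(t$vocabulary, t$identifier),
                   character(1))
    for (t in terms) {
      key <- paste(t$vocabulary, t$identifier)
      if (!key %in% have) {
        ev$annotations[[length(ev$annotations) + 1L]] <- t
        have <- c(have, key)
      }
    }
    ev$unmapped <- length(ev$annotations) == 0L
    graph$events[[id]] <- ev
  }
  invisible(graph)
}
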