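# Classed conditions so callers can branch on failure kind rather than on
# message text.  Every error signalled by this package inherits "teo_error".

teo_abort <- function(class, message, ..., call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "teo_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

abort_invalid_input <- function(message, ...) teo_abort("teo_invalid_input", message, ...)
abort_not_found     <- function(message, ...) teo_abort("teo_not_found", message, ...)
abort_conflict      <- function(message, ...) teo_abort("teo_conflict", message, ...)
abort_parse         <- function(message, ...) teo_abort("teo_parse_error", message, ...)
abort_structural    <- function(message, ...) teo_abort("teo_structural_error", message, ...)
abort_inconsistency <- function(message, ...) teo_abort("teo_inconsistency", message, ...)
abort_ambiguity     <- function(message, ...) teo_abort("teo_ambiguity", message, ...)
abort_not_periodic  <- function(message, ...) teo_abort("teo_not_periodic", message, ...)
abort_anchor        <- function(message, ...) teo_abort("teo_anchor_error", message, ...)
abort_annotation    <- function(message, ...) teo_abort("teo_annotation_error", message, ...)
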