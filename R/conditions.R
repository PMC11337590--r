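# Typed conditions used across the package. Every malformed input raises one
# of these; nothing is silently dropped.

abort_typed <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "equicatch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
abort_schema <- function(msg, ...) abort_typed("equicatch_schema_error", msg, ...)

#' @noRd
abort_validation <- function(msg, ...) abort_typed("equicatch_validation_error", msg, ...)

#' @noRd
abort_config <- function(msg, ...) abort_typed("equicatch_config_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
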