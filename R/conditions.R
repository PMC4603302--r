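# Structured error conditions used throughout the pipeline. Every error is a
# subclass of "flux_error" so callers can catch the whole family, and each
# pipeline stage raises its own subclass so failures are attributable.

flux_abort <- function(subclass, message, ..., call = NULL) {
  cond <- structure(
    class = c(subclass, "flux_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @rdname flux-conditions
#' @param message Human-readable description of the failure.
#' @param ... Additional condition fields (stored on the condition object).
#' @export
config_error <- function(message, ...) flux_abort("flux_config_error", message, ...)

#' @rdname flux-conditions
#' @export
poll_error <- function(message, ...) flux_abort("flux_poll_error", message, ...)

#' @rdname flux-conditions
#' @export
extract_error <- function(message, ...) flux_abort("flux_extract_error", message, ...)

#' @rdname flux-conditions
#' @export
detection_error <- function(message, ...) flux_abort("flux_detection_error", message, ...)

#' @rdname flux-conditions
#' @export
render_error <- function(message, ...) flux_abort("flux_render_error", message, ...)

#' @rdname flux-conditions
#' @export
auth_error <- function(message, ...) flux_abort("flux_auth_error", message, ...)

#' @rdname flux-conditions
#' @export
validation_error <- function(message, ...) flux_abort("flux_validation_error", message, ...)

#' Pipeline error conditions
#'
#' Constructors for the structured conditions raised by the framework:
#' configuration mistakes (`config_error`), unreachable origin resources
#' (`poll_error`, retriable), unparseable content (`extract_error`), cache
#' backend failures (`detection_error`), template rendering failures
#' (`render_error`), authentication failures (`auth_error`), invalid pushed
#' payloads (`validation_error`) and unknown entities (`not_found_error`).
#' All inherit from class `flux_error`.
#'
#' @name flux-conditions
#' @export
not_found_error <- function(message, ...) flux_abort("flux_not_found_error", message, ...)

is_flux_error <- function(x, subclass = NULL) {
  inherits(x, if (is.null(subclass)) "flux_error" else paste0("flux_", subclass))
}
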