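# Log engine: every pipeline step appends at least one entry. Entries carry
# the minimal set of information required to re-enact a transaction: a
# timestamp, the origin and destination of the step, a message and a status.
# The store is append-only; entries are never mutated or removed.

#' Append a log entry
#'
#' @param ws A [flux_workspace()].
#' @param origin,destination Component or resource names for the step, e.g.
#'   `"agent:a1"` and `"detector"`.
#' @param message Free-text description of what happened.
#' @param status One of `"ok"`, `"warning"`, `"error"`.
#' @return The entry, invisibly.
#' @export
flux_log <- function(ws, origin, destination, message, status = c("ok", "warning", "error")) {
  status <- match.arg(status)
  entry <- list(
    timestamp = ws$clock(),
    origin = origin,
    destination = destination,
    message = message,
    status = status
  )
  ws$log[[length(ws$log) + 1L]] <- entry
  if (!ws$quiet) {
    message(sprintf("[%s] %s -> %s: %s (%s)",
                    format(entry$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    origin, destination, message, status))
  }
  invisible(entry)
}

#' Retrieve the log as a data frame
#'
#' @param ws A [flux_workspace()].
#' @return A data frame with columns `timestamp`, `origin`, `destination`,
#'   `message`, `status`, in append order.
#' @export
get_log <- function(ws) {
  if (!length(ws$log)) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      origin = character(), destination = character(),
                      message = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    timestamp = do.call(c, lapply(ws$log, `[[`, "timestamp")),
    origin = vapply(ws$log, `[[`, "", "origin"),
    destination = vapply(ws$log, `[[`, "", "destination"),
    message = vapply(ws$log, `[[`, "", "message"),
    status = vapply(ws$log, `[[`, "", "status"),
    stringsAsFactors = FALSE
  )
}
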