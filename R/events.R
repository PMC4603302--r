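# Events are the outcome of monitoring: one atomic unit of detected change
# carrying everything needed to finalize its delivery — the payload (selector
# key -> string), the originating agent, a timestamp and the fingerprint
# under which it was cached.

new_event <- function(ws, agent, record_values, fp) {
  structure(
    list(id = next_id(ws, "event"), agent_id = agent$id,
         created_at = ws$clock(),
         payload = lapply(record_values, as.character),
         fingerprint = fp),
    class = "flux_event"
  )
}

#' Create events from newly detected records
#'
#' Pure construction: one event per record, order-preserving, timestamped
#' with the workspace clock. Records must already have passed change
#' detection.
#'
#' @param ws A [flux_workspace()].
#' @param agent The originating agent.
#' @param new_records Records returned by [detect_new()].
#' @return List of `flux_event` objects.
#' @export
create_events <- function(ws, agent, new_records) {
  events <- lapply(new_records, function(rec) {
    new_event(ws, agent, rec$values, fingerprint(rec, agent$cache_key))
  })
  if (length(events)) {
    flux_log(ws, "detector", paste0("agent:", agent$id),
             sprintf("generated %d event(s)", length(events)), "ok")
  }
  events
}

#' Serialize events to and from JSON
#'
#' @param event A `flux_event`.
#' @param x A JSON string or parsed list.
#' @return `event_to_json` returns a JSON string; `event_from_json` the event.
#' @export
event_to_json <- function(event) {
  jsonlite::toJSON(
    list(id = event$id, agent_id = event$agent_id,
         created_at = format(event$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         payload = event$payload, fingerprint = event$fingerprint),
    auto_unbox = TRUE
  )
}

#' @rdname event_to_json
#' @export
event_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  structure(
    list(id = x$id, agent_id = x$agent_id,
         created_at = as.POSIXct(x$created_at, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         payload = lapply(x$payload, as.character),
         fingerprint = x$fingerprint),
    class = "flux_event"
  )
}

#' @export
print.flux_event <- function(x, ...) {
  cat(sprintf("<flux_event %s> agent=%s fingerprint=%s\n  %s\n",
              x$id, x$agent_id, x$fingerprint,
              paste(sprintf("%s=%s", names(x$payload), unlist(x$payload)),
                    collapse = ", ")))
  invisible(x)
}

#' Define an integration
#'
#' Integrations bind agents to templates many-to-many: every event from any
#' member agent is delivered once per member template, defining the data's
#' origin and destination.
#'
#' @param id,name Identifier and display name.
#' @param agent_ids,template_ids Character vectors; both must be non-empty
#'   when the integration is enabled.
#' @param enabled Disabled integrations route nothing.
#' @return An object of class `flux_integration`.
#' @export
integration <- function(id, agent_ids, template_ids, name = id, enabled = TRUE) {
  agent_ids <- unique(as.character(agent_ids))
  template_ids <- unique(as.character(template_ids))
  if (isTRUE(enabled) && (!length(agent_ids) || !length(template_ids))) {
    config_error("an enabled integration needs at least one agent and one template")
  }
  structure(list(id = as.character(id), name = as.character(name),
                 agent_ids = agent_ids, template_ids = template_ids,
                 enabled = isTRUE(enabled)),
            class = "flux_integration")
}

#' Route an event to its destinations
#'
#' The central flow manager: finds every enabled integration containing the
#' event's agent and delivers the event once per template of each, pushing
#' events iteratively (one delivery per event-template pair). Deliveries for
#' one event run sequentially in template-id order within each integration;
#' a failing delivery is reported and logged but never aborts the remaining
#' deliveries. An event whose agent belongs to no enabled integration is
#' logged as a warning and routed nowhere.
#'
#' @param ws A [flux_workspace()].
#' @param event A `flux_event`.
#' @return List of delivery reports (see [deliver()]), one per
#'   integration-template pair.
#' @export
route <- function(ws, event) {
  hits <- Filter(function(ig) ig$enabled && event$agent_id %in% ig$agent_ids,
                 ws$integrations)
  if (!length(hits)) {
    flux_log(ws, "router", paste0("agent:", event$agent_id),
             sprintf("event %s matches no enabled integration", event$id),
             "warning")
    return(list())
  }
  reports <- list()
  for (ig in hits) {
    for (tid in sort(ig$template_ids, method = "radix")) {
      tpl <- get_template(ws, tid)
      flux_log(ws, "router", paste0("template:", tid),
               sprintf("forwarding event %s via integration %s", event$id, ig$id),
               "ok")
      reports[[length(reports) + 1L]] <- deliver(ws, event, tpl)
    }
  }
  reports
}

#' Push an event directly into the platform
#'
#' The passive integration path: origin systems post new data straight to
#' the platform instead of being polled, skipping the content-detection
#' sub-sequence. The payload becomes an event exactly as a detected record
#' would, its fingerprint is registered in the agent's cache scope (so a
#' later poll of the same source does not re-deliver the same content), and
#' the event is routed normally.
#'
#' @param ws A [flux_workspace()].
#' @param agent_id Target agent id; must exist.
#' @param payload Named list/character vector; keys must be a subset of the
#'   agent's declared selector keys.
#' @return List of delivery reports, as from [route()].
#' @export
push_event <- function(ws, agent_id, payload) {
  agent <- get_agent(ws, agent_id)
  payload <- lapply(as.list(payload), as.character)
  unknown <- setdiff(names(payload), names(agent$selectors))
  if (length(unknown) || is.null(names(payload)) || !length(payload)) {
    validation_error(paste0("payload keys must match agent selectors; unknown: ",
                            toString(unknown)))
  }
  fp <- fingerprint(payload, agent$cache_key)
  cache_check_insert(ws$cache, agent$id, fp, now = ws$clock())
  event <- new_event(ws, agent, payload, fp)
  flux_log(ws, paste0("push:agent:", agent_id), "router",
           sprintf("accepted pushed event %s", event$id), "ok")
  route(ws, event)
}
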