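#' Monitor an agent's resource for changes
#'
#' One full detection pass over one concrete agent: poll the origin, extract
#' records with the format-specific detector, keep the records whose
#' fingerprints are new to the agent's cache scope, and turn exactly those
#' into events. On an unchanged resource this yields no events, and nothing
#' is ever cached from a failed poll or extraction (those errors propagate
#' before the cache is touched).
#'
#' @param ws A [flux_workspace()].
#' @param agent A concrete [agent_config()] (seed placeholders already
#'   expanded; see [expand_seeds()]).
#' @return List of `flux_event` objects, in source record order.
#' @export
monitor <- function(ws, agent) {
  content <- poll(ws, agent)
  records <- extract(ws, content, agent)
  new_records <- detect_new(ws, agent, records)
  events <- create_events(ws, agent, new_records)
  ws$last_run[[agent$id]] <- ws$clock()
  events
}

#' Run an agent end to end
#'
#' Expands the agent over its seeds (if any), monitors every concrete agent
#' and routes each resulting event to its destinations through the enabled
#' integrations. This is the complete polling pipeline, from origin to
#' destination.
#'
#' @param ws A [flux_workspace()].
#' @param agent An [agent_config()] registered in the workspace (or passed
#'   directly).
#' @return Invisibly, `list(events = <all events>, reports = <all delivery
#'   reports>)`.
#' @export
run_agent <- function(ws, agent) {
  if (is.character(agent)) agent <- get_agent(ws, agent)
  concrete <- if (length(agent$seed_refs)) expand_seeds(ws, agent) else list(agent)
  events <- list()
  reports <- list()
  for (ag in concrete) {
    evs <- monitor(ws, ag)
    for (ev in evs) {
      reports <- c(reports, route(ws, ev))
    }
    events <- c(events, evs)
  }
  invisible(list(events = events, reports = reports))
}

#' Run an integration once
#'
#' Executes the full monitoring-and-delivery sequence for every member agent
#' of one integration. Disabled integrations run nothing (logged as a
#' warning).
#'
#' @param ws A [flux_workspace()].
#' @param id Integration id.
#' @return Invisibly, as [run_agent()], aggregated over member agents.
#' @export
run_integration <- function(ws, id) {
  ig <- get_integration(ws, id)
  if (!ig$enabled) {
    flux_log(ws, "router", paste0("integration:", id),
             "integration disabled; nothing to run", "warning")
    return(invisible(list(events = list(), reports = list())))
  }
  out <- list(events = list(), reports = list())
  for (aid in ig$agent_ids) {
    res <- run_agent(ws, get_agent(ws, aid))
    out$events <- c(out$events, res$events)
    out$reports <- c(out$reports, res$reports)
  }
  invisible(out)
}
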