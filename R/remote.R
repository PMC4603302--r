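# Remote (client-side) agents. The agent runs where the data live; only
# fingerprints and new payloads cross the wire. The client polls and
# extracts locally, asks the server which fingerprints are new via the
# check endpoint, and initiates delivery for exactly those records through
# the push endpoint — so remote and local monitoring produce identical
# destination contents.

#' API transports
#'
#' A transport is a function `(method, path, token, body)` returning the
#' parsed JSON response (an error with the HTTP status is raised for
#' non-2xx answers). `local_transport()` drives a [flux_app()] handler in
#' process; `http_transport()` speaks to a remote server over HTTP.
#'
#' @param app A handler from [flux_app()].
#' @param base_url Server base URL, e.g. `"http://localhost:8321"`.
#' @param http HTTP backend (see [http_curl_backend()]).
#' @return A transport function.
#' @export
local_transport <- function(app) {
  function(method, path, token, body = NULL) {
    res <- app(list(
      method = method, path = path,
      headers = list(Authorization = paste("Token", token)),
      body = if (is.null(body)) NULL else
        as.character(jsonlite::toJSON(body, auto_unbox = TRUE))
    ))
    parsed <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
    if (res$status >= 400L) {
      cls <- switch(as.character(res$status),
                    "400" = validation_error, "401" = auth_error,
                    "403" = auth_error, "404" = not_found_error,
                    poll_error)
      cls(paste0("API error ", res$status, ": ", parsed$error %||% "unknown"),
          http_status = res$status)
    }
    parsed
  }
}

#' @rdname local_transport
#' @export
http_transport <- function(base_url, http = http_curl_backend()) {
  base_url <- sub("/+$", "", base_url)
  function(method, path, token, body = NULL) {
    res <- http(method, paste0(base_url, path),
                body = if (is.null(body)) NULL else
                  as.character(jsonlite::toJSON(body, auto_unbox = TRUE)),
                content_type = "application/json",
                headers = list(Authorization = paste("Token", token)))
    parsed <- tryCatch(jsonlite::fromJSON(res$body, simplifyVector = FALSE),
                       error = function(e) list())
    if (res$status >= 400L) {
      auth_or <- if (res$status %in% c(401L, 403L)) auth_error else
        if (res$status == 400L) validation_error else
        if (res$status == 404L) not_found_error else poll_error
      auth_or(paste0("API error ", res$status, ": ", parsed$error %||% "unknown"),
              http_status = res$status)
    }
    parsed
  }
}

#' Run a remote agent once
#'
#' Executes one distributed monitoring pass: poll and extract at the client,
#' verify fingerprints against the server's cache scope through the API, and
#' push the payloads of exactly the new records for delivery. Within a
#' batch, repeated fingerprints count once (first occurrence wins), matching
#' server-side detection.
#'
#' @param client_ws A client-side [flux_workspace()] (supplies the HTTP
#'   backend for polling and the local log; its cache is not used).
#' @param agent The [agent_config()] to run; seed expansion happens
#'   client-side via [expand_seeds()] when `seed_refs` are set and the seeds
#'   are registered in `client_ws`.
#' @param transport A transport from [local_transport()] or
#'   [http_transport()].
#' @param token The user's access token.
#' @return Invisibly, `list(pushed = <n events pushed>, deliveries =
#'   <per-delivery summaries>)`.
#' @export
run_remote_agent <- function(client_ws, agent, transport, token) {
  concrete <- if (length(agent$seed_refs)) {
    expand_seeds(client_ws, agent)
  } else {
    list(agent)
  }
  pushed <- 0L
  deliveries <- list()
  for (ag in concrete) {
    records <- extract(client_ws, poll(client_ws, ag), ag)
    fps <- vapply(records, fingerprint, "", cache_key = ag$cache_key)
    resp <- transport("POST", paste0("/api/agents/", ag$id, "/check"), token,
                      list(fingerprints = as.list(fps)))
    new_fps <- as.character(unlist(resp$new))
    seen <- character()
    for (i in seq_along(records)) {
      if (fps[[i]] %in% new_fps && !fps[[i]] %in% seen) {
        seen <- c(seen, fps[[i]])
        ans <- transport("POST", paste0("/api/agents/", ag$id, "/events"), token,
                         list(payload = records[[i]]$values))
        pushed <- pushed + 1L
        deliveries <- c(deliveries, ans$deliveries)
      }
    }
  }
  flux_log(client_ws, paste0("remote-agent:", agent$id), "api",
           sprintf("pushed %d new event(s)", pushed), "ok")
  invisible(list(pushed = pushed, deliveries = deliveries))
}
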