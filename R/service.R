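# Service layer: the framework's HTTP surface. Two endpoints exist — remote
# fingerprint verification and direct event push — and every route requires
# a user access token; there is no anonymous route. The app is an
# in-process request handler (method/path/headers/body in, status/body
# out), so the full HTTP contract is exercisable without sockets; a thin
# httpuv runner serves the same handler over real HTTP.

token_alphabet <- c(letters, 0:9)

#' Generate a user access token
#'
#' Tokens are unique 32-character strings over `[a-z0-9]`, drawn from a
#' cryptographically strong random source. A token grants access only to
#' its owner's agents; users may hold several tokens and revoke any of
#' them.
#'
#' @param ws A [flux_workspace()].
#' @param owner Owning user id.
#' @return The token string (also registered in the workspace).
#' @export
generate_token <- function(ws, owner) {
  repeat {
    bytes <- as.integer(openssl::rand_bytes(32))
    token <- paste(token_alphabet[(bytes %% length(token_alphabet)) + 1L],
                   collapse = "")
    if (is.null(ws$tokens[[token]])) break
  }
  ws$tokens[[token]] <- list(token = token, owner = as.character(owner),
                             revoked = FALSE, created_at = ws$clock())
  token
}

#' @rdname generate_token
#' @param token The token string to revoke.
#' @export
revoke_token <- function(ws, token) {
  if (is.null(ws$tokens[[token]])) not_found_error("unknown token")
  ws$tokens[[token]]$revoked <- TRUE
  invisible(TRUE)
}

authenticate <- function(ws, token) {
  entry <- if (is.null(token)) NULL else ws$tokens[[token]]
  if (is.null(entry) || entry$revoked) {
    auth_error("invalid or revoked access token", http_status = 401L)
  }
  entry$owner
}

authorize_agent <- function(ws, owner, agent_id) {
  agent <- get_agent(ws, agent_id)
  if (!identical(agent$owner, owner)) {
    auth_error(paste0("token does not own agent ", agent_id),
               http_status = 403L)
  }
  agent
}

#' Remote-agent fingerprint verification
#'
#' The server half of distributed monitoring: a remote agent extracts and
#' fingerprints records where the data live, then asks the server which
#' fingerprints are unseen. The new subset is returned and atomically
#' cached, exactly as in local detection.
#'
#' @param ws A [flux_workspace()].
#' @param token A valid access token owning the agent.
#' @param agent_id Agent whose cache scope is checked.
#' @param fingerprints Character vector.
#' @return Character vector of new fingerprints.
#' @export
api_check <- function(ws, token, agent_id, fingerprints) {
  owner <- authenticate(ws, token)
  authorize_agent(ws, owner, agent_id)
  check_fingerprints(ws, agent_id, fingerprints)
}

#' Push an event through the API
#'
#' Token-authenticated wrapper over [push_event()]: the pushed payload skips
#' content detection entirely and enters the pipeline at routing, exactly as
#' Fig. 2's passive path. Returns one status entry per attempted delivery.
#'
#' @inheritParams api_check
#' @param payload Named list of strings; keys must be declared agent
#'   selector keys.
#' @return List of `list(template_id, status, detail)` summaries.
#' @export
api_push <- function(ws, token, agent_id, payload) {
  owner <- authenticate(ws, token)
  authorize_agent(ws, owner, agent_id)
  reports <- push_event(ws, agent_id, payload)
  lapply(reports, function(r) {
    list(template_id = r$template_id, status = r$status, detail = r$detail)
  })
}

json_response <- function(status, data) {
  list(status = as.integer(status),
       body = as.character(jsonlite::toJSON(data, auto_unbox = TRUE, null = "null")))
}

#' Build the service request handler
#'
#' Returns a handler `function(req)` where `req` is
#' `list(method, path, headers, body)` and the result is
#' `list(status, body)` with a JSON body. Routes:
#'
#' * `POST /api/agents/<id>/check` — body `{"fingerprints": [...]}`, answers
#'   `{"new": [...]}`.
#' * `POST /api/agents/<id>/events` — body `{"payload": {...}}`, answers
#'   `{"deliveries": [...]}`.
#'
#' Authentication uses the `Authorization: Token <value>` header. Error
#' mapping: malformed payloads 400, missing/revoked tokens 401, foreign
#' agents 403, unknown agents or routes 404.
#'
#' @param ws A [flux_workspace()].
#' @return The handler function, usable directly in tests or served over
#'   HTTP with [flux_serve()].
#' @export
flux_app <- function(ws) {
  function(req) {
    token <- NULL
    auth <- req$headers[["Authorization"]] %||% req$headers[["authorization"]]
    if (!is.null(auth) && grepl("^Token ", auth)) {
      token <- sub("^Token ", "", auth)
    }
    m <- regmatches(req$path,
                    regexec("^/api/agents/([^/]+)/(check|events)$", req$path))[[1]]
    tryCatch({
      if (length(m) != 3L) not_found_error(paste0("no such route: ", req$path))
      if (!identical(req$method, "POST")) {
        validation_error("only POST is supported on this route")
      }
      agent_id <- m[[2]]
      body <- tryCatch(
        jsonlite::fromJSON(req$body %||% "{}", simplifyVector = FALSE),
        error = function(e) validation_error("request body is not valid JSON"))
      if (identical(m[[3]], "check")) {
        fps <- as.character(unlist(body$fingerprints))
        new <- api_check(ws, token, agent_id, fps)
        json_response(200L, list(new = as.list(new)))
      } else {
        if (is.null(body$payload)) validation_error("missing `payload` field")
        summaries <- api_push(ws, token, agent_id, body$payload)
        json_response(200L, list(deliveries = summaries))
      }
    },
    flux_validation_error = function(e) json_response(400L, list(error = conditionMessage(e))),
    flux_auth_error = function(e) {
      json_response(e$http_status %||% 401L, list(error = conditionMessage(e)))
    },
    flux_not_found_error = function(e) json_response(404L, list(error = conditionMessage(e))),
    flux_error = function(e) json_response(500L, list(error = conditionMessage(e))))
  }
}

#' Serve the API over HTTP
#'
#' Thin runner mounting the [flux_app()] handler on an httpuv server.
#' Transport security (TLS) is delegated to the deployment in front of the
#' service. Requires the `httpuv` package.
#'
#' @param ws A [flux_workspace()].
#' @param host,port Bind address.
#' @return The httpuv server handle (running in the background; stop with
#'   `httpuv::stopServer()`).
#' @export
flux_serve <- function(ws, host = "127.0.0.1", port = 8321L) {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    config_error("the httpuv package is required to serve over HTTP")
  }
  app <- flux_app(ws)
  httpuv::startServer(host, port, list(
    call = function(req) {
      body <- tryCatch(rawToChar(req$rook.input$read()), error = function(e) "")
      res <- app(list(
        method = req$REQUEST_METHOD,
        path = req$PATH_INFO,
        headers = list(Authorization = req$HTTP_AUTHORIZATION),
        body = body
      ))
      list(status = res$status,
           headers = list("Content-Type" = "application/json"),
           body = res$body)
    }
  ))
}
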