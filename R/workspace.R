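#' Create an integration workspace
#'
#' The workspace is the central mutable state of the framework: it holds the
#' registered agents, seeds, templates and integrations, the fingerprint
#' cache, the append-only log, access tokens, per-agent run bookkeeping and
#' the application settings (schedule list, worker limit). All pipeline
#' functions take a workspace as their first argument.
#'
#' The workspace also carries the injection points that make the framework
#' testable and deployable: a `clock` (a zero-argument function returning the
#' current [POSIXct] time, UTC), an `http` backend used both for polling HTTP
#' origins and for URL deliveries, and an `email` transport. Defaults are the
#' system clock, a curl-based HTTP backend and an in-process capture sink.
#'
#' @param cache A cache backend created by [cache_memory()] or
#'   [cache_sqlite()]. Stores one fingerprint per detected record, scoped per
#'   agent, and is the basis of idempotent change detection.
#' @param root Workspace root directory for file deliveries. Rendered file
#'   paths are confined to this directory.
#' @param settings Application settings as returned by [default_settings()].
#' @param clock Zero-argument function returning the current time (POSIXct).
#' @param http HTTP backend: `function(method, url, body, content_type,
#'   headers)` returning `list(status, body)`. See [http_curl_backend()].
#' @param email Email transport: a function receiving the composed message
#'   list. See [email_capture_transport()].
#' @param quiet Suppress mirroring of log entries to the console stream.
#' @return An object of class `flux_workspace`.
#' @examples
#' ws <- flux_workspace(root = tempfile("wsroot"))
#' ws
#' @export
flux_workspace <- function(cache = cache_memory(),
                           root = file.path(tempdir(), "flux-workspace"),
                           settings = default_settings(),
                           clock = utc_clock,
                           http = http_curl_backend(),
                           email = email_capture_transport(),
                           quiet = TRUE) {
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  ws <- new.env(parent = emptyenv())
  ws$agents <- list()
  ws$seeds <- list()
  ws$templates <- list()
  ws$integrations <- list()
  ws$tokens <- new.env(parent = emptyenv())
  ws$cache <- cache
  ws$root <- normalizePath(root)
  ws$settings <- validate_settings(settings)
  ws$clock <- clock
  ws$http <- http
  ws$email <- email
  ws$quiet <- isTRUE(quiet)
  ws$log <- list()
  ws$last_run <- list()   # agent id -> POSIXct of last monitoring run
  ws$counters <- list(event = 0L, job = 0L)
  class(ws) <- "flux_workspace"
  ws
}

utc_clock <- function() as.POSIXct(Sys.time(), tz = "UTC")

#' Default application settings
#'
#' The schedule list is configuration, not code: instances may define their
#' own named intervals. The default list spans the shortest supported polling
#' interval of 5 minutes (the floor chosen as the trade-off between platform
#' load and freshness) up to weekly runs, and a default worker limit of 2
#' concurrent monitoring jobs.
#'
#' @return A list with elements `schedules` (named vector of interval
#'   seconds) and `worker_limit`.
#' @export
default_settings <- function() {
  list(
    schedules = c(
      every_5_minutes  = 5 * 60,
      every_15_minutes = 15 * 60,
      hourly           = 60 * 60,
      daily            = 24 * 60 * 60,
      weekly           = 7 * 24 * 60 * 60
    ),
    worker_limit = 2L
  )
}

validate_settings <- function(settings) {
  if (!is.list(settings) || is.null(settings$schedules)) {
    config_error("settings must contain a named `schedules` vector")
  }
  sch <- settings$schedules
  if (is.null(names(sch)) || any(!nzchar(names(sch))) || any(sch <= 0)) {
    config_error("every schedule needs a name and a positive interval")
  }
  settings$schedules <- vapply(sch, as.numeric, numeric(1))
  settings$worker_limit <- max(1L, as.integer(settings$worker_limit %||% 2L))
  settings
}

#' Read and write application settings as JSON
#'
#' @param path File path of the JSON settings document.
#' @param settings Settings list as from [default_settings()].
#' @return `read_settings` returns a validated settings list.
#' @export
read_settings <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_settings(list(
    schedules = unlist(raw$schedules),
    worker_limit = raw$worker_limit %||% 2L
  ))
}

#' @rdname read_settings
#' @export
write_settings <- function(settings, path) {
  settings <- validate_settings(settings)
  jsonlite::write_json(
    list(schedules = as.list(settings$schedules),
         worker_limit = settings$worker_limit),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Register framework entities in a workspace
#'
#' Agents, seeds, templates and integrations are registered by id; an
#' existing entity with the same id is replaced.
#'
#' @param ws A [flux_workspace()].
#' @param x The entity to register.
#' @return The entity, invisibly.
#' @export
add_agent <- function(ws, x) {
  stopifnot(inherits(x, "flux_agent"))
  resolve_schedule(ws, x$schedule)
  ws$agents[[x$id]] <- x
  invisible(x)
}

#' @rdname add_agent
#' @export
add_seed <- function(ws, x) {
  stopifnot(inherits(x, "flux_seed"))
  ws$seeds[[x$id]] <- x
  invisible(x)
}

#' @rdname add_agent
#' @export
add_template <- function(ws, x) {
  stopifnot(inherits(x, "flux_template"))
  ws$templates[[x$id]] <- x
  invisible(x)
}

#' @rdname add_agent
#' @export
add_integration <- function(ws, x) {
  stopifnot(inherits(x, "flux_integration"))
  missing_a <- setdiff(x$agent_ids, names(ws$agents))
  missing_t <- setdiff(x$template_ids, names(ws$templates))
  if (length(missing_a)) config_error(paste0("unknown agents: ", toString(missing_a)))
  if (length(missing_t)) config_error(paste0("unknown templates: ", toString(missing_t)))
  ws$integrations[[x$id]] <- x
  invisible(x)
}

get_agent <- function(ws, id) {
  ag <- ws$agents[[id]]
  if (is.null(ag)) not_found_error(paste0("unknown agent: ", id), agent_id = id)
  ag
}

get_template <- function(ws, id) {
  tp <- ws$templates[[id]]
  if (is.null(tp)) not_found_error(paste0("unknown template: ", id), template_id = id)
  tp
}

get_integration <- function(ws, id) {
  ig <- ws$integrations[[id]]
  if (is.null(ig)) not_found_error(paste0("unknown integration: ", id), integration_id = id)
  ig
}

next_id <- function(ws, kind) {
  ws$counters[[kind]] <- (ws$counters[[kind]] %||% 0L) + 1L
  sprintf("%s-%06d", kind, ws$counters[[kind]])
}

#' @export
print.flux_workspace <- function(x, ...) {
  cat("<flux_workspace>\n")
  cat("  agents:      ", length(x$agents), "\n")
  cat("  seeds:       ", length(x$seeds), "\n")
  cat("  templates:   ", length(x$templates), "\n")
  cat("  integrations:", length(x$integrations), "\n")
  cat("  cache:       ", class(x$cache)[1], "\n")
  cat("  schedules:   ", paste(names(x$settings$schedules), collapse = ", "), "\n")
  cat("  worker limit:", x$settings$worker_limit, "\n")
  cat("  log entries: ", length(x$log), "\n")
  invisible(x)
}
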