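# Polling: step one of the monitoring sequence. The agent connects to the
# origin resource and loads its current content without mutating it. What
# "content" is depends on the format family: raw text for file/HTTP origins,
# a result set (data frame) for SQL origins.

sql_connect <- function(endpoint) {
  if (inherits(endpoint, "DBIConnection")) return(list(con = endpoint, own = FALSE))
  if (!is.character(endpoint) || length(endpoint) != 1L) {
    config_error("malformed connection string")
  }
  path <- if (startsWith(endpoint, "sqlite://")) {
    sub("^sqlite://", "", endpoint)
  } else if (grepl("\\.(sqlite|sqlite3|db)$", endpoint)) {
    endpoint
  } else {
    config_error(paste0("malformed connection string: ", endpoint,
                        " (expected sqlite://<path> or a SQLite file path)"))
  }
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path),
                  error = function(e) {
                    config_error(paste0("cannot open database ", path, ": ",
                                        conditionMessage(e)))
                  })
  list(con = con, own = TRUE)
}

read_text_resource <- function(ws, endpoint) {
  if (grepl("^https?://", endpoint)) {
    res <- ws$http("GET", endpoint)
    if (res$status >= 400L) {
      poll_error(paste0("GET ", endpoint, " returned status ", res$status),
                 endpoint = endpoint, status = res$status)
    }
    return(res$body)
  }
  path <- sub("^file://", "", endpoint)
  if (!file.exists(path)) {
    poll_error(paste0("unreachable endpoint: ", path), endpoint = path)
  }
  readChar(path, file.info(path)$size, useBytes = TRUE)
}

#' Poll an agent's origin resource
#'
#' Loads the resource's current content: the text body for file and HTTP
#' endpoints, or the query's result set (a data frame) for SQL agents. The
#' resource is never mutated. Failures to reach the endpoint raise a
#' retriable poll error and are logged; malformed connection strings raise a
#' configuration error.
#'
#' @param ws A [flux_workspace()].
#' @param agent A [agent_config()].
#' @return Character scalar (csv/tsv/xml/json) or data frame (sql).
#' @export
poll <- function(ws, agent) {
  if (!agent$enabled) config_error(paste0("agent ", agent$id, " is disabled"))
  origin <- paste0("agent:", agent$id)
  content <- withCallingHandlers(
    {
      if (identical(agent$format, "sql")) {
        db <- sql_connect(agent$endpoint)
        if (db$own) on.exit(DBI::dbDisconnect(db$con), add = TRUE)
        tryCatch(DBI::dbGetQuery(db$con, agent$query), error = function(e) {
          poll_error(paste0("query failed on ", format(agent$endpoint), ": ",
                            conditionMessage(e)))
        })
      } else {
        read_text_resource(ws, agent$endpoint)
      }
    },
    flux_poll_error = function(e) {
      flux_log(ws, origin, "origin", conditionMessage(e), "error")
    }
  )
  flux_log(ws, origin, "origin", "polled origin resource", "ok")
  content
}
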