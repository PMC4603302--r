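# Delivery execution: the final step of the pipeline. The rendered template
# is applied to the destination resource — a SQL database, a composed email,
# a file in the user workspace, or an HTTP endpoint. Every attempt yields
# exactly one delivery report and one log entry; a failure is contained in
# its report and never rolls back the detection cache (delivery verification
# is deliberately out of scope).

new_report <- function(ws, event, tpl, status, detail) {
  structure(list(event_id = event$id, template_id = tpl$id,
                 status = status, detail = detail, timestamp = ws$clock()),
            class = "flux_delivery_report")
}

#' @export
print.flux_delivery_report <- function(x, ...) {
  cat(sprintf("<delivery %s -> %s: %s> %s\n", x$event_id, x$template_id,
              x$status, x$detail))
  invisible(x)
}

# Resolve a rendered path inside the workspace root, rejecting absolute
# paths and any ".." traversal that would escape it. Required because
# payload variables flow into file paths.
safe_workspace_path <- function(root, path) {
  if (grepl("^([A-Za-z]:)?[/\\\\]", path)) {
    config_error(paste0("file path must be relative to the workspace root: ", path))
  }
  parts <- strsplit(path, "[/\\\\]+")[[1]]
  stack <- character()
  for (p in parts) {
    if (p %in% c("", ".")) next
    if (identical(p, "..")) {
      if (!length(stack)) {
        config_error(paste0("file path escapes the workspace root: ", path))
      }
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, p)
    }
  }
  if (!length(stack)) config_error("file path resolves to the workspace root itself")
  file.path(root, paste(stack, collapse = "/"))
}

deliver_sql <- function(ws, event, tpl, ctx) {
  if (isTRUE(tpl$escape_sql)) ctx$transform <- quote_sql
  statement <- render(tpl$statement, ctx)
  db <- sql_connect(render(tpl$connection, ctx))
  if (db$own) on.exit(DBI::dbDisconnect(db$con), add = TRUE)
  n <- DBI::dbExecute(db$con, statement)
  paste0("executed statement, ", n, " row(s) affected")
}

deliver_email <- function(ws, event, tpl, ctx) {
  msg <- list(
    to = render(tpl$to, ctx),
    cc = if (is.null(tpl$cc)) "" else render(tpl$cc, ctx),
    bcc = if (is.null(tpl$bcc)) "" else render(tpl$bcc, ctx),
    subject = render(tpl$subject, ctx),
    message = render(tpl$message, ctx)
  )
  ws$email(msg)
  paste0("email composed for ", msg$to)
}

deliver_file <- function(ws, event, tpl, ctx) {
  target <- safe_workspace_path(ws$root, render(tpl$path, ctx))
  if (identical(tpl$mode, "delete")) {
    if (!file.exists(target)) {
      return("delete of non-existent file (no-op)")
    }
    unlink(target)
    return(paste0("deleted ", basename(target)))
  }
  content <- render(tpl$content %||% "", ctx)
  dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
  if (identical(tpl$mode, "create")) {
    writeLines(content, target, useBytes = TRUE)
    paste0("created ", basename(target))
  } else {
    cat(content, "\n", sep = "", file = target, append = TRUE)
    paste0("appended to ", basename(target))
  }
}

deliver_url <- function(ws, event, tpl, ctx) {
  addr_ctx <- ctx
  addr_ctx$transform <- function(x) curl::curl_escape(x)
  address <- render(tpl$address, addr_ctx)
  if (identical(tpl$method, "GET")) {
    res <- ws$http("GET", address)
  } else {
    content_type <- switch(tpl$payload_format,
                           text = "text/plain",
                           json = "application/json",
                           xml = "application/xml")
    body <- render(tpl$body %||% "", ctx)
    res <- ws$http("POST", address, body = body, content_type = content_type)
  }
  if (res$status >= 400L) {
    stop(paste0(tpl$method, " ", address, " returned status ", res$status))
  }
  paste0(tpl$method, " ", address, " -> ", res$status)
}

#' Deliver an event through a template
#'
#' Renders the template's text fields with the event payload (plus the
#' built-in functions, timestamped with the workspace clock) and dispatches
#' to the type-specific executor: `sql` executes the rendered statement on
#' the destination connection, `email` composes a message and hands it to
#' the transport, `file` creates/appends/deletes the rendered path inside
#' the workspace root, and `url` issues a GET or a POST whose Content-Type
#' matches the payload format. Deleting a non-existent file succeeds with a
#' warning detail. A failing destination yields `status = "failed"` with the
#' reason, and never affects the detection cache or sibling deliveries.
#'
#' @param ws A [flux_workspace()].
#' @param event A `flux_event`.
#' @param tpl A [template()].
#' @return A `flux_delivery_report` with fields `event_id`, `template_id`,
#'   `status` (`"delivered"` or `"failed"`), `detail` and `timestamp`.
#' @export
deliver <- function(ws, event, tpl) {
  ctx <- render_context(variables = event$payload, now = ws$clock())
  origin <- paste0("postman:event:", event$id)
  dest <- paste0(tpl$type, ":", tpl$id)
  report <- tryCatch(
    {
      detail <- switch(tpl$type,
        sql = deliver_sql(ws, event, tpl, ctx),
        email = deliver_email(ws, event, tpl, ctx),
        file = deliver_file(ws, event, tpl, ctx),
        url = deliver_url(ws, event, tpl, ctx)
      )
      new_report(ws, event, tpl, "delivered", detail)
    },
    error = function(e) {
      new_report(ws, event, tpl, "failed", conditionMessage(e))
    }
  )
  flux_log(ws, origin, dest, report$detail,
           if (identical(report$status, "delivered")) "ok" else "error")
  report
}
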