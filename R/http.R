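# HTTP backends. The workspace's `http` slot is the single seam through
# which the framework talks HTTP, for both polling HTTP origins and URL
# deliveries, so deployments use the real curl backend while tests swap in a
# recording stub and run fully offline.

#' HTTP backends
#'
#' An HTTP backend is a function `(method, url, body, content_type, headers)`
#' returning `list(status = <integer>, body = <character>)`.
#'
#' `http_curl_backend()` performs real HTTP/1.1 requests via curl with a
#' single network timeout and no retries. `http_stub_backend()` is an
#' in-process double: it records every request in its `$requests` list and
#' answers using a user-supplied responder, making URL destinations and HTTP
#' origins fully testable offline.
#'
#' @param timeout Network timeout in seconds for the curl backend.
#' @param responder For the stub: `function(method, url, body, content_type)`
#'   returning `list(status, body)`; defaults to a `200 "ok"` answer.
#' @return A backend function; the stub additionally carries the `requests`
#'   environment field.
#' @export
http_curl_backend <- function(timeout = 15) {
  function(method, url, body = NULL, content_type = NULL, headers = list()) {
    h <- curl::new_handle(timeout = timeout)
    hdr <- headers
    if (identical(method, "POST")) {
      raw_body <- charToRaw(body %||% "")
      curl::handle_setopt(h, post = TRUE, postfieldsize = length(raw_body),
                          postfields = raw_body)
      if (!is.null(content_type)) hdr[["Content-Type"]] <- content_type
    }
    if (length(hdr)) do.call(curl::handle_setheaders, c(list(h), hdr))
    res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) {
      poll_error(paste0("request to ", url, " failed: ", conditionMessage(e)),
                 endpoint = url)
    })
    list(status = res$status_code, body = rawToChar(res$content))
  }
}

#' @rdname http_curl_backend
#' @export
http_stub_backend <- function(responder = NULL) {
  store <- new.env(parent = emptyenv())
  store$requests <- list()
  backend <- function(method, url, body = NULL, content_type = NULL, headers = list()) {
    store$requests[[length(store$requests) + 1L]] <- list(
      method = method, url = url, body = body, content_type = content_type,
      headers = headers
    )
    if (is.null(responder)) list(status = 200L, body = "ok")
    else responder(method, url, body, content_type)
  }
  class(backend) <- c("flux_http_stub", "function")
  attr(backend, "store") <- store
  backend
}

#' Requests recorded by a stub HTTP backend
#'
#' @param backend A backend from [http_stub_backend()].
#' @return List of recorded requests, oldest first.
#' @export
stub_requests <- function(backend) attr(backend, "store")$requests

#' Email transports
#'
#' Delivery of composed email messages is pluggable: production deployments
#' supply a function that hands the message to their mail system, while
#' `email_capture_transport()` collects messages in process so email
#' templates are testable without a mail server. A composed message is a
#' list with fields `to`, `cc`, `bcc`, `subject`, `message`.
#'
#' @return A transport function with a `$messages` record accessible via
#'   [captured_emails()].
#' @export
email_capture_transport <- function() {
  store <- new.env(parent = emptyenv())
  store$messages <- list()
  transport <- function(msg) {
    store$messages[[length(store$messages) + 1L]] <- msg
    invisible(TRUE)
  }
  class(transport) <- c("flux_email_capture", "function")
  attr(transport, "store") <- store
  transport
}

#' @rdname email_capture_transport
#' @param transport A transport from [email_capture_transport()].
#' @export
captured_emails <- function(transport) attr(transport, "store")$messages
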