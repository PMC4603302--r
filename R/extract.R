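# Extraction: turn polled content into records, one per CSV data row, XML
# item node, JSON array element or SQL result row, in source order. Each
# selector is applied relative to the record's own scope; a selector that
# matches nothing yields the empty string and a warning log entry. All
# extracted values are normalized to whitespace-trimmed strings.

norm_value <- function(x) trimws(as.character(x))

selector_miss <- function(ws, agent, key, ordinal) {
  msg <- sprintf("selector '%s' matched nothing in record %d", key, ordinal)
  if (!is.null(ws)) {
    flux_log(ws, paste0("agent:", agent$id), "detector", msg, "warning")
  }
  ""
}

extract_tabular <- function(content, agent, ws) {
  df <- tryCatch(
    utils::read.table(text = content, sep = agent$delimiter, header = FALSE,
                      colClasses = "character", quote = "\"",
                      stringsAsFactors = FALSE, blank.lines.skip = TRUE,
                      comment.char = "",
                      skip = if (agent$has_header) 1L else 0L),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame())
      }
      extract_error(paste0("unparseable ", agent$format, " content: ",
                           conditionMessage(e)))
    })
  cols <- lapply(agent$selectors, function(v) {
    iv <- suppressWarnings(as.integer(v))
    if (is.na(iv) || iv < 1L) {
      config_error(paste0("csv/tsv selector values must be 1-based column numbers, got: ", v))
    }
    iv
  })
  n <- nrow(df)
  lapply(seq_len(n), function(i) {
    vals <- lapply(names(cols), function(key) {
      j <- cols[[key]]
      if (j > ncol(df)) selector_miss(ws, agent, key, i) else norm_value(df[i, j])
    })
    names(vals) <- names(cols)
    new_record(vals, agent$id, i)
  })
}

extract_xml <- function(content, agent, ws) {
  doc <- tryCatch(xml2::read_xml(content), error = function(e) {
    extract_error(paste0("unparseable xml content: ", conditionMessage(e)))
  })
  # xml2 signals bad XPath as an error or (for some malformed expressions)
  # a warning with an empty result; both are configuration mistakes
  bad_xpath <- function(e) {
    config_error(paste0("invalid items XPath '", agent$items, "': ",
                        conditionMessage(e)))
  }
  nodes <- withCallingHandlers(
    tryCatch(xml2::xml_find_all(doc, agent$items), error = bad_xpath),
    warning = bad_xpath
  )
  lapply(seq_along(nodes), function(i) {
    vals <- lapply(names(agent$selectors), function(key) {
      xp <- agent$selectors[[key]]
      hit <- tryCatch(xml2::xml_find_all(nodes[[i]], xp), error = function(e) {
        config_error(paste0("invalid XPath for selector '", key, "': ",
                            conditionMessage(e)))
      })
      if (length(hit) == 0L) {
        selector_miss(ws, agent, key, i)
      } else {
        # several matched nodes within one item are flattened with ";"
        paste(norm_value(xml2::xml_text(hit)), collapse = ";")
      }
    })
    names(vals) <- names(agent$selectors)
    new_record(vals, agent$id, i)
  })
}

json_dig <- function(x, path) {
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(x) || is.null(x[[key]])) return(NULL)
    x <- x[[key]]
  }
  x
}

extract_json <- function(content, agent, ws) {
  doc <- tryCatch(jsonlite::fromJSON(content, simplifyVector = FALSE),
                  error = function(e) {
                    extract_error(paste0("unparseable json content: ",
                                         conditionMessage(e)))
                  })
  arr <- json_dig(doc, agent$items)
  if (is.null(arr) || !is.list(arr) || !is.null(names(arr))) {
    config_error(paste0("items path '", agent$items, "' must address a JSON array"))
  }
  lapply(seq_along(arr), function(i) {
    vals <- lapply(names(agent$selectors), function(key) {
      hit <- json_dig(arr[[i]], agent$selectors[[key]])
      if (is.null(hit)) {
        selector_miss(ws, agent, key, i)
      } else if (is.list(hit)) {
        paste(vapply(hit, norm_value, ""), collapse = ";")
      } else {
        norm_value(hit)
      }
    })
    names(vals) <- names(agent$selectors)
    new_record(vals, agent$id, i)
  })
}

extract_sql <- function(content, agent, ws) {
  if (!is.data.frame(content)) {
    extract_error("sql extraction expects a result set (data frame)")
  }
  lapply(seq_len(nrow(content)), function(i) {
    vals <- lapply(names(agent$selectors), function(key) {
      col <- agent$selectors[[key]]
      if (!col %in% names(content)) {
        selector_miss(ws, agent, key, i)
      } else {
        norm_value(content[i, col][[1]])
      }
    })
    names(vals) <- names(agent$selectors)
    new_record(vals, agent$id, i)
  })
}

#' Extract records from polled content
#'
#' Applies the agent's format-specific detector to split the content into
#' records and evaluate every selector relative to each record's scope.
#' Record order always equals source order.
#'
#' @param ws A [flux_workspace()] used for warning log entries, or `NULL`.
#' @param content As returned by [poll()].
#' @param agent The [agent_config()] the content was polled for.
#' @return List of records; each has `$values` (named list of strings, keys
#'   equal to the declared selector keys), `$source_agent` and `$ordinal`.
#' @export
extract <- function(ws, content, agent) {
  recs <- switch(detector_family(agent$format),
    "csv/tsv" = extract_tabular(content, agent, ws),
    "xml"     = extract_xml(content, agent, ws),
    "json"    = extract_json(content, agent, ws),
    "sql"     = extract_sql(content, agent, ws)
  )
  if (!is.null(ws)) {
    flux_log(ws, paste0("agent:", agent$id), "detector",
             sprintf("extracted %d record(s)", length(recs)), "ok")
  }
  recs
}
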