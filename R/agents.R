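#' Data selectors
#'
#' Selectors are key-value pairs mapping a unique variable name (the key) to
#' a format-specific extraction expression (the value): a 1-based column
#' number for CSV/TSV, an XPath 1.0 string for XML, a dot-separated key path
#' for JSON, and a result-column name for SQL. The keys become the payload
#' variables available to delivery templates, so every template variable must
#' have a corresponding selector in the agent.
#'
#' @param ... Named extraction expressions, e.g. `gene = 1, variant = 2` for
#'   a CSV agent or `title = "./title/text()"` for an XML agent.
#' @return A named list of selector expressions.
#' @export
selectors <- function(...) {
  sel <- list(...)
  validate_selectors(sel)
  sel
}

validate_selectors <- function(sel) {
  if (!length(sel)) config_error("an agent needs at least one selector")
  keys <- names(sel)
  if (is.null(keys) || any(!nzchar(keys))) {
    config_error("every selector needs a key (a variable name)")
  }
  bad <- keys[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", keys)]
  if (length(bad)) {
    config_error(paste0("invalid selector key(s): ", toString(bad)))
  }
  if (anyDuplicated(keys)) {
    config_error(paste0("duplicate selector key(s): ",
                        toString(unique(keys[duplicated(keys)]))))
  }
  invisible(sel)
}

agent_formats <- c("csv", "tsv", "xml", "json", "sql")

#' Detector and delivery registries
#'
#' `detector_formats()` lists the format families the change-detection engine
#' supports; CSV and TSV share one tabular detector. `delivery_types()` lists
#' the supported destination template types. Both registries are the
#' extension points for new formats or delivery methods.
#'
#' @return A character vector of registry names.
#' @export
detector_formats <- function() c("csv/tsv", "sql", "xml", "json")

#' @rdname detector_formats
#' @export
delivery_types <- function() c("sql", "email", "file", "url")

detector_family <- function(format) {
  switch(format, csv = "csv/tsv", tsv = "csv/tsv", format)
}

#' Configure a monitoring agent
#'
#' An agent monitors one origin resource: it knows where the resource lives
#' (`endpoint`), how to read it (`format`, plus `query` for SQL and `items`
#' for XML/JSON), which data elements to extract (`selectors`), how change
#' detection fingerprints each record (`cache_key`), and how often it runs
#' (`schedule`). Agents referencing seeds are definition templates: at run
#' time one concrete agent is instantiated per harvested seed record via
#' [expand_seeds()].
#'
#' @param id Unique agent identifier.
#' @param name Human-readable name; defaults to the id.
#' @param format One of `"csv"`, `"tsv"`, `"xml"`, `"json"`, `"sql"`.
#' @param endpoint Resource locator: a file path, an `http(s)://` URL, or
#'   (for SQL) a `sqlite://<path>` connection string.
#' @param selectors Named list from [selectors()].
#' @param query SQL text; required for and exclusive to `format = "sql"`.
#' @param items Record-splitting expression; required for and exclusive to
#'   XML (a node-set XPath, e.g. `"//entry"`) and JSON (a dotted path that
#'   must address an array, e.g. `"variants"`).
#' @param cache_key Optional selector key whose value identifies a record for
#'   change detection; when absent, records are fingerprinted by an MD5
#'   digest of their full content (see [fingerprint()]).
#' @param schedule Schedule name, resolved against the workspace settings.
#' @param seed_refs Character vector of seed ids used by this agent.
#' @param has_header For CSV/TSV: does the first row hold column names to be
#'   skipped? Default `TRUE`.
#' @param delimiter For CSV/TSV: field delimiter; defaults to `","` for CSV
#'   and `"\t"` for TSV.
#' @param owner Owning user id; tokens grant access only to their owner's
#'   agents.
#' @param enabled Disabled agents are never polled.
#' @return An object of class `flux_agent`.
#' @examples
#' agent_config("a1", format = "csv", endpoint = "variants.csv",
#'              selectors = selectors(gene = 1, variant = 2),
#'              cache_key = "variant")
#' @export
agent_config <- function(id, format, endpoint, selectors,
                         name = id, query = NULL, items = NULL,
                         cache_key = NULL, schedule = "every_5_minutes",
                         seed_refs = character(), has_header = TRUE,
                         delimiter = NULL, owner = "default", enabled = TRUE) {
  format <- as.character(format)
  if (!format %in% agent_formats) {
    config_error(paste0("unsupported format: ", format,
                        " (supported: ", toString(agent_formats), ")"))
  }
  validate_selectors(selectors)
  if (identical(format, "sql")) {
    if (is.null(query) || !nzchar(query)) config_error("sql agents require a query")
  } else if (!is.null(query)) {
    config_error("`query` is only valid for sql agents")
  }
  if (format %in% c("xml", "json")) {
    if (is.null(items) || !nzchar(items)) {
      config_error(paste0(format, " agents require an `items` expression"))
    }
  } else if (!is.null(items)) {
    config_error("`items` is only valid for xml/json agents")
  }
  if (!is.null(cache_key) && !cache_key %in% names(selectors)) {
    config_error(paste0("cache_key '", cache_key, "' is not a declared selector key"))
  }
  if (is.null(delimiter)) delimiter <- if (identical(format, "tsv")) "\t" else ","
  structure(
    list(id = as.character(id), name = as.character(name), format = format,
         endpoint = endpoint, query = query, items = items,
         selectors = selectors, cache_key = cache_key, schedule = schedule,
         seed_refs = as.character(seed_refs), has_header = isTRUE(has_header),
         delimiter = delimiter, owner = as.character(owner),
         enabled = isTRUE(enabled)),
    class = "flux_agent"
  )
}

#' @export
print.flux_agent <- function(x, ...) {
  cat(sprintf("<flux_agent %s> %s [%s] %s\n", x$id, x$name, x$format,
              if (x$enabled) "" else "(disabled)"))
  cat("  endpoint:", format(x$endpoint), "\n")
  if (!is.null(x$query)) cat("  query:   ", x$query, "\n")
  if (!is.null(x$items)) cat("  items:   ", x$items, "\n")
  cat("  selectors:", paste(sprintf("%s=%s", names(x$selectors),
                                    vapply(x$selectors, format, "")), collapse = ", "), "\n")
  if (!is.null(x$cache_key)) cat("  cache_key:", x$cache_key, "\n")
  cat("  schedule:", x$schedule, "\n")
  invisible(x)
}

#' Configure a seed
#'
#' Seeds dynamically populate values in an agent's configuration: a seed is
#' itself a small extraction (same format/endpoint/items/selectors machinery
#' as an agent) whose harvested records are substituted into the placeholders
#' `%{seed.<placeholder>}` occurring in an agent's endpoint, query, items or
#' selector values, creating one concrete agent per harvested record. The
#' canonical use is iterating one feed agent over a predefined gene list.
#'
#' @inheritParams agent_config
#' @param placeholder Name under which harvested values are substituted. The
#'   substituted value is the harvested record's value for the selector key
#'   equal to `placeholder` (or the record's single value if it has exactly
#'   one selector).
#' @return An object of class `flux_seed`.
#' @export
seed_config <- function(id, placeholder, format, endpoint, selectors,
                        query = NULL, items = NULL, has_header = TRUE,
                        delimiter = NULL) {
  harvest <- agent_config(id = paste0("seed-", id), format = format,
                          endpoint = endpoint, selectors = selectors,
                          query = query, items = items,
                          has_header = has_header, delimiter = delimiter)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", placeholder)) {
    config_error(paste0("invalid seed placeholder: ", placeholder))
  }
  structure(
    list(id = as.character(id), placeholder = placeholder, harvest = harvest),
    class = "flux_seed"
  )
}

# ---- JSON (de)serialization: the on-disk config format for remote agents ----

agent_to_list <- function(agent) {
  keep <- c("id", "name", "format", "endpoint", "query", "items", "selectors",
            "cache_key", "schedule", "seed_refs", "has_header", "delimiter",
            "owner", "enabled")
  out <- agent[keep]
  out[!vapply(out, is.null, TRUE)]
}

#' Serialize agents and seeds to and from JSON
#'
#' JSON documents are the shared configuration format: remote agents keep
#' their definitions in a private local JSON file and the CLI loads them from
#' there.
#'
#' @param agent,seed The object to serialize.
#' @param x A list parsed from JSON.
#' @return `agent_to_json`/`seed_to_json` return a JSON string;
#'   `agent_from_json`/`seed_from_json` accept a JSON string (or parsed list)
#'   and return the object.
#' @export
agent_to_json <- function(agent) {
  jsonlite::toJSON(agent_to_list(agent), auto_unbox = TRUE, null = "null")
}

#' @rdname agent_to_json
#' @export
agent_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  agent_config(
    id = x$id, format = x$format, endpoint = x$endpoint,
    selectors = x$selectors, name = x$name %||% x$id,
    query = x$query, items = x$items, cache_key = x$cache_key,
    schedule = x$schedule %||% "every_5_minutes",
    seed_refs = as.character(unlist(x$seed_refs)),
    has_header = x$has_header %||% TRUE, delimiter = x$delimiter,
    owner = x$owner %||% "default", enabled = x$enabled %||% TRUE
  )
}

#' @rdname agent_to_json
#' @export
seed_to_json <- function(seed) {
  h <- agent_to_list(seed$harvest)
  h$id <- NULL
  jsonlite::toJSON(
    list(id = seed$id, placeholder = seed$placeholder, harvest = h),
    auto_unbox = TRUE, null = "null"
  )
}

#' @rdname agent_to_json
#' @export
seed_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  h <- x$harvest
  seed_config(id = x$id, placeholder = x$placeholder, format = h$format,
              endpoint = h$endpoint, selectors = h$selectors,
              query = h$query, items = h$items,
              has_header = h$has_header %||% TRUE, delimiter = h$delimiter)
}

# A record is one extracted data element: the atomic unit of change
# detection. Values are always strings, in declared-selector order.
new_record <- function(values, source_agent, ordinal) {
  structure(list(values = values, source_agent = source_agent,
                 ordinal = as.integer(ordinal)),
            class = "flux_record")
}
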