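# Atomic fingerprint cache: the heart of change detection. Each extracted
# data element is stored independently as one (scope, fingerprint) entry,
# without dependencies on other resources, datasets or agents. Entries are
# only ever inserted, never mutated; a record is "new" exactly when its
# fingerprint was absent from the agent's scope at check time, and the check
# and the insert are one atomic operation.

#' Fingerprint a record for change detection
#'
#' Two fingerprinting modes exist. If the agent designates a `cache_key`,
#' the record's value for that selector is used verbatim — this is intended
#' for fields that identify records unequivocally, such as stable
#' identifiers. Otherwise the fingerprint is the lowercase 32-hex-character
#' MD5 digest of the record's canonical serialization: keys sorted
#' lexicographically, one `key=value` line per selector joined by newlines,
#' UTF-8 encoded. The canonical form makes the digest independent of
#' insertion order, and any change to any value changes the digest.
#'
#' @param record A record (from [extract()]) or a named list/character
#'   vector of values.
#' @param cache_key Optional key whose value identifies the record.
#' @return Character scalar fingerprint.
#' @examples
#' fingerprint(list(gene = "BRCA2"))                    # MD5 of "gene=BRCA2"
#' fingerprint(list(id = "VAR001", pos = "100"), "id")  # "VAR001"
#' @export
fingerprint <- function(record, cache_key = NULL) {
  values <- if (inherits(record, "flux_record")) record$values else as.list(record)
  if (!is.null(cache_key)) {
    if (!cache_key %in% names(values)) {
      config_error(paste0("cache_key '", cache_key, "' absent from record"))
    }
    return(as.character(values[[cache_key]]))
  }
  keys <- sort(names(values), method = "radix")
  canon <- paste(paste0(keys, "=", vapply(values[keys], as.character, "")),
                 collapse = "\n")
  digest::digest(enc2utf8(canon), algo = "md5", serialize = FALSE)
}

# ---- cache backend contract --------------------------------------------
# A backend implements check-and-insert as a single atomic operation over a
# batch: given a scope and a fingerprint vector, return a logical vector
# marking which fingerprints were new, having inserted exactly those. A
# failure must leave the scope unchanged (no partial insert). The contract
# is deliberately small so further backends (e.g. an external key-value
# accelerator) can be plugged in.

#' Fingerprint cache backends
#'
#' `cache_memory()` keeps entries in an R environment and is the natural
#' test backend. `cache_sqlite()` persists entries in a relational table
#' `(scope, fingerprint, first_seen)` with a uniqueness constraint on
#' `(scope, fingerprint)`; the whole check-and-insert batch runs in one
#' transaction. Both backends implement identical decision semantics.
#'
#' @param path SQLite database file for the persistent backend.
#' @return A cache backend object.
#' @export
cache_memory <- function() {
  env <- new.env(parent = emptyenv())
  env$scopes <- new.env(parent = emptyenv())
  structure(list(env = env), class = c("flux_cache_memory", "flux_cache"))
}

#' @rdname cache_memory
#' @export
cache_sqlite <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS fingerprint_cache (
      scope       TEXT NOT NULL,
      fingerprint TEXT NOT NULL,
      first_seen  TEXT NOT NULL,
      UNIQUE (scope, fingerprint)
    )")
  guard <- new.env(parent = emptyenv())
  guard$con <- con
  reg.finalizer(guard, function(e) {
    if (DBI::dbIsValid(e$con)) try(DBI::dbDisconnect(e$con), silent = TRUE)
  }, onexit = TRUE)
  structure(list(con = con, path = path, guard = guard),
            class = c("flux_cache_sqlite", "flux_cache"))
}

#' Atomically check and insert fingerprints
#'
#' @param cache A cache backend.
#' @param scope Agent id owning the entries.
#' @param fingerprints Character vector of fingerprints to test.
#' @param now Timestamp recorded as `first_seen` for inserted entries.
#' @return Logical vector: `TRUE` where the fingerprint was not yet cached
#'   (its first occurrence in this batch included).
#' @export
cache_check_insert <- function(cache, scope, fingerprints,
                               now = as.POSIXct(Sys.time(), tz = "UTC")) {
  UseMethod("cache_check_insert")
}

#' @export
cache_check_insert.flux_cache_memory <- function(cache, scope, fingerprints,
                                                 now = as.POSIXct(Sys.time(), tz = "UTC")) {
  scopes <- cache$env$scopes
  seen <- scopes[[scope]]
  if (is.null(seen)) seen <- character()
  is_new <- logical(length(fingerprints))
  for (i in seq_along(fingerprints)) {
    fp <- fingerprints[[i]]
    if (!fp %in% seen) {
      is_new[[i]] <- TRUE
      seen <- c(seen, fp)
    }
  }
  scopes[[scope]] <- seen
  is_new
}

#' @export
cache_check_insert.flux_cache_sqlite <- function(cache, scope, fingerprints,
                                                 now = as.POSIXct(Sys.time(), tz = "UTC")) {
  if (!length(fingerprints)) return(logical())
  con <- cache$con
  ts <- format(now, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tryCatch(
    DBI::dbWithTransaction(con, {
      vapply(fingerprints, function(fp) {
        n <- DBI::dbExecute(con,
          "INSERT OR IGNORE INTO fingerprint_cache (scope, fingerprint, first_seen)
           VALUES (?, ?, ?)", params = list(scope, fp, ts))
        n == 1L
      }, logical(1), USE.NAMES = FALSE)
    }),
    error = function(e) {
      detection_error(paste0("cache backend failure: ", conditionMessage(e)))
    }
  )
}

#' Number of cached fingerprints in a scope
#'
#' @inheritParams cache_check_insert
#' @export
cache_size <- function(cache, scope) UseMethod("cache_size")

#' @export
cache_size.flux_cache_memory <- function(cache, scope) {
  length(cache$env$scopes[[scope]])
}

#' @export
cache_size.flux_cache_sqlite <- function(cache, scope) {
  DBI::dbGetQuery(cache$con,
    "SELECT COUNT(*) AS n FROM fingerprint_cache WHERE scope = ?",
    params = list(scope))$n
}

#' Detect which records are new
#'
#' The four-step verification behind every monitoring run: the detector has
#' loaded the agent's configuration and polled the resource; `detect_new`
#' now validates each extracted record against the agent's cache scope and
#' keeps exactly those whose fingerprints were absent, storing them as it
#' decides. Repeated fingerprints within one batch count once (first
#' occurrence wins). If none are new, the integration run stops here.
#'
#' @param ws A [flux_workspace()].
#' @param agent The agent whose cache policy and scope apply.
#' @param records Records from [extract()].
#' @return The sub-list of new records, in source order.
#' @export
detect_new <- function(ws, agent, records) {
  fps <- vapply(records, fingerprint, "", cache_key = agent$cache_key)
  is_new <- cache_check_insert(ws$cache, agent$id, fps, now = ws$clock())
  flux_log(ws, "detector", "cache",
           sprintf("%d of %d record(s) new", sum(is_new), length(records)), "ok")
  records[is_new]
}

#' Check bare fingerprints for a remote agent
#'
#' The service-layer counterpart of [detect_new()]: remote agents fingerprint
#' records locally and ask the server which of them are unseen. Semantics are
#' identical — the new subset is returned and atomically cached.
#'
#' @param ws A [flux_workspace()].
#' @param agent_id Agent scope to check against; must exist.
#' @param fingerprints Character vector.
#' @return The sub-vector of fingerprints that were new.
#' @export
check_fingerprints <- function(ws, agent_id, fingerprints) {
  get_agent(ws, agent_id)
  fingerprints <- as.character(fingerprints)
  is_new <- cache_check_insert(ws$cache, agent_id, fingerprints, now = ws$clock())
  flux_log(ws, paste0("api:agent:", agent_id), "cache",
           sprintf("%d of %d fingerprint(s) new", sum(is_new), length(fingerprints)),
           "ok")
  fingerprints[is_new]
}
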