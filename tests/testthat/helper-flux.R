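# Shared test helpers: every fixture is built in code at test time.

new_ws <- function(...) {
  flux_workspace(root = tempfile("flux-root-"), ...)
}

# fixed, manually advanceable clock for timing-sensitive tests
test_clock <- function(start = "2024-01-01 00:00:00") {
  env <- new.env(parent = emptyenv())
  env$now <- as.POSIXct(start, tz = "UTC")
  clock <- function() env$now
  attr(clock, "env") <- env
  clock
}

advance_clock <- function(clock, secs) {
  env <- attr(clock, "env")
  env$now <- env$now + secs
  invisible(env$now)
}

write_variant_csv <- function(path, rows, header = TRUE) {
  lines <- c(if (header) "gene,variant", rows)
  writeLines(lines, path, useBytes = TRUE)
  path
}

make_dest_db <- function(path = tempfile(fileext = ".sqlite"),
                         ddl = "CREATE TABLE v (gene TEXT, variant TEXT)") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, ddl)
  path
}

db_query <- function(path, sql) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbGetQuery(con, sql)
}

csv_agent <- function(id, path, cache_key = NULL, ...) {
  agent_config(id, format = "csv", endpoint = path,
               selectors = selectors(gene = 1, variant = 2),
               cache_key = cache_key, ...)
}

payloads_of <- function(events) lapply(events, `[[`, "payload")

sql_variant_template <- function(id, dest) {
  template(id, "sql", connection = paste0("sqlite://", dest),
           statement = "INSERT INTO v VALUES ('%{gene}','%{variant}')")
}
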