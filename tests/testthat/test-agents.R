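# Agent and selector configuration, polling, and format-specific extraction.

test_that("selector and agent invariants are enforced", {
  expect_error(selectors("x"), class = "flux_config_error")          # unnamed
  expect_error(selectors(`1bad` = 1), class = "flux_config_error")   # bad key
  expect_error(agent_config("a", "csv", "f.csv",
                            selectors = list(g = 1, g = 2)),
               class = "flux_config_error")                          # duplicate
  expect_error(agent_config("a", "yaml", "f", selectors(g = 1)),
               class = "flux_config_error")                          # bad format
  expect_error(agent_config("a", "csv", "f", selectors(g = 1),
                            query = "SELECT 1"),
               class = "flux_config_error")                          # query iff sql
  expect_error(agent_config("a", "sql", "db.sqlite", selectors(g = "g")),
               class = "flux_config_error")                          # sql needs query
  expect_error(agent_config("a", "xml", "f.xml", selectors(g = "./g")),
               class = "flux_config_error")                          # xml needs items
  expect_error(agent_config("a", "csv", "f", selectors(g = 1), items = "x"),
               class = "flux_config_error")                          # items iff xml/json
  expect_error(agent_config("a", "csv", "f", selectors(g = 1),
                            cache_key = "nope"),
               class = "flux_config_error")                          # undeclared cache_key
})

test_that("the detector and delivery registries each cover four entries", {
  expect_setequal(detector_formats(), c("csv/tsv", "sql", "xml", "json"))
  expect_length(detector_formats(), 4L)
  expect_setequal(delivery_types(), c("sql", "email", "file", "url"))
  expect_length(delivery_types(), 4L)
})

test_that("polling a file returns its content unchanged", {
  ws <- new_ws()
  path <- tempfile(fileext = ".csv")
  writeLines(c("gene,variant", "BRCA2,c.100A>T", "TP53,c.215C>G"), path)
  ag <- csv_agent("a1", path)
  content <- poll(ws, ag)
  expect_identical(content, paste0(paste(readLines(path), collapse = "\n"), "\n"))
  expect_identical(readLines(path),
                   c("gene,variant", "BRCA2,c.100A>T", "TP53,c.215C>G"))
})

test_that("polling a SQL agent returns the query's result set", {
  ws <- new_ws()
  db <- tempfile(fileext = ".sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbWriteTable(con, "v", data.frame(gene = c("BRCA2", "TP53"),
                                         variant = c("c.1A>G", "c.2C>T")))
  DBI::dbDisconnect(con)
  ag <- agent_config("s1", "sql", paste0("sqlite://", db),
                     selectors(gene = "gene", variant = "variant"),
                     query = "SELECT gene, variant FROM v")
  res <- poll(ws, ag)
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 2L)
})

test_that("unreachable endpoints raise a logged, retriable poll error", {
  ws <- new_ws(http = http_stub_backend(function(...) list(status = 500L, body = "boom")))
  ag <- csv_agent("a1", "http://origin.invalid/data.csv")
  expect_error(poll(ws, ag), class = "flux_poll_error")
  log <- get_log(ws)
  expect_true(any(log$status == "error" & grepl("500", log$message)))
  expect_error(poll(ws, csv_agent("a2", tempfile())), class = "flux_poll_error")
  expect_error(poll(ws, agent_config("a3", "sql", "not-a-connection",
                                     selectors(g = "g"), query = "SELECT 1")),
               class = "flux_config_error")
  ag$enabled <- FALSE
  expect_error(poll(ws, ag), class = "flux_config_error")
})

test_that("CSV extraction yields one record per data row with header skip", {
  ws <- new_ws()
  content <- "gene,variant\nBRCA2,c.100A>T\nTP53,c.215C>G"
  ag <- csv_agent("a1", "unused.csv")
  recs <- extract(ws, content, ag)
  expect_length(recs, 2L)
  expect_identical(recs[[1]]$values, list(gene = "BRCA2", variant = "c.100A>T"))
  expect_identical(recs[[2]]$values, list(gene = "TP53", variant = "c.215C>G"))
  expect_identical(vapply(recs, `[[`, 0L, "ordinal"), 1:2)

  # header flag off: the first row is data
  ag2 <- agent_config("a2", "csv", "unused.csv", selectors(gene = 1),
                      has_header = FALSE)
  expect_length(extract(ws, content, ag2), 3L)
})

test_that("TSV uses the tab delimiter and values are whitespace-trimmed", {
  ws <- new_ws()
  ag <- agent_config("t1", "tsv", "unused.tsv",
                     selectors(gene = 1, variant = 2), has_header = FALSE)
  recs <- extract(ws, "BRCA2\t c.1A>G \nTP53\tc.2C>T", ag)
  expect_identical(recs[[1]]$values$variant, "c.1A>G")
  expect_length(recs, 2L)
})

test_that("XML extraction splits on the items XPath and scopes selectors per item", {
  ws <- new_ws()
  entries <- paste0("<entry><title>t", 1:5, "</title></entry>", collapse = "")
  content <- paste0("<feed>", entries, "</feed>")
  ag <- agent_config("x1", "xml", "unused.xml",
                     selectors(title = "./title/text()"), items = "//entry")
  recs <- extract(ws, content, ag)
  expect_length(recs, 5L)
  expect_identical(recs[[3]]$values$title, "t3")
})

test_that("multiple XML nodes matched within one item are joined with ';'", {
  ws <- new_ws()
  content <- "<r><item><tag>a</tag><tag>b</tag></item></r>"
  ag <- agent_config("x2", "xml", "u.xml", selectors(tags = "./tag/text()"),
                     items = "//item")
  expect_identical(extract(ws, content, ag)[[1]]$values$tags, "a;b")
})

test_that("JSON record count matches an independent parse of the document", {
  ws <- new_ws()
  n <- 7L
  doc <- jsonlite::toJSON(list(variants = lapply(seq_len(n), function(i) {
    list(gene = paste0("G", i), hgvs = list(desc = paste0("c.", i, "A>T")))
  })), auto_unbox = TRUE)
  ag <- agent_config("j1", "json", "u.json",
                     selectors(gene = "gene", desc = "hgvs.desc"),
                     items = "variants")
  recs <- extract(ws, as.character(doc), ag)
  independent <- jsonlite::fromJSON(as.character(doc), simplifyVector = FALSE)
  expect_length(recs, length(independent$variants))
  expect_identical(recs[[2]]$values$desc, "c.2A>T")   # dotted path descends
})

test_that("a selector matching nothing yields empty string plus a warning log entry", {
  ws <- new_ws()
  ag <- agent_config("m1", "csv", "u.csv", selectors(gene = 1, extra = 9),
                     has_header = FALSE)
  recs <- extract(ws, "BRCA2,c.1A>G", ag)
  expect_identical(recs[[1]]$values$extra, "")
  expect_true(any(get_log(ws)$status == "warning"))
})

test_that("unparseable content and invalid expressions raise distinct errors", {
  ws <- new_ws()
  xml_ag <- agent_config("x", "xml", "u", selectors(t = "./t"), items = "//i")
  expect_error(extract(ws, "<unclosed>", xml_ag), class = "flux_extract_error")
  bad_items <- agent_config("x", "xml", "u", selectors(t = "./t"),
                            items = "//[broken")
  expect_error(extract(ws, "<a><b/></a>", bad_items), class = "flux_config_error")
  json_ag <- agent_config("j", "json", "u", selectors(g = "g"), items = "nope")
  expect_error(extract(ws, "not json", json_ag), class = "flux_extract_error")
  expect_error(extract(ws, '{"nope": {"k": 1}}', json_ag),
               class = "flux_config_error")  # items must address an array
})

test_that("agent and seed definitions round-trip through JSON", {
  ag <- agent_config("a1", "xml", "http://x/feed_%{seed.gene}.xml",
                     selectors(vid = "./variant_id/text()"), items = "//entry",
                     cache_key = "vid", seed_refs = "genes",
                     schedule = "hourly", owner = "u1")
  back <- agent_from_json(agent_to_json(ag))
  expect_equal(back, ag)

  sd <- seed_config("genes", placeholder = "gene", format = "csv",
                    endpoint = "genes.csv", selectors = selectors(gene = 1))
  sback <- seed_from_json(seed_to_json(sd))
  expect_equal(sback, sd)
})
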