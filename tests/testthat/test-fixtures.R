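# Synthetic resource generators: the variant feed and the tabular parity set.

feed_agent <- function(id, path) {
  agent_config(id, "xml", path, items = "//entry",
               selectors(vid = "./variant_id/text()", gene = "./gene/text()",
                         hgvs = "./hgvs/text()"),
               cache_key = "vid")
}

test_that("the feed holds genes x variants entries with unique ids", {
  path <- tempfile(fileext = ".xml")
  make_variant_feed(path, c("BRCA2", "TP53"), variants_per_gene = 3L, seed = 5L)
  doc <- xml2::read_xml(path)
  ids <- xml2::xml_text(xml2::xml_find_all(doc, "//entry/variant_id"))
  expect_length(ids, 6L)
  expect_false(anyDuplicated(ids) > 0L)
  expect_setequal(unique(xml2::xml_text(xml2::xml_find_all(doc, "//entry/gene"))),
                  c("BRCA2", "TP53"))
})

test_that("the same feed specification is byte-deterministic", {
  p1 <- tempfile(fileext = ".xml")
  p2 <- tempfile(fileext = ".xml")
  make_variant_feed(p1, c("CFTR", "MLH1"), 4L, seed = 9L)
  make_variant_feed(p2, c("CFTR", "MLH1"), 4L, seed = 9L)
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
})

test_that("an empty feed is valid and yields no events", {
  ws <- new_ws()
  path <- tempfile(fileext = ".xml")
  make_variant_feed(path, c("BRCA2", "TP53"), variants_per_gene = 0L)
  ag <- feed_agent("f0", path)
  add_agent(ws, ag)
  expect_length(monitor(ws, ag), 0L)
})

test_that("mutating the feed by k produces exactly k events, additively", {
  ws <- new_ws()
  path <- tempfile(fileext = ".xml")
  make_variant_feed(path, c("BRCA2", "TP53"), 3L, seed = 1L)
  ag <- feed_agent("f1", path)
  add_agent(ws, ag)
  expect_length(monitor(ws, ag), 6L)

  mutate_feed(path, 2L, seed = 2L)
  expect_length(monitor(ws, ag), 2L)      # event-count oracle: k = 2

  mutate_feed(path, 0L, seed = 3L)
  expect_length(monitor(ws, ag), 0L)

  mutate_feed(path, 1L, seed = 4L)
  mutate_feed(path, 1L, seed = 5L)
  expect_length(monitor(ws, ag), 2L)      # additivity of successive mutations

  all_ids <- xml2::xml_text(xml2::xml_find_all(xml2::read_xml(path),
                                               "//entry/variant_id"))
  expect_false(anyDuplicated(all_ids) > 0L)
  expect_error(mutate_feed(tempfile(), 1L), class = "flux_extract_error")
})

test_that("tabular resources agree in row counts and regenerate byte-stably", {
  d1 <- tempfile("fx1-")
  d2 <- tempfile("fx2-")
  r1 <- make_tabular_resources(d1, n_rows = 4L, seed = 21L)
  r2 <- make_tabular_resources(d2, n_rows = 4L, seed = 21L)
  expect_equal(nrow(r1$data), 4L)
  expect_equal(length(readLines(r1$csv)) - 1L, 4L)   # header + 4 rows
  expect_length(jsonlite::fromJSON(r1$json, simplifyVector = FALSE)$variants, 4L)
  expect_length(xml2::xml_find_all(xml2::read_xml(r1$xml), "//row"), 4L)
  expect_equal(nrow(db_query(r1$sqlite, "SELECT * FROM variants")), 4L)
  expect_identical(readLines(r1$csv), readLines(r2$csv))
  expect_identical(readLines(r1$json), readLines(r2$json))
})

test_that("the variome scenario keeps the warehouse in step with the feeds", {
  # seeded feed agents over a 2-gene synthetic feed, mutated over 3 cycles:
  # destination row count tracks total distinct variants, with no duplicates
  ws <- new_ws()
  dir <- tempfile("variome-")
  dir.create(dir)
  genes <- c("BRCA2", "TP53")
  for (g in genes) {
    make_variant_feed(file.path(dir, paste0("feed_", g, ".xml")), g,
                      variants_per_gene = 3L, seed = match(g, genes))
  }
  gene_list <- file.path(dir, "genes.csv")
  writeLines(c("gene", genes), gene_list)
  add_seed(ws, seed_config("genes", placeholder = "gene", format = "csv",
                           endpoint = gene_list,
                           selectors = selectors(gene = 1)))
  lovd <- agent_config("lovd", "xml",
                       file.path(dir, "feed_%{seed.gene}.xml"),
                       items = "//entry",
                       selectors = selectors(vid = "./variant_id/text()",
                                             gene = "./gene/text()",
                                             hgvs = "./hgvs/text()"),
                       cache_key = "vid", seed_refs = "genes")
  add_agent(ws, lovd)
  dest <- make_dest_db(ddl = "CREATE TABLE variants (vid TEXT, gene TEXT, hgvs TEXT)")
  add_template(ws, template("sqlvar", "sql",
                            connection = paste0("sqlite://", dest),
                            statement = "INSERT INTO variants VALUES ('%{vid}','%{gene}','%{hgvs}')"))
  add_integration(ws, integration("variome", "lovd", "sqlvar"))

  total <- 6L
  run_agent(ws, lovd)
  for (cycle in 1:3) {
    for (g in genes) {
      added <- mutate_feed(file.path(dir, paste0("feed_", g, ".xml")), cycle,
                           seed = 10L * cycle + match(g, genes))
      total <- total + length(added)
    }
    run_agent(ws, lovd)
    rows <- db_query(dest, "SELECT vid FROM variants")$vid
    expect_length(rows, total)
    expect_false(anyDuplicated(rows) > 0L)   # always up to date, no duplicates
  }
})
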