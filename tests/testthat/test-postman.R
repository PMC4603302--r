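# Delivery executors: sql, file, url, email; safety and isolation.

pushed_event <- function(ws, agent_id = "a1",
                         payload = list(gene = "BRCA2", variant = "c.1A>G")) {
  ag <- ws$agents[[agent_id]]
  dataflux::create_events(ws, ag, list(
    structure(list(values = payload, source_agent = agent_id, ordinal = 1L),
              class = "flux_record")))[[1]]
}

delivery_ws <- function(...) {
  ws <- new_ws(...)
  add_agent(ws, csv_agent("a1", "u.csv"))
  ws
}

test_that("sql delivery inserts one row per event", {
  ws <- delivery_ws()
  dest <- make_dest_db()
  tpl <- sql_variant_template("t1", dest)
  for (i in 1:3) {
    ev <- pushed_event(ws, payload = list(gene = paste0("G", i),
                                          variant = paste0("c.", i, "A>G")))
    expect_identical(deliver(ws, ev, tpl)$status, "delivered")
  }
  got <- db_query(dest, "SELECT gene FROM v ORDER BY gene")
  expect_identical(got$gene, c("G1", "G2", "G3"))
})

test_that("file append writes one line per event in event order", {
  ws <- delivery_ws()
  tpl <- template("t1", "file", path = "out/lines.txt", mode = "append",
                  content = "%{gene},%{variant}")
  for (g in c("BRCA2", "TP53")) {
    deliver(ws, pushed_event(ws, payload = list(gene = g, variant = "c.1A>G")), tpl)
  }
  lines <- readLines(file.path(ws$root, "out/lines.txt"))
  expect_identical(lines, c("BRCA2,c.1A>G", "TP53,c.1A>G"))
})

test_that("file create overwrites and delete is idempotent", {
  ws <- delivery_ws()
  create <- template("tc", "file", path = "f.txt", mode = "create",
                     content = "%{gene}")
  deliver(ws, pushed_event(ws, payload = list(gene = "ONE")), create)
  deliver(ws, pushed_event(ws, payload = list(gene = "TWO")), create)
  expect_identical(readLines(file.path(ws$root, "f.txt")), "TWO")

  del <- template("td", "file", path = "f.txt", mode = "delete")
  r1 <- deliver(ws, pushed_event(ws), del)
  expect_identical(r1$status, "delivered")
  expect_false(file.exists(file.path(ws$root, "f.txt")))
  # tolerant semantics: deleting a non-existent file succeeds with a warning detail
  r2 <- deliver(ws, pushed_event(ws), del)
  expect_identical(r2$status, "delivered")
  expect_match(r2$detail, "non-existent")
})

test_that("rendered paths escaping the workspace root are rejected", {
  ws <- delivery_ws()
  for (bad in c("../../etc/owned", "/etc/owned", "a/../../../owned")) {
    tpl <- template("tb", "file", path = bad, mode = "create", content = "x")
    expect_identical(deliver(ws, pushed_event(ws), tpl)$status, "failed")
  }
  # variables flowing into paths are covered too
  tpl <- template("tv", "file", path = "%{gene}.txt", mode = "create",
                  content = "x")
  ev <- pushed_event(ws, payload = list(gene = "../escape", variant = "v"))
  expect_identical(deliver(ws, ev, tpl)$status, "failed")
})

test_that("url POST sends the rendered body with the matching content type", {
  stub <- http_stub_backend()
  ws <- delivery_ws(http = stub)
  tpl <- template("tu", "url", address = "http://svc.example/variants",
                  method = "POST", payload_format = "json",
                  body = '{"gene": "%{gene}", "variant": "%{variant}"}')
  ev <- pushed_event(ws, payload = list(gene = "BRCA2", variant = "c.100A>T"))
  expect_identical(deliver(ws, ev, tpl)$status, "delivered")
  req <- stub_requests(stub)[[1]]
  expect_identical(req$method, "POST")
  expect_identical(req$content_type, "application/json")
  # capture-and-parse oracle: the endpoint sees exactly the event payload
  expect_identical(jsonlite::fromJSON(req$body, simplifyVector = FALSE),
                   ev$payload)
})

test_that("url GET percent-escapes substituted values in the address", {
  stub <- http_stub_backend()
  ws <- delivery_ws(http = stub)
  tpl <- template("tg", "url", address = "http://svc.example/v?q=%{variant}",
                  method = "GET")
  ev <- pushed_event(ws, payload = list(gene = "G", variant = "c.1A>G x"))
  deliver(ws, ev, tpl)
  expect_identical(stub_requests(stub)[[1]]$url,
                   "http://svc.example/v?q=c.1A%3EG%20x")
})

test_that("destination failures yield failed reports, never errors", {
  stub <- http_stub_backend(function(...) list(status = 503L, body = "down"))
  ws <- delivery_ws(http = stub)
  tpl <- template("tu", "url", address = "http://svc.example/x", method = "GET")
  r <- deliver(ws, pushed_event(ws), tpl)
  expect_identical(r$status, "failed")
  expect_match(r$detail, "503")
  expect_true(any(get_log(ws)$status == "error"))
})

test_that("a failing template does not affect sibling deliveries of the event", {
  ws <- delivery_ws()
  add_template(ws, template("bad", "sql", connection = "sqlite:///nope/nope.db",
                            statement = "INSERT INTO missing VALUES (1)"))
  add_template(ws, template("good", "file", path = "ok.txt", mode = "append",
                            content = "%{gene}"))
  add_integration(ws, integration("i1", "a1", c("bad", "good")))
  reports <- push_event(ws, "a1", list(gene = "BRCA2", variant = "c.1A>G"))
  statuses <- vapply(reports, `[[`, "", "status")
  names(statuses) <- vapply(reports, `[[`, "", "template_id")
  expect_identical(statuses[["bad"]], "failed")
  expect_identical(statuses[["good"]], "delivered")
  expect_identical(readLines(file.path(ws$root, "ok.txt")), "BRCA2")
})

test_that("email delivery composes rendered messages into the transport", {
  sink <- email_capture_transport()
  ws <- delivery_ws(email = sink)
  tpl <- template("te", "email", to = "curator@lsdb.example",
                  subject = "new variant in %{gene}",
                  message = "Variant %{variant} was published (${datetime}).")
  ev <- pushed_event(ws, payload = list(gene = "BRCA2", variant = "c.100A>T"))
  expect_identical(deliver(ws, ev, tpl)$status, "delivered")
  msg <- captured_emails(sink)[[1]]
  expect_identical(msg$to, "curator@lsdb.example")
  expect_identical(msg$subject, "new variant in BRCA2")
  expect_match(msg$message, "^Variant c\\.100A>T was published")
})
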