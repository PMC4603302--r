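# Event construction, many-to-many routing, pushed events and the log.

file_template <- function(id, path = paste0(id, ".txt")) {
  template(id, "file", path = path, mode = "append",
           content = "%{gene},%{variant}")
}

routing_ws <- function() {
  ws <- new_ws()
  add_agent(ws, csv_agent("a1", "u.csv"))
  ws
}

test_that("create_events preserves order and payloads, and serializes losslessly", {
  ws <- routing_ws()
  ag <- ws$agents$a1
  recs <- extract(ws, "g,v\nBRCA2,c.1A>G\nTP53,c.2C>T", ag)
  events <- create_events(ws, ag, recs)
  expect_length(events, 2L)
  expect_identical(events[[1]]$payload, list(gene = "BRCA2", variant = "c.1A>G"))
  expect_length(create_events(ws, ag, list()), 0L)
  back <- event_from_json(event_to_json(events[[1]]))
  expect_identical(back$payload, events[[1]]$payload)
  expect_identical(back$fingerprint, events[[1]]$fingerprint)
  expect_identical(back$agent_id, events[[1]]$agent_id)
})

test_that("an event fans out once per template of every enabled integration", {
  ws <- routing_ws()
  for (id in c("t1", "t2", "t3")) add_template(ws, file_template(id))
  add_integration(ws, integration("i1", "a1", c("t1", "t2")))
  ev <- create_events(ws, ws$agents$a1,
                      extract(ws, "g,v\nBRCA2,c.1A>G", ws$agents$a1))[[1]]
  reports <- route(ws, ev)
  expect_length(reports, 2L)
  expect_setequal(vapply(reports, `[[`, "", "template_id"), c("t1", "t2"))

  # a template shared by two integrations fires once per integration
  add_integration(ws, integration("i2", "a1", c("t2", "t3")))
  reports2 <- route(ws, ev)
  expect_length(reports2, 4L)
  expect_equal(sum(vapply(reports2, `[[`, "", "template_id") == "t2"), 2L)
})

test_that("disabled integrations and unrouted agents deliver nothing", {
  ws <- routing_ws()
  add_template(ws, file_template("t1"))
  add_integration(ws, integration("i1", "a1", "t1", enabled = FALSE))
  ev <- create_events(ws, ws$agents$a1,
                      extract(ws, "g,v\nX,c.1A>G", ws$agents$a1))[[1]]
  expect_length(route(ws, ev), 0L)
  expect_true(any(get_log(ws)$status == "warning"))
})

test_that("fan-out equals the sum of template counts over matching integrations", {
  set.seed(13)
  for (trial in 1:4) {
    ws <- new_ws()
    for (a in c("a1", "a2")) add_agent(ws, csv_agent(a, "u.csv"))
    for (t in paste0("t", 1:4)) add_template(ws, file_template(t))
    n_int <- sample(1:3, 1)
    for (k in seq_len(n_int)) {
      add_integration(ws, integration(
        paste0("i", k),
        agent_ids = sample(c("a1", "a2"), sample(1:2, 1)),
        template_ids = sample(paste0("t", 1:4), sample(1:4, 1)),
        enabled = sample(c(TRUE, FALSE), 1)
      ))
    }
    ev <- create_events(ws, ws$agents$a1,
                        extract(ws, "g,v\nG,c.1A>G", ws$agents$a1))[[1]]
    expected <- sum(vapply(ws$integrations, function(ig) {
      if (ig$enabled && "a1" %in% ig$agent_ids) length(ig$template_ids) else 0L
    }, 0L))
    expect_length(route(ws, ev), expected)
  }
})

test_that("pushed events deliver and pre-empt later polling of the same content", {
  ws <- new_ws()
  path <- tempfile(fileext = ".csv")
  write_variant_csv(path, "BRCA2,c.1A>G")
  add_agent(ws, csv_agent("a1", path))
  dest <- make_dest_db()
  add_template(ws, sql_variant_template("t1", dest))
  add_integration(ws, integration("i1", "a1", "t1"))

  reports <- push_event(ws, "a1", list(gene = "BRCA2", variant = "c.1A>G"))
  expect_length(reports, 1L)
  expect_identical(reports[[1]]$status, "delivered")
  expect_equal(nrow(db_query(dest, "SELECT * FROM v")), 1L)

  # cross-pipeline cache consistency: the same content polled later is not new
  expect_length(monitor(ws, ws$agents$a1), 0L)
})

test_that("pushed payloads must match the agent's declared selectors", {
  ws <- routing_ws()
  expect_error(push_event(ws, "a1", list(nope = "x")),
               class = "flux_validation_error")
  expect_error(push_event(ws, "ghost", list(gene = "x")),
               class = "flux_not_found_error")
})

test_that("a pushed payload and a polled record render byte-identical deliveries", {
  run_one <- function(mode) {
    ws <- new_ws(clock = test_clock())
    path <- tempfile(fileext = ".csv")
    write_variant_csv(path, "BRCA2,c.100A>T")
    add_agent(ws, csv_agent("a1", path))
    add_template(ws, template("t1", "file", path = "out.txt", mode = "create",
                              content = "%{gene}|%{variant}|${datetime}"))
    add_integration(ws, integration("i1", "a1", "t1"))
    if (mode == "poll") {
      run_agent(ws, ws$agents$a1)
    } else {
      push_event(ws, "a1", list(gene = "BRCA2", variant = "c.100A>T"))
    }
    readBin(file.path(ws$root, "out.txt"), "raw",
            file.info(file.path(ws$root, "out.txt"))$size)
  }
  expect_identical(run_one("poll"), run_one("push"))
})

test_that("an end-to-end run logs the full poll/detect/event/deliver sequence", {
  ws <- new_ws()
  path <- tempfile(fileext = ".csv")
  write_variant_csv(path, "BRCA2,c.1A>G")
  add_agent(ws, csv_agent("a1", path))
  add_template(ws, file_template("t1"))
  add_integration(ws, integration("i1", "a1", "t1"))
  run_agent(ws, ws$agents$a1)
  log <- get_log(ws)
  expect_true(any(log$origin == "agent:a1" & log$destination == "origin"))
  expect_true(any(log$origin == "detector" & log$destination == "cache"))
  expect_true(any(log$origin == "detector" & log$destination == "agent:a1"))
  expect_true(any(log$origin == "router" & log$destination == "template:t1"))
  expect_true(any(grepl("^postman:", log$origin) & log$destination == "file:t1"))
})
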