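# dataflux

Event-driven, near real-time data integration for heterogeneous
life-sciences resources.

Keeping a warehouse in step with living data sources — locus-specific
variant databases, institutional result tables, web-service feeds — is
usually done with batch ETL pipelines that re-process everything on a
timer, or with one-off scripts glued to a single source. `dataflux`
implements the alternative: **agents** poll origin resources (CSV/TSV
files, XML documents and Atom-like feeds, JSON documents, SQL query
results) on configurable schedules, an **atomic fingerprint cache** turns
content changes into **events**, and **integrations** route each event
many-to-many into typed delivery **templates** (SQL statements, emails,
workspace files, HTTP requests) rendered by a small template engine.
Origin systems that prefer to announce their own changes can instead
*push* payloads into a token-authenticated API, skipping detection
entirely.

It is aimed at researchers and data engineers who curate aggregated
resources — the motivating scenario is collecting newly published variants
for a gene list from LOVD-style per-gene Atom feeds into a relational
warehouse, continuously and without manual triggers.

## The model

An agent *A* declares selectors `k -> e(k)`: variable names mapped to
format-specific extraction expressions (1-based column numbers for
CSV/TSV, XPath for XML, dotted paths for JSON, result-column names for
SQL). A monitoring pass extracts records `r_1, ..., r_n` (one per data
row / item node / array element / result row, in source order) and
fingerprints each one:

* identifier mode — `fp(r) = r[cache_key]`, when the agent designates a
  selector that identifies records unequivocally;
* digest mode — `fp(r) = MD5(canonical(r))`, where `canonical(r)` joins
  `key=value` lines sorted by key; any change to any value changes the
  fingerprint.

Each `(agent, fp)` pair is stored independently, exactly once, in an
append-only cache; a record is **new** iff its fingerprint was absent at
check time, and check-and-insert is one atomic operation. New records
become events; an event fans out to one delivery per template of every
enabled integration containing its agent. Template text substitutes
`%{variable}` from the event payload, `${datetime}` (and other registered
functions), and `${code(...)}` — a sandboxed, time-bounded R snippet with
the payload variables bound as values. Monitoring jobs run through a
homogeneous FIFO queue with bounded concurrency (by default, two at a
time), and the smallest default polling interval is every 5 minutes.

## Worked example: a variant feed kept in a warehouse

```r
library(dataflux)

ws <- flux_workspace(root = tempdir())

# a synthetic per-gene variant feed stands in for an LOVD-style API
feed <- tempfile(fileext = ".xml")
make_variant_feed(feed, genes = "BRCA2", variants_per_gene = 3, seed = 42)

agent <- agent_config(
  "lovd-brca2", format = "xml", endpoint = feed, items = "//entry",
  selectors = selectors(vid  = "./variant_id/text()",
                        gene = "./gene/text()",
                        hgvs = "./hgvs/text()"),
  cache_key = "vid"
)
add_agent(ws, agent)

dest <- tempfile(fileext = ".sqlite")
con <- DBI::dbConnect(RSQLite::SQLite(), dest)
invisible(DBI::dbExecute(con, "CREATE TABLE variants (vid TEXT, gene TEXT, hgvs TEXT)"))
DBI::dbDisconnect(con)
add_template(ws, template(
  "warehouse", "sql", connection = paste0("sqlite://", dest),
  statement = "INSERT INTO variants VALUES ('%{vid}','%{gene}','%{hgvs}')"
))
add_integration(ws, integration("variome", "lovd-brca2", "warehouse"))

res <- run_agent(ws, "lovd-brca2")
length(res$events)
#> [1] 3
res$reports[[1]]
#> <delivery event-000001 -> warehouse: delivered> executed statement, 1 row(s) affected

# an unchanged feed produces no events ...
length(run_agent(ws, "lovd-brca2")$events)
#> [1] 0

# ... and two newly published variants produce exactly two
mutate_feed(feed, 2, seed = 43)
length(run_agent(ws, "lovd-brca2")$events)
#> [1] 2

con <- DBI::dbConnect(RSQLite::SQLite(), dest)
DBI::dbGetQuery(con, "SELECT * FROM variants")
#>       vid  gene       hgvs
#> 1 BRCA2:1 BRCA2 c.61413C>T
#> 2 BRCA2:2 BRCA2 c.54425C>T
#> 3 BRCA2:3 BRCA2 c.99556A>C
#> 4 BRCA2:4 BRCA2 c.98744C>G
#> 5 BRCA2:5 BRCA2 c.10407G>T
```

The first run integrates every variant of the fresh feed (3 events, each
delivered as one SQL insert). The second run detects nothing — all
fingerprints are cached. After the feed gains two variants, exactly those
two flow to the warehouse, which ends up holding all 5 distinct variants
with no duplicates. A gene *list* scales this to many feeds through a
seed: `seed_config()` harvests the list and `%{seed.gene}` in the agent's
endpoint instantiates one concrete agent per gene (see
`vignette("dataflux-methods")`).

Remote monitoring uses the same machinery over the API: `flux_app()`
builds the request handler (servable with `flux_serve()`), access tokens
come from `generate_token()`, and `run_remote_agent()` polls locally,
verifies fingerprints via `POST /api/agents/<id>/check` and delivers new
records via `POST /api/agents/<id>/events`. The installed script
`inst/cli/dataflux.R` wraps serving, agent runs, integration runs and
fixture generation for shell use.

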