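---
title: "Event-driven data integration with dataflux: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven data integration with dataflux: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dataflux)
```

## The integration model

`dataflux` treats data integration as a stream of atomic change events
rather than a batch job. Five kinds of objects cooperate:

* **Agents** monitor one origin resource each. An agent knows the
  resource locator, the format (`csv`, `tsv`, `xml`, `json`, `sql`), a
  record-splitting expression where the format needs one (`items`: a
  node-set XPath for XML, a dotted path to an array for JSON), and
  *selectors* — named extraction expressions whose keys become the
  payload variables of every downstream event.
* **Seeds** turn one agent definition into many concrete agents by
  harvesting a value list (with the same extraction machinery) and
  substituting `%{seed.<placeholder>}` occurrences in the agent's
  endpoint, query, items and selector values. The canonical use is a
  gene list driving one variant-feed agent per gene.
* The **fingerprint cache** decides novelty. Every extracted record is
  reduced to a fingerprint and the pair (agent scope, fingerprint) is
  stored exactly once, append-only.
* **Integrations** bind agents to templates many-to-many; every event
  from a member agent is delivered once per member template.
* **Templates** are typed delivery actions (`sql`, `email`, `file`,
  `url`) whose text is rendered per event.

A monitoring pass is `poll -> extract -> detect -> create events ->
route -> deliver`, and each step appends at least one entry to the
append-only log, so a transaction can be re-enacted from its entries.
Two variants reuse the same pipeline: *remote agents* run poll/extract
where the data live and use the token-authenticated API for the detect
and deliver halves, and *pushed events* enter at routing, skipping
detection entirely. Because all three variants construct events through
the same code path, identical record content yields byte-identical
rendered deliveries — a property the test suite asserts literally.

### Assumptions

The model assumes origin resources are snapshot-readable (a poll sees a
consistent document or result set), that records are meaningful in
isolation (an event carries everything needed to finalize its delivery),
and that novelty is decidable per record from its own content — there is
no cross-record or cross-resource reasoning. Compressed or encrypted
payloads and multi-step acquisitions (joins across sources before
detection) are out of scope.

## Change detection

Fingerprinting has two modes:

* **Identifier mode.** When the agent designates `cache_key`, the
  record's value for that selector is used verbatim. This is the right
  mode when the source exposes stable unique identifiers (variant
  accessions, database keys): a record edit under the same identifier is
  then deliberately *not* re-integrated.
* **Digest mode.** Otherwise the fingerprint is the lowercase MD5 hex
  digest of the record's canonical serialization: keys sorted
  lexicographically (radix order, locale-independent), one `key=value`
  line per selector, joined with `\n`, UTF-8 encoded. Canonicalization
  makes the digest independent of extraction order; sorting ties the
  digest to content only. MD5 is used as a change-detection fingerprint,
  not as a security primitive; collisions are astronomically unlikely at
  the scale of per-agent scopes and would cost one missed event, not
  corruption.

Check-and-insert is a single atomic operation over a batch. Repeated
fingerprints within one batch count once, first occurrence winning, so a
source that repeats rows cannot double-deliver. Two backends implement
the same contract: an in-memory environment (the natural test backend)
and a SQLite table `(scope, fingerprint, first_seen)` with a uniqueness
constraint, the whole batch inside one transaction so a backend failure
inserts nothing. The backend contract is deliberately tiny
(`cache_check_insert`, `cache_size`) so a faster external store can be
plugged in without touching detection semantics. Entries are kept
forever: eviction would re-open the door to duplicate integration, and
the per-agent scope keeps tables small. A delivery failure never rolls
back the cache — delivery verification is a different concern (and an
explicit non-goal), and retrying is the destination operator's decision.

Pushed events *do* populate the cache before routing. Without this, a
source that both pushes and is polled would deliver the same content
twice; with it, push-then-poll is idempotent, which the tests assert.

## The template engine

Rendering is a single left-to-right scan; constructs do not nest.
`%{var}` substitutes a payload variable (unknown variables are errors
naming the variable — silent empty substitution would corrupt
destinations), `${fn}` calls a registered built-in (`datetime` renders
the delivery time as ISO-8601 UTC; the registry is extensible), and
`${code(<script>)}` evaluates an embedded R snippet. Scripts get the
payload variables bound as named string *values* — they are never
textually spliced into the code, which would invite injection and
quoting bugs — and run in a sandbox environment exposing only an
allowlist of computational base functions (arithmetic, comparisons,
control flow, strings, collections, small matrix machinery; no file,
system or network access), bounded by a wall-clock limit of 5 s per
block (tunable via `render_context(timeout=)`). The script must finish
returning a value, which is stringified; vector results join with `;`.

Escaping is opt-in by design: default substitution is plain text, which
matches what a curator writing an `INSERT INTO ... VALUES ('%{gene}')`
template expects, and `escape_sql = TRUE` doubles single quotes in
substituted values for SQL templates. URL `GET` templates always
percent-escape substituted values inside the address, since an address
is not free text. Rendered file paths are confined to the workspace
root: absolute paths and `..` traversal are rejected, because payload
variables flow into paths.

## Scheduling and the job queue

Schedules are configuration, not code: a named list of intervals in the
application settings. The default list is `every_5_minutes`,
`every_15_minutes`, `hourly`, `daily`, `weekly`; five minutes is the
default floor — frequent enough for near real-time freshness, coarse
enough not to hammer origins. An agent is due when its interval has
elapsed since its last run.

Monitoring jobs enter a homogeneous FIFO queue without priorities, with
at most one pending job per agent (a slow source cannot pile up
duplicate work). Processing assigns each job, strictly in arrival order,
to the earliest-free worker of a pool of `worker_limit` (default 2), so
peak concurrency never exceeds the limit: with four queued jobs and two
workers, they run two at a time in order of arrival. The pool is a
deterministic multi-server simulation on an injectable clock — the
recurrence `start_i = max(arrival_i, min(worker free times))` — and each
job's real work executes at its dequeue point. What the package
guarantees (and tests, against an independent discrete-event oracle) is
the contract: FIFO start order, bounded concurrency, failure isolation.
The execution mechanism behind that contract can be swapped (e.g.
parallel R sessions) without changing observable behaviour; timing tests
run instantly on the simulated clock either way.

## The service layer

Every route requires a token; there is no anonymous endpoint. Tokens are
unique 32-character strings over `[a-z0-9]` drawn from a
cryptographically strong source, revocable, and scoped to their owner's
agents (a valid token on a foreign agent is a 403, distinct from the 401
of a missing/revoked token). The API surface is two POST routes —
`/api/agents/<id>/check` (fingerprint verification) and
`/api/agents/<id>/events` (event push) — with JSON bodies. The handler
is an in-process function from requests to responses; `flux_serve()`
mounts it on httpuv for real deployments, and transport security is
delegated to whatever terminates TLS in front of it. Keeping the handler
transport-free means the full HTTP contract (status codes, header
handling, body schemas) is exercised in tests without sockets.

## What the synthetic resources emulate — and what they do not

`make_variant_feed()` writes a minimal Atom-like feed: `feed/entry` with
`id`, `title`, `updated` plus one extension element per payload field
(`gene`, `variant_id`, `hgvs`), no XML namespaces. This captures what
matters for the integration problem — per-gene feeds of uniquely
identified entries that grow over time (`mutate_feed()` appends novel
entries with fresh identifiers) — while deliberately not reproducing any
real feed dialect: no namespaces, no paging, no author/summary
metadata. Variant descriptions are HGVS-*like* random strings
(`c.<pos><ref>><alt>` with distinct positions); no biological validity
is claimed. `make_tabular_resources()` writes one small variant table as
CSV, JSON, XML and SQLite for format-parity tests. Everything is
byte-deterministic under a seed (timestamps derive from a fixed epoch,
not the wall clock).

Passing tests on these fixtures therefore demonstrate the pipeline's
*mechanics* — extraction parity across formats, exactly-once detection,
fan-out accounting, end-to-end warehouse consistency — not robustness to
the messiness of production feeds (schema drift, namespaces, invalid
XML, rate limits, authentication on origins).

Test and acceptance problem sizes are small by choice — tables of 4–6
rows, feeds of 2 genes x 3–4 variants over 3 mutation cycles, queues of
4–10 jobs, 200–10,000 tokens — because every guarantee checked is a
discrete property (counts, orders, byte equality) already fully
exercised at that scale.

## Design decisions on genuinely open points

* **Column numbers are 1-based** (spreadsheet convention); CSV/TSV
  agents take a `has_header` flag (default `TRUE`) and a configurable
  delimiter.
* **Several XML nodes matched by one selector within one item** join
  with `;` — a record field must be a scalar string, and `;` keeps the
  information without inventing nested payloads.
* **Seeds**: with several seeds on one agent, concrete agents are the
  cross product of harvested records. Concrete agents keep the parent's
  id as cache scope, so re-seeding (a gene added to the list) never
  resets detection state for existing genes. Seeds are re-harvested on
  every run — the list is itself living data.
* **Duplicate (integration, template) pairs each fire**: routing is per
  integration membership, making an integration's behaviour independent
  of which other integrations exist. Deliveries for one event run
  sequentially in template-id order, for reproducibility.
* **file/create overwrites**; file/delete of a missing file reports
  success with a warning detail (the desired post-state holds).
* **SQL** destinations execute the rendered text as a single statement;
  connection strings are `sqlite://<path>` (the embedded engine used
  throughout; other DBI backends would slot into the same seam).
  **Email** transport is pluggable — message composition is implemented,
  the wire protocol is injected (an in-process capture sink by default).
  **URL** deliveries use one 15 s network timeout and no retries; retry
  policy belongs to the caller's scheduler, not the delivery primitive.
* **Event routing with zero matching integrations** still caches the
  fingerprint at detection time: novelty is a property of the source,
  not of the current routing table.

## Known limitations

Single-process execution (true parallel workers would need external
worker processes honouring the same queue contract); no delivery
receipts or replay; identifier-mode detection ignores edits under an
unchanged identifier by construction; the code sandbox is an allowlist,
not an OS-level jail, and is intended for trusted-but-fallible curator
scripts rather than adversarial input; SQLite is the only bundled SQL
backend; schedule inference (adapting polling frequency to observed
event rates) is not attempted.
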