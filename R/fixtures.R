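# Synthetic origin resources. Every pipeline in the package is testable
# without touching the network: these generators produce an Atom-like
# variant feed emulating the per-gene feeds served by locus-specific
# database installations, plus logically identical small variant tables in
# CSV, JSON, XML and SQLite form for cross-format tests. Variant
# descriptions are syntactically HGVS-like random strings; no biological
# validity is claimed. The same seed always yields byte-identical output.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

random_hgvs <- function(n) {
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(99999L, n, replace = FALSE)  # distinct positions -> unique strings
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  sprintf("c.%d%s>%s", pos, ref, alt)
}

feed_timestamp <- function(i) {
  format(as.POSIXct("2015-10-13 00:00:00", tz = "UTC") + i * 3600,
         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

feed_entry <- function(gene, index, hgvs) {
  vid <- paste0(gene, ":", index)
  c("  <entry>",
    paste0("    <id>tag:variants:", xml_escape(vid), "</id>"),
    paste0("    <title>", xml_escape(paste(gene, hgvs)), "</title>"),
    paste0("    <updated>", feed_timestamp(index), "</updated>"),
    paste0("    <gene>", xml_escape(gene), "</gene>"),
    paste0("    <variant_id>", xml_escape(vid), "</variant_id>"),
    paste0("    <hgvs>", xml_escape(hgvs), "</hgvs>"),
    "  </entry>")
}

#' Generate a synthetic variant feed
#'
#' Writes a minimal Atom-like XML feed with one `<entry>` per variant.
#' Each entry carries `id`, `title` and `updated` plus one extension
#' element per payload field (`gene`, `variant_id`, `hgvs`). Variant
#' identifiers (`<gene>:<n>`) are unique within a feed, and the same
#' specification produces byte-identical files.
#'
#' @param path Output file path.
#' @param genes Character vector of gene symbols.
#' @param variants_per_gene Number of variants per gene (>= 0).
#' @param seed Integer random seed driving the HGVS-like descriptions.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' make_variant_feed(f, c("BRCA2", "TP53"), variants_per_gene = 3)
#' @export
make_variant_feed <- function(path, genes, variants_per_gene = 5L, seed = 1L) {
  stopifnot(variants_per_gene >= 0L)
  lines <- with_seed(seed, {
    body <- unlist(lapply(genes, function(g) {
      if (variants_per_gene == 0L) return(character())
      hgvs <- random_hgvs(variants_per_gene)
      unlist(lapply(seq_len(variants_per_gene), function(i) {
        feed_entry(g, i, hgvs[[i]])
      }))
    }))
    c('<?xml version="1.0" encoding="UTF-8"?>',
      "<feed>",
      "  <title>synthetic variant feed</title>",
      paste0("  <updated>", feed_timestamp(0L), "</updated>"),
      body,
      "</feed>")
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Append novel variants to an existing feed
#'
#' Emulates curators publishing new variants: appends `k` entries with
#' fresh, unique identifiers (continuing each gene's index sequence) to a
#' feed written by [make_variant_feed()]. Genes are cycled round-robin so
#' repeated mutations spread across the feed's genes.
#'
#' @param path Feed file to mutate in place.
#' @param k Number of novel entries to append (>= 0).
#' @param seed Integer seed for the new HGVS-like descriptions.
#' @return Invisibly, the character vector of appended variant ids.
#' @export
mutate_feed <- function(path, k, seed = 1L) {
  stopifnot(k >= 0L)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    extract_error(paste0("malformed feed ", path, ": ", conditionMessage(e)))
  })
  if (k == 0L) return(invisible(character()))
  ids <- xml2::xml_text(xml2::xml_find_all(doc, "//entry/variant_id"))
  genes <- unique(xml2::xml_text(xml2::xml_find_all(doc, "//entry/gene")))
  if (!length(genes)) genes <- "GENE"
  max_index <- vapply(genes, function(g) {
    idx <- suppressWarnings(as.integer(sub(paste0("^", g, ":"), "",
                                           ids[startsWith(ids, paste0(g, ":"))])))
    if (!length(idx) || all(is.na(idx))) 0L else max(idx, na.rm = TRUE)
  }, 0L)
  new_lines <- character()
  new_ids <- character()
  with_seed(seed, {
    hgvs <- random_hgvs(k)
    for (j in seq_len(k)) {
      g <- genes[[(j - 1L) %% length(genes) + 1L]]
      max_index[[g]] <- max_index[[g]] + 1L
      new_lines <- c(new_lines, feed_entry(g, max_index[[g]], hgvs[[j]]))
      new_ids <- c(new_ids, paste0(g, ":", max_index[[g]]))
    }
  })
  text <- readLines(path, warn = FALSE)
  close_at <- max(which(trimws(text) == "</feed>"))
  writeLines(c(text[seq_len(close_at - 1L)], new_lines, text[close_at:length(text)]),
             path, useBytes = TRUE)
  invisible(new_ids)
}

#' Generate logically identical tabular resources in four formats
#'
#' Writes one small variant table — columns `gene`, `variant`,
#' `pathogenic` — as a CSV file (RFC 4180, with header), a JSON document
#' (`{"variants": [...]}`), an XML document (`<variants><row>...</row>
#' </variants>`) and an embedded SQLite database (table `variants`), for
#' cross-format parity tests. CSV, JSON and XML outputs are byte-stable
#' under the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param n_rows Number of variant rows.
#' @param seed Integer seed.
#' @return A list with the table (`$data`) and the paths `$csv`, `$json`,
#'   `$xml`, `$sqlite`.
#' @export
make_tabular_resources <- function(dir, n_rows = 4L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- c("BRCA2", "TP53", "CFTR", "MLH1", "FBN1", "DMD")
  df <- with_seed(seed, data.frame(
    gene = sample(genes, n_rows, replace = TRUE),
    variant = random_hgvs(n_rows),
    pathogenic = sample(c("yes", "no"), n_rows, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  csv <- file.path(dir, "variants.csv")
  writeLines(c("gene,variant,pathogenic",
               sprintf("%s,%s,%s", df$gene, df$variant, df$pathogenic)),
             csv, useBytes = TRUE)

  json <- file.path(dir, "variants.json")
  writeLines(as.character(jsonlite::toJSON(list(variants = df),
                                           dataframe = "rows", pretty = TRUE)),
             json, useBytes = TRUE)

  xml <- file.path(dir, "variants.xml")
  rows <- unlist(lapply(seq_len(n_rows), function(i) {
    c("  <row>",
      paste0("    <gene>", xml_escape(df$gene[[i]]), "</gene>"),
      paste0("    <variant>", xml_escape(df$variant[[i]]), "</variant>"),
      paste0("    <pathogenic>", df$pathogenic[[i]], "</pathogenic>"),
      "  </row>")
  }))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>', "<variants>", rows,
               "</variants>"), xml, useBytes = TRUE)

  sqlite <- file.path(dir, "variants.sqlite")
  if (file.exists(sqlite)) unlink(sqlite)
  con <- DBI::dbConnect(RSQLite::SQLite(), sqlite)
  DBI::dbWriteTable(con, "variants", df)
  DBI::dbDisconnect(con)

  list(data = df, csv = csv, json = json, xml = xml, sqlite = sqlite)
}
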