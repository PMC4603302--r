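# Template engine. Template text mixes literal content with three kinds of
# placeholder: %{var} substitutes an event payload variable (every template
# variable must have a corresponding agent selector; a variable may be used
# any number of times), ${fn} calls a registered built-in function, and
# ${code(<script>)} evaluates an embedded script with the payload variables
# bound as named string values and substitutes its returned value. Scanning
# is a single left-to-right pass; constructs do not nest.

#' Define a delivery template
#'
#' A template is a typed delivery action whose text fields may contain
#' placeholders rendered at delivery time:
#'
#' * `sql` — `connection` (a `sqlite://<path>` string) and `statement`
#'   (executed as a single statement on the destination). With
#'   `escape_sql = TRUE`, substituted variable values have single quotes
#'   doubled ([quote_sql()]); the default is plain textual substitution.
#' * `email` — `to`, `cc`, `bcc`, `subject`, `message`; all renderable.
#' * `file` — `path` (relative to the workspace root) and `mode` among
#'   `create` (overwrites), `append`, `delete`.
#' * `url` — `address`, `method` (`GET`/`POST`), `payload_format` (`text`,
#'   `json`, `xml`) and `body`. GET renders variables into the address with
#'   percent-escaping of substituted values; POST sends the rendered body
#'   with the matching Content-Type.
#'
#' @param id,name Identifier and display name.
#' @param type One of `"sql"`, `"email"`, `"file"`, `"url"`.
#' @param ... Type-specific fields, see above.
#' @return An object of class `flux_template`.
#' @examples
#' template("t1", "sql", connection = "sqlite:///tmp/dest.sqlite",
#'          statement = "INSERT INTO v VALUES ('%{gene}','%{variant}')")
#' @export
template <- function(id, type, ..., name = id) {
  type <- as.character(type)
  if (!type %in% delivery_types()) {
    config_error(paste0("unsupported template type: ", type,
                        " (supported: ", toString(delivery_types()), ")"))
  }
  fields <- list(...)
  required <- switch(type,
    sql = c("connection", "statement"),
    email = c("to", "subject", "message"),
    file = c("path", "mode"),
    url = c("address", "method")
  )
  missing <- setdiff(required, names(fields))
  if (length(missing)) {
    config_error(paste0(type, " template requires field(s): ", toString(missing)))
  }
  if (identical(type, "file") && !fields$mode %in% c("create", "append", "delete")) {
    config_error("file template mode must be create, append or delete")
  }
  if (identical(type, "url")) {
    if (!fields$method %in% c("GET", "POST")) {
      config_error("url template method must be GET or POST")
    }
    fields$payload_format <- fields$payload_format %||% "text"
    if (!fields$payload_format %in% c("text", "json", "xml")) {
      config_error("url payload_format must be text, json or xml")
    }
  }
  check_placeholder_syntax(fields)
  structure(c(list(id = as.character(id), name = as.character(name), type = type),
              fields),
            class = "flux_template")
}

check_placeholder_syntax <- function(fields) {
  for (f in names(fields)) {
    v <- fields[[f]]
    if (!is.character(v)) next
    # unterminated placeholder opener is a configuration mistake
    stripped <- gsub("%\\{[A-Za-z_][A-Za-z0-9_.]*\\}", "", v)
    stripped <- gsub("\\$\\{[^}]*\\}", "", strip_code_blocks(stripped))
    if (grepl("%\\{|\\$\\{", stripped)) {
      config_error(paste0("malformed placeholder in template field '", f, "': ", v))
    }
  }
}

strip_code_blocks <- function(text) {
  repeat {
    m <- regexpr("\\$\\{code\\(", text)
    if (m == -1L) return(text)
    close <- match_paren(text, m + attr(m, "match.length") - 1L)
    if (is.na(close) || substr(text, close + 1L, close + 1L) != "}") return(text)
    text <- paste0(substr(text, 1L, m - 1L),
                   substr(text, close + 2L, nchar(text)))
  }
}

# position of the ")" matching the "(" at `open`, or NA
match_paren <- function(text, open) {
  depth <- 0L
  chars <- strsplit(substr(text, open, nchar(text)), "", fixed = TRUE)[[1]]
  for (k in seq_along(chars)) {
    if (chars[[k]] == "(") depth <- depth + 1L
    if (chars[[k]] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(open + k - 1L)
    }
  }
  NA_integer_
}

#' Create a rendering context
#'
#' @param variables Named list of payload variables (strings).
#' @param now Delivery timestamp (POSIXct, UTC).
#' @param functions Registry of built-ins, each `function(ctx)` returning a
#'   string; extend by adding entries. Ships with `datetime` (ISO-8601 UTC
#'   time of delivery).
#' @param transform Applied to every substituted variable value (not to
#'   literal text or function output); used for per-type escaping such as
#'   [quote_sql()] or percent-escaping in URLs.
#' @param timeout Wall-clock limit in seconds for one embedded code block.
#' @return A list of class `flux_render_context`.
#' @export
render_context <- function(variables = list(),
                           now = as.POSIXct(Sys.time(), tz = "UTC"),
                           functions = builtin_functions(),
                           transform = identity,
                           timeout = 5) {
  structure(list(variables = lapply(as.list(variables), as.character),
                 now = now, functions = functions, transform = transform,
                 timeout = timeout),
            class = "flux_render_context")
}

#' @rdname render_context
#' @export
builtin_functions <- function() {
  list(
    datetime = function(ctx) format(ctx$now, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
}

#' Double single quotes for SQL string literals
#'
#' Opt-in escaping helper for `sql` templates (`escape_sql = TRUE`): the
#' default delivery behaviour is plain textual substitution.
#'
#' @param x Character vector.
#' @return `x` with every `'` doubled.
#' @export
quote_sql <- function(x) gsub("'", "''", x, fixed = TRUE)

#' Render template text
#'
#' Replaces every `%{var}` with the corresponding context variable, every
#' `${fn}` with the registered function's output and every
#' `${code(<script>)}` with the script's returned value (see [eval_code()]).
#' Literal text is preserved byte-for-byte, and rendering never mutates the
#' context. An unknown variable or function raises a render error naming it.
#'
#' @param text Template text.
#' @param ctx A [render_context()].
#' @return The rendered string, free of placeholder constructs.
#' @examples
#' render("INSERT INTO v VALUES ('%{gene}')",
#'        render_context(list(gene = "BRCA2")))
#' @export
render <- function(text, ctx) {
  stopifnot(inherits(ctx, "flux_render_context"))
  out <- character()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    m <- regexpr("[%$]\\{", rest)
    if (m == -1L) {
      out <- c(out, rest)
      break
    }
    if (m > 1L) out <- c(out, substr(rest, 1L, m - 1L))
    start <- i + m - 1L                       # position of the sigil
    sigil <- substr(text, start, start)
    if (identical(sigil, "%")) {
      close <- find_char(text, start + 2L, "}")
      if (is.na(close)) render_error(paste0("unterminated %{ at position ", start))
      var <- substr(text, start + 2L, close - 1L)
      if (!var %in% names(ctx$variables)) {
        render_error(paste0("unknown variable: ", var), variable = var)
      }
      out <- c(out, ctx$transform(ctx$variables[[var]]))
      i <- close + 1L
    } else {
      if (identical(substr(text, start + 2L, start + 6L), "code(")) {
        close_paren <- match_paren(text, start + 6L)
        if (is.na(close_paren) ||
            substr(text, close_paren + 1L, close_paren + 1L) != "}") {
          render_error(paste0("unterminated ${code( at position ", start))
        }
        script <- substr(text, start + 7L, close_paren - 1L)
        out <- c(out, eval_code(script, ctx))
        i <- close_paren + 2L
      } else {
        close <- find_char(text, start + 2L, "}")
        if (is.na(close)) render_error(paste0("unterminated ${ at position ", start))
        fn <- substr(text, start + 2L, close - 1L)
        impl <- ctx$functions[[fn]]
        if (is.null(impl)) {
          render_error(paste0("unknown function: ", fn), fn = fn)
        }
        out <- c(out, as.character(impl(ctx)))
        i <- close + 1L
      }
    }
  }
  paste(out, collapse = "")
}

find_char <- function(text, from, char) {
  rest <- substr(text, from, nchar(text))
  p <- regexpr(char, rest, fixed = TRUE)
  if (p == -1L) NA_integer_ else from + p - 1L
}

# Allowlisted base functions available to embedded scripts: arithmetic,
# comparison, control flow, string manipulation, collections and small
# matrix machinery — enough for conditional transformations, mappings and
# numerical calculations, but no file, system or network access.
code_allowlist <- c(
  "+", "-", "*", "/", "^", "%%", "%/%", "==", "!=", "<", ">", "<=", ">=",
  "&", "|", "&&", "||", "!", "(", "{", "[", "[[", "$", "<-", "=",
  "[<-", "[[<-", "if", "for", "while", "repeat", "break", "next", "function",
  "c", "list", "vector", "paste", "paste0", "sprintf", "format", "formatC",
  "toupper", "tolower", "substr", "substring", "nchar", "gsub", "sub",
  "grepl", "regmatches", "regexpr", "strsplit", "trimws", "startsWith",
  "endsWith", "ifelse", "switch", "as.numeric", "as.integer", "as.character",
  "as.logical", "is.na", "is.null", "round", "signif", "floor", "ceiling",
  "abs", "exp", "log", "log2", "log10", "sqrt", "min", "max", "sum", "prod",
  "length", "rev", "sort", "unique", "seq", "seq_len", "seq_along", "rep",
  "setNames", "names", "names<-", "unlist", "match", "%in%", "which",
  "any", "all", "identical", "matrix", "dim", "t", "%*%", "nrow", "ncol",
  "return", "invisible", "isTRUE", "isFALSE", "xor", "strtoi", "chartr",
  "mean", "Recall", "vapply", "sapply", "lapply", "Map", "Reduce", "Filter"
)

#' Evaluate an embedded template script
#'
#' Scripts inside `${code(...)}` are R snippets evaluated in a sandbox: the
#' event payload variables are bound as named string values, only an
#' allowlist of computational base functions is visible (no file, system or
#' network access), and execution is bounded by a wall-clock limit. The
#' script must finish returning a value, which is stringified into the
#' rendered output; multiple statements may be separated by `;` or
#' newlines, and the last value wins. Variables are bound as values — they
#' are never textually pre-substituted into the script.
#'
#' @param script The script text.
#' @param ctx A [render_context()] supplying variables and the time limit.
#' @return Character scalar.
#' @examples
#' eval_code("1 + 1", render_context())
#' eval_code('map <- c(yes = "1", no = "0"); map[[pathogenic]]',
#'           render_context(list(pathogenic = "yes")))
#' @export
eval_code <- function(script, ctx) {
  if (!nzchar(trimws(script))) render_error("empty code block")
  exprs <- tryCatch(parse(text = script, keep.source = FALSE),
                    error = function(e) {
                      render_error(paste0("code block syntax error: ",
                                          conditionMessage(e)), script = script)
                    })
  base_fns <- mget(code_allowlist, envir = baseenv(), ifnotfound = list(NULL))
  base_fns <- base_fns[!vapply(base_fns, is.null, TRUE)]
  sandbox <- list2env(base_fns, parent = emptyenv())
  env <- list2env(ctx$variables, parent = sandbox)
  old <- options(warn = 1)
  on.exit({setTimeLimit(Inf, Inf, transient = FALSE); options(old)}, add = TRUE)
  setTimeLimit(elapsed = ctx$timeout, transient = TRUE)
  value <- tryCatch(
    {
      v <- NULL
      for (e in exprs) v <- eval(e, envir = env)
      v
    },
    error = function(e) {
      render_error(paste0("code block failed: ", conditionMessage(e)),
                   script = script)
    }
  )
  setTimeLimit(Inf, Inf, transient = FALSE)
  if (is.null(value) || !length(value)) {
    render_error("code block returned no value", script = script)
  }
  paste(as.character(value), collapse = ";")
}

# ---- JSON (de)serialization --------------------------------------------

#' Serialize templates to and from JSON
#'
#' @param tpl A `flux_template`.
#' @param x A JSON string or parsed list.
#' @return `template_to_json` returns a JSON string; `template_from_json`
#'   the template.
#' @export
template_to_json <- function(tpl) {
  jsonlite::toJSON(unclass(tpl), auto_unbox = TRUE, null = "null")
}

#' @rdname template_to_json
#' @export
template_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  fields <- x[setdiff(names(x), c("id", "name", "type"))]
  do.call(template, c(list(id = x$id, type = x$type, name = x$name %||% x$id),
                      fields))
}
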