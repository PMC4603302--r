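# Seed expansion: one agent definition plus a harvested value list becomes
# many concrete agents, e.g. one variant-feed agent per gene in a list.

seed_placeholder_rx <- "%\\{seed\\.([A-Za-z_][A-Za-z0-9_]*)\\}"

find_seed_placeholders <- function(agent) {
  texts <- c(agent$endpoint, agent$query, agent$items,
             unlist(lapply(agent$selectors, as.character), use.names = FALSE))
  texts <- texts[vapply(texts, is.character, TRUE)]
  m <- regmatches(texts, gregexpr(seed_placeholder_rx, texts))
  unique(sub(seed_placeholder_rx, "\\1", unlist(m)))
}

substitute_seed <- function(text, values) {
  if (!is.character(text)) return(text)
  for (ph in names(values)) {
    text <- gsub(paste0("%{seed.", ph, "}"), values[[ph]], text, fixed = TRUE)
  }
  text
}

seed_value <- function(seed, record) {
  v <- record$values[[seed$placeholder]]
  if (is.null(v) && length(record$values) == 1L) v <- record$values[[1]]
  if (is.null(v)) {
    config_error(paste0("seed '", seed$id, "' record has no value for placeholder '",
                        seed$placeholder, "'"))
  }
  v
}

#' Expand an agent over its seeds
#'
#' Harvests each referenced seed (poll + extract with the seed's own
#' configuration) and returns one concrete agent per combination of
#' harvested records, with every `%{seed.<placeholder>}` occurrence in the
#' endpoint, query, items and selector values substituted. Concrete agents
#' share the parent's cache scope (they keep the parent agent id for change
#' detection), so re-seeding never resets detection state. An agent without
#' seed placeholders expands to itself; an empty seed harvest yields an
#' empty list.
#'
#' @param ws A [flux_workspace()].
#' @param agent The seed-referencing [agent_config()].
#' @param seeds Optional list of [seed_config()] objects; defaults to the
#'   agent's `seed_refs` resolved against the workspace.
#' @return List of concrete `flux_agent` objects.
#' @export
expand_seeds <- function(ws, agent, seeds = NULL) {
  if (is.null(seeds)) {
    missing <- setdiff(agent$seed_refs, names(ws$seeds))
    if (length(missing)) {
      config_error(paste0("agent ", agent$id, " references unknown seed(s): ",
                          toString(missing)))
    }
    seeds <- ws$seeds[agent$seed_refs]
  }
  used <- find_seed_placeholders(agent)
  declared <- vapply(seeds, `[[`, "", "placeholder")
  unresolved <- setdiff(used, declared)
  if (length(unresolved)) {
    config_error(paste0("unresolvable seed placeholder(s): ",
                        paste0("%{seed.", unresolved, "}", collapse = ", ")))
  }
  if (!length(used)) return(list(agent))

  seeds <- seeds[match(used, declared)]
  harvests <- lapply(seeds, function(seed) {
    recs <- extract(ws, poll(ws, seed$harvest), seed$harvest)
    vapply(recs, function(r) seed_value(seed, r), "")
  })
  if (any(!lengths(harvests))) return(list())

  grid <- expand.grid(harvests, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- used
  lapply(seq_len(nrow(grid)), function(i) {
    values <- as.list(grid[i, , drop = FALSE])
    concrete <- agent
    concrete$endpoint <- substitute_seed(agent$endpoint, values)
    concrete$query <- substitute_seed(agent$query, values)
    concrete$items <- substitute_seed(agent$items, values)
    concrete$selectors <- lapply(agent$selectors, substitute_seed, values = values)
    concrete$seed_refs <- character()
    concrete$name <- paste0(agent$name, " [", paste(unlist(values), collapse = ","), "]")
    concrete
  })
}
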