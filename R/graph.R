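#' Build the guideline knowledge graph
#'
#' Encodes the follow-up decision table as a labelled property graph. Each
#' rule contributes one chain
#' `nodule_name -has-> solidity -has_an_attribute-> size_bin
#' -has_an_attribute-> quantity -has_an_attribute-> risk_level
#' -follow_up_is-> followup`; chains sharing a slot prefix share nodes, so
#' the rule set forms a prefix tree whose root is the nodule-name node and
#' whose leaves are the nine follow-up recommendation nodes. Surface forms
#' from the catalog are attached to their canonical nodes with `same_as`
#' edges. Chain-node labels are path-qualified (e.g. `"SOLID|LT6|SINGLE"`)
#' so that `(category, label)` is unique while every complete state selects
#' a unique path; the plain slot value is kept in the `value` attribute.
#'
#' The rule table is checked for mutual exclusivity and full coverage of
#' the valid state space before building; offending states are reported.
#'
#' @param rules decision table (default [default_rules()]).
#' @param catalog catalog tibble (default [default_vocabulary()]).
#' @return object of class `guideline_graph`: a list with elements
#'   `igraph`, `rules`, `catalog`.
#' @export
#' @examples
#' g <- build_guideline_graph()
#' g
build_guideline_graph <- function(rules = default_rules(),
                                  catalog = default_vocabulary()) {
  chk <- check_rules(rules)
  if (!chk$ok) {
    stop_bad_arg(
      "rule table is not a partition of the state space%s%s",
      if (length(chk$uncovered) > 0)
        paste0("; uncovered: ", paste(chk$uncovered, collapse = " ")) else "",
      if (length(chk$overlapping) > 0)
        paste0("; overlapping: ", paste(chk$overlapping, collapse = " ")) else "")
  }
  node <- function(name, category, label, value = label,
                   level = NA_character_, text = NA_character_) {
    tibble::tibble(name = name, category = category, label = label,
                   value = value, level = level, text = text)
  }
  lv <- recommendation_levels()
  nodes <- list(
    node("name:PRESENT", "nodule_name", "PRESENT"),
    node("name:ABSENT", "nodule_name", "ABSENT"),
    node("quantity:SINGLE", "quantity", "SINGLE"),
    node("quantity:MULTIPLE", "quantity", "MULTIPLE"),
    node("risk_level:LOW", "risk_level", "LOW"),
    node("risk_level:HIGH", "risk_level", "HIGH"),
    node(paste0("followup:", lv$level), "followup", lv$level,
         value = lv$level, level = lv$level, text = lv$text))
  edges <- list()
  add_edge <- function(from, to, type, rule_id = NA_character_) {
    edges[[length(edges) + 1]] <<-
      tibble::tibble(from = from, to = to, type = type, rule_id = rule_id)
  }
  seen <- character()
  add_chain_node <- function(name, category, label, value) {
    if (!name %in% seen) {
      nodes[[length(nodes) + 1]] <<- node(name, category, label, value)
      seen <<- c(seen, name)
    }
    name
  }
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    sol <- add_chain_node(paste0("solidity:", r$solidity), "solidity",
                          r$solidity, r$solidity)
    bin_lab <- paste(r$solidity, r$size_bin, sep = "|")
    bin <- add_chain_node(paste0("size_bin:", bin_lab), "size_bin",
                          bin_lab, r$size_bin)
    qty_lab <- paste(bin_lab, r$quantity, sep = "|")
    qty <- add_chain_node(paste0("quantity:", qty_lab), "quantity",
                          qty_lab, r$quantity)
    rsk_lab <- paste(qty_lab, r$risk, sep = "|")
    rsk <- add_chain_node(paste0("risk_level:", rsk_lab), "risk_level",
                          rsk_lab, r$risk)
    add_edge("name:PRESENT", sol, "has")
    add_edge(sol, bin, "has_an_attribute")
    add_edge(bin, qty, "has_an_attribute")
    add_edge(qty, rsk, "has_an_attribute")
    add_edge(rsk, paste0("followup:", r$level), "follow_up_is", r$rule_id)
  }
  # surface forms of the graph's entity categories, attached by same_as
  canon_target <- function(type, canonical) {
    switch(type,
           NODULE_NAME = paste0("name:", canonical),
           SOLIDITY = paste0("solidity:", canonical),
           QUANTITY = paste0("quantity:", canonical),
           RISK_LEVEL = paste0("risk_level:", canonical),
           FOLLOWUP = paste0("followup:", canonical),
           NA_character_)
  }
  surf <- dplyr::filter(catalog, .data$type %in%
                          c("NODULE_NAME", "SOLIDITY", "QUANTITY",
                            "RISK_LEVEL", "FOLLOWUP"))
  for (i in seq_len(nrow(surf))) {
    sname <- paste0("surface:", surf$type[i], "|", surf$surface[i])
    nodes[[length(nodes) + 1]] <- node(sname, "surface_form",
                                       surf$surface[i], surf$canonical[i])
    add_edge(sname, canon_target(surf$type[i], surf$canonical[i]), "same_as")
  }
  node_df <- dplyr::distinct(dplyr::bind_rows(nodes), .data$name,
                             .keep_all = TRUE)
  edge_df <- dplyr::distinct(dplyr::bind_rows(edges))
  g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                     vertices = node_df)
  structure(list(igraph = g, rules = rules, catalog = catalog),
            class = "guideline_graph")
}

graph_frames <- function(graph) {
  list(nodes = tibble::as_tibble(igraph::as_data_frame(graph$igraph,
                                                       what = "vertices")),
       edges = tibble::as_tibble(igraph::as_data_frame(graph$igraph,
                                                       what = "edges")))
}

# traverse the chain for one complete state; returns the followup node
# names reached (0, 1 or more)
traverse_state <- function(frames, solidity, size_bin, quantity, risk) {
  nodes <- frames$nodes
  edges <- frames$edges
  step <- function(from, type, value) {
    to <- edges$to[edges$from %in% from & edges$type == type]
    to[nodes$value[match(to, nodes$name)] %in% value]
  }
  sol <- step("name:PRESENT", "has", solidity)
  bin <- step(sol, "has_an_attribute", size_bin)
  qty <- step(bin, "has_an_attribute", quantity)
  rsk <- step(qty, "has_an_attribute", c(risk, "ANY"))
  edges$to[edges$from %in% rsk & edges$type == "follow_up_is"]
}

#' Structurally validate a guideline graph
#'
#' Checks that (i) every valid complete state reaches exactly one follow-up
#' node, (ii) every risk terminal has exactly one outgoing `follow_up_is`
#' edge, (iii) `follow_up_is` edges terminate only at follow-up nodes,
#' (iv) `same_as` edges connect surface forms to canonical nodes only,
#' (v) every canonical catalog value of the graph's entity categories
#' appears as a node, and (vi) all nine recommendation levels are reachable.
#' Violations are returned as data, not raised.
#'
#' @param graph a `guideline_graph`.
#' @return tibble with columns `check`, `pass`, `detail`; attribute
#'   `"pass"` carries the overall verdict (see [graph_is_valid()]).
#' @export
validate_graph <- function(graph) {
  frames <- graph_frames(graph)
  nodes <- frames$nodes
  edges <- frames$edges
  states <- enumerate_states()
  reached <- purrr::pmap(states[c("solidity", "size_bin", "quantity", "risk")],
                         function(solidity, size_bin, quantity, risk) {
                           traverse_state(frames, solidity, size_bin,
                                          quantity, risk)
                         })
  state_lab <- sprintf("(%s, %s, %s, %s)", states$solidity, states$quantity,
                       states$size_bin, states$risk)
  bad_path <- lengths(reached) != 1
  fu_out <- edges[edges$type == "follow_up_is", ]
  risk_terminals <- nodes$name[nodes$category == "risk_level" &
                                 grepl("\\|", nodes$label)]
  n_fu <- table(factor(fu_out$from, levels = risk_terminals))
  bad_terminal <- names(n_fu)[n_fu != 1]
  fu_bad_target <- fu_out$to[nodes$category[match(fu_out$to, nodes$name)] !=
                               "followup"]
  sa <- edges[edges$type == "same_as", ]
  sa_bad <- sa$from[nodes$category[match(sa$from, nodes$name)] !=
                      "surface_form" |
                      nodes$category[match(sa$to, nodes$name)] ==
                      "surface_form"]
  graph_types <- c(NODULE_NAME = "nodule_name", SOLIDITY = "solidity",
                   QUANTITY = "quantity", RISK_LEVEL = "risk_level",
                   FOLLOWUP = "followup")
  canon <- dplyr::filter(graph$catalog, .data$type %in% names(graph_types)) |>
    dplyr::distinct(.data$type, .data$canonical)
  canon_missing <- purrr::map2_lgl(canon$type, canon$canonical, function(ty, cv) {
    !any(nodes$category == graph_types[[ty]] & nodes$value == cv &
           !grepl("\\|", nodes$label))
  })
  levels_hit <- sort(unique(nodes$level[match(unlist(reached), nodes$name)]))
  missing_levels <- setdiff(recommendation_levels()$level, levels_hit)
  checks <- tibble::tibble(
    check = c("state_paths_unique", "one_followup_per_terminal",
              "follow_up_is_targets", "same_as_shape",
              "canonical_coverage", "levels_reachable"),
    pass = c(!any(bad_path), length(bad_terminal) == 0,
             length(fu_bad_target) == 0, length(sa_bad) == 0,
             !any(canon_missing), length(missing_levels) == 0),
    detail = c(
      if (any(bad_path)) paste("orphan or ambiguous state(s):",
                               paste(state_lab[bad_path], collapse = " ")) else "",
      if (length(bad_terminal) > 0)
        paste("terminal(s) without exactly one follow_up_is:",
              paste(bad_terminal, collapse = " ")) else "",
      if (length(fu_bad_target) > 0)
        paste("follow_up_is into non-followup node(s):",
              paste(fu_bad_target, collapse = " ")) else "",
      if (length(sa_bad) > 0)
        paste("malformed same_as edge(s) at:",
              paste(sa_bad, collapse = " ")) else "",
      if (any(canon_missing))
        paste("canonical value(s) missing from graph:",
              paste(canon$canonical[canon_missing], collapse = " ")) else "",
      if (length(missing_levels) > 0)
        paste("unreachable level(s):",
              paste(missing_levels, collapse = " ")) else ""))
  structure(checks, pass = all(checks$pass))
}

#' @rdname validate_graph
#' @return `graph_is_valid()`: a single logical.
#' @export
graph_is_valid <- function(graph) {
  isTRUE(attr(validate_graph(graph), "pass"))
}

#' Query the graph for a follow-up recommendation
#'
#' Traverses the unique attribute chain matching a complete nodule state
#' and returns the follow-up node it terminates in. An absent state (no
#' nodule) yields `NOT_APPLICABLE` without touching the graph.
#'
#' @param graph a `guideline_graph`.
#' @param state one-row state tibble (see [assemble_state()]).
#' @return one-row tibble with columns `level`, `text`, `rule_id`.
#' @export
#' @examples
#' g <- build_guideline_graph()
#' query_recommendation(g, tibble::tibble(present = TRUE, solidity = "SOLID",
#'   quantity = "SINGLE", size_bin = "LT6", risk = "LOW"))
query_recommendation <- function(graph, state) {
  stopifnot(nrow(state) == 1)
  if (!isTRUE(state$present)) {
    return(tibble::tibble(level = "NOT_APPLICABLE",
                          text = recommendation_text("NOT_APPLICABLE"),
                          rule_id = NA_character_))
  }
  frames <- graph_frames(graph)
  fu <- traverse_state(frames, state$solidity, state$size_bin,
                       state$quantity, state$risk)
  if (length(fu) != 1) {
    stop_bad_arg("state (%s, %s, %s, %s) reaches %d follow-up node(s); graph is invalid",
                 state$solidity, state$quantity, state$size_bin, state$risk,
                 length(fu))
  }
  nodes <- frames$nodes
  edges <- frames$edges
  hit <- which(edges$type == "follow_up_is" & edges$to == fu)
  tibble::tibble(level = nodes$level[match(fu, nodes$name)],
                 text = nodes$text[match(fu, nodes$name)],
                 rule_id = edges$rule_id[hit[1]])
}

#' Export a guideline graph to Cypher or GraphML
#'
#' `cypher` writes one `CREATE` statement per node (labelled with its
#' category, carrying `uid`, `label`, `value`, `level`, `text` properties)
#' and one `MATCH ... CREATE` statement per relationship, using exactly the
#' four relationship types `has`, `has_an_attribute`, `follow_up_is`,
#' `same_as`, ready to pipe into a Neo4j shell. `graphml` uses the standard
#' schema via [igraph::write_graph()] and round-trips node and edge
#' multisets. A graph failing [validate_graph()] is exported with a
#' warning.
#'
#' @param graph a `guideline_graph`.
#' @param path output file path.
#' @param format `"cypher"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("cypher", "graphml")) {
  if (!is.character(format) || !all(format %in% c("cypher", "graphml"))) {
    stop_bad_arg("unknown export format: %s",
                 paste(setdiff(format, c("cypher", "graphml")), collapse = ", "))
  }
  format <- match.arg(format)
  if (!graph_is_valid(graph)) {
    warn("exporting a graph that fails validation",
         class = "noduleaudit_invalid_export")
  }
  frames <- graph_frames(graph)
  if (format == "cypher") {
    esc <- function(x) {
      x[is.na(x)] <- ""
      gsub("\"", "\\\\\"", x)
    }
    n <- frames$nodes
    node_lines <- sprintf(
      "CREATE (:%s {uid: \"%s\", label: \"%s\", value: \"%s\", level: \"%s\", text: \"%s\"});",
      n$category, esc(n$name), esc(n$label), esc(n$value), esc(n$level),
      esc(n$text))
    e <- frames$edges
    edge_lines <- sprintf(
      "MATCH (a {uid: \"%s\"}), (b {uid: \"%s\"}) CREATE (a)-[:%s]->(b);",
      esc(e$from), esc(e$to), e$type)
    writeLines(c(node_lines, edge_lines), path, useBytes = TRUE)
  } else {
    g <- graph$igraph
    for (attr in c("label", "value", "level", "text")) {
      v <- igraph::vertex_attr(g, attr)
      v[is.na(v)] <- ""
      g <- igraph::set_vertex_attr(g, attr, value = v)
    }
    e <- igraph::edge_attr(g, "rule_id")
    if (!is.null(e)) {
      e[is.na(e)] <- ""
      g <- igraph::set_edge_attr(g, "rule_id", value = e)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @export
print.guideline_graph <- function(x, ...) {
  frames <- graph_frames(x)
  cat("<guideline_graph>\n")
  cat(sprintf("  %d nodes, %d edges, %d rules\n",
              nrow(frames$nodes), nrow(frames$edges), nrow(x$rules)))
  cat("  nodes by category:\n")
  tb <- table(frames$nodes$category)
  for (nm in names(tb)) cat(sprintf("    %-14s %d\n", nm, tb[[nm]]))
  cat("  edges by type:\n")
  tb <- table(frames$edges$type)
  for (nm in names(tb)) cat(sprintf("    %-16s %d\n", nm, tb[[nm]]))
  invisible(x)
}

#' Tidy a guideline graph
#'
#' @param x a `guideline_graph`.
#' @param what `"nodes"` or `"edges"`.
#' @param ... unused.
#' @return tibble of nodes (or edges).
#' @export
tidy.guideline_graph <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  graph_frames(x)[[what]]
}

#' @rdname tidy.guideline_graph
#' @return `glance()`: one-row tibble with node/edge/rule counts and the
#'   validation verdict.
#' @export
glance.guideline_graph <- function(x, ...) {
  frames <- graph_frames(x)
  tibble::tibble(n_nodes = nrow(frames$nodes),
                 n_edges = nrow(frames$edges),
                 n_rules = nrow(x$rules),
                 n_followup = sum(frames$nodes$category == "followup"),
                 valid = graph_is_valid(x))
}
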