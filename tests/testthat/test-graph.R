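test_that("the default graph builds deterministically with 9 follow-up nodes", {
  g1 <- build_guideline_graph()
  nodes <- tidy(g1, "nodes")
  expect_equal(sum(nodes$category == "followup"), 9)
  g2 <- build_guideline_graph()
  expect_equal(tidy(g2, "nodes"), nodes)
  expect_equal(tidy(g2, "edges"), tidy(g1, "edges"))
  expect_true(igraph::isomorphic(g1$igraph, g2$igraph))
})

test_that("non-covering or overlapping rule tables are rejected", {
  expect_error(build_guideline_graph(default_rules()[0, ]), "uncovered")
  dropped <- default_rules()[-1, ] # loses (SOLID, SINGLE, LT6, LOW)
  expect_error(build_guideline_graph(dropped),
               "uncovered.*SOLID, SINGLE, LT6, LOW")
  dup <- dplyr::bind_rows(default_rules(),
                          dplyr::mutate(default_rules()[1, ],
                                        rule_id = "rule99", level = "L5"))
  expect_error(build_guideline_graph(dup), "overlapping")
})

test_that("the default graph passes validation", {
  g <- build_guideline_graph()
  v <- validate_graph(g)
  expect_true(all(v$pass))
  expect_true(graph_is_valid(g))
})

test_that("deleting any follow_up_is edge breaks validation, naming the orphan", {
  g <- build_guideline_graph()
  eids <- which(igraph::E(g$igraph)$type == "follow_up_is")
  for (eid in eids) {
    mutant <- g
    mutant$igraph <- igraph::delete_edges(g$igraph, eid)
    v <- validate_graph(mutant)
    expect_false(attr(v, "pass"))
    expect_match(v$detail[v$check == "state_paths_unique"], "orphan")
  }
})

test_that("a terminal with two follow_up_is edges fails validation", {
  g <- build_guideline_graph()
  term <- igraph::ends(g$igraph,
                       which(igraph::E(g$igraph)$type == "follow_up_is")[1])[1]
  mutant <- g
  mutant$igraph <- igraph::add_edges(g$igraph, c(term, "followup:L9"),
                                     attr = list(type = "follow_up_is",
                                                 rule_id = "dup"))
  v <- validate_graph(mutant)
  expect_false(attr(v, "pass"))
  expect_false(v$pass[v$check == "one_followup_per_terminal"])
})

test_that("graph queries return the guideline recommendation", {
  g <- build_guideline_graph()
  lv <- recommendation_levels()
  q <- function(sol, qty, bin, rsk) {
    query_recommendation(g, tibble::tibble(present = TRUE, solidity = sol,
                                           quantity = qty, size_bin = bin,
                                           risk = rsk))
  }
  r1 <- q("SOLID", "SINGLE", "LT6", "LOW")
  expect_equal(r1$level, "L1")
  expect_equal(r1$text, "No routine follow up required")
  expect_equal(q("GROUND_GLASS", "SINGLE", "GE6", "LOW")$level, "L7")
  expect_equal(q("GROUND_GLASS", "SINGLE", "GE6", "HIGH")$level, "L7")
  na <- query_recommendation(g, tibble::tibble(present = FALSE))
  expect_equal(na$level, "NOT_APPLICABLE")
})

test_that("graph queries agree with the oracle on the full state space", {
  g <- build_guideline_graph()
  states <- enumerate_states()
  got <- purrr::map_chr(seq_len(nrow(states)),
                        ~ query_recommendation(g, states[.x, ])$level)
  expect_equal(got, oracle_recommend(states))
  expect_setequal(unique(got), recommendation_levels()$level)
})

test_that("cypher export carries exactly the four relationship types", {
  g <- build_guideline_graph()
  tmp <- withr::local_tempfile(fileext = ".cypher")
  export_graph(g, tmp, "cypher")
  lines <- readLines(tmp)
  rels <- unique(regmatches(lines, regexpr("\\[:[a-z_]+\\]", lines)))
  expect_setequal(rels, c("[:has]", "[:has_an_attribute]",
                          "[:follow_up_is]", "[:same_as]"))
  expect_equal(sum(grepl("^CREATE \\(:", lines)),
               igraph::vcount(g$igraph))
})

test_that("graphml export round-trips node and edge counts", {
  g <- build_guideline_graph()
  tmp <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, tmp, "graphml")
  back <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g$igraph))
  expect_equal(igraph::ecount(back), igraph::ecount(g$igraph))
  expect_setequal(unique(igraph::E(back)$type),
                  unique(igraph::E(g$igraph)$type))
})

test_that("exporting an invalid graph warns; unknown formats error", {
  g <- build_guideline_graph()
  tmp <- withr::local_tempfile(fileext = ".cypher")
  expect_error(export_graph(g, tmp, "dot"), "format")
  mutant <- g
  mutant$igraph <- igraph::delete_edges(
    g$igraph, which(igraph::E(g$igraph)$type == "follow_up_is")[1])
  expect_warning(export_graph(mutant, tmp, "cypher"), "validation")
})

test_that("rule tables round-trip through YAML", {
  rules <- default_rules()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, tmp)
  expect_equal(read_rules(tmp), rules)
})
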