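#' The default follow-up decision table
#'
#' One row per guideline rule over the slots (solidity, quantity, size bin,
#' risk level); `risk = "ANY"` matches both risk levels. Solid nodules use
#' the three-bin size split and distinguish risk below 6 mm; subsolid
#' nodules (ground-glass, part-solid) use the two-bin split and do not
#' depend on risk. The table is the single point of truth for the graph
#' builder and is user-replaceable (see [read_rules()]).
#'
#' @return tibble with columns `rule_id`, `solidity`, `quantity`,
#'   `size_bin`, `risk`, `level`.
#' @export
#' @examples
#' default_rules()
default_rules <- function() {
  out <- tibble::tribble(
    ~solidity, ~quantity, ~size_bin, ~risk, ~level,
    "SOLID", "SINGLE", "LT6", "LOW", "L1",
    "SOLID", "SINGLE", "LT6", "HIGH", "L2",
    "SOLID", "SINGLE", "SIX_TO_8", "ANY", "L3",
    "SOLID", "SINGLE", "GT8", "ANY", "L5",
    "SOLID", "MULTIPLE", "LT6", "LOW", "L1",
    "SOLID", "MULTIPLE", "LT6", "HIGH", "L2",
    "SOLID", "MULTIPLE", "SIX_TO_8", "ANY", "L4",
    "SOLID", "MULTIPLE", "GT8", "ANY", "L4",
    "GROUND_GLASS", "SINGLE", "LT6", "ANY", "L1",
    "GROUND_GLASS", "SINGLE", "GE6", "ANY", "L7",
    "GROUND_GLASS", "MULTIPLE", "LT6", "ANY", "L6",
    "GROUND_GLASS", "MULTIPLE", "GE6", "ANY", "L9",
    "PART_SOLID", "SINGLE", "LT6", "ANY", "L1",
    "PART_SOLID", "SINGLE", "GE6", "ANY", "L8",
    "PART_SOLID", "MULTIPLE", "LT6", "ANY", "L6",
    "PART_SOLID", "MULTIPLE", "GE6", "ANY", "L9")
  dplyr::mutate(out, rule_id = sprintf("rule%02d", dplyr::row_number()),
                .before = 1)
}

#' Enumerate all valid complete nodule states
#'
#' The cross product of solidity, quantity, size bin and risk level,
#' honouring the solidity-dependent size bins (3 bins for solid, 2 for
#' subsolid): 12 + 8 + 8 = 28 states.
#'
#' @return tibble with columns `solidity`, `quantity`, `size_bin`, `risk`
#'   and `present = TRUE`.
#' @export
enumerate_states <- function() {
  grid <- function(sol, bins) {
    tidyr::expand_grid(solidity = sol, quantity = c("SINGLE", "MULTIPLE"),
                       size_bin = bins, risk = c("LOW", "HIGH"))
  }
  out <- dplyr::bind_rows(
    grid("SOLID", c("LT6", "SIX_TO_8", "GT8")),
    grid("GROUND_GLASS", c("LT6", "GE6")),
    grid("PART_SOLID", c("LT6", "GE6")))
  dplyr::mutate(out, present = TRUE, .before = 1)
}

# which rules match each state; returns list of rule_id vectors
match_rules <- function(states, rules) {
  purrr::pmap(states[c("solidity", "quantity", "size_bin", "risk")],
              function(solidity, quantity, size_bin, risk) {
                hit <- rules$solidity == solidity &
                  rules$quantity == quantity &
                  rules$size_bin == size_bin &
                  (rules$risk == risk | rules$risk == "ANY")
                rules$rule_id[hit]
              })
}

# coverage/exclusivity check of a decision table
check_rules <- function(rules) {
  states <- enumerate_states()
  hits <- match_rules(states, rules)
  state_lab <- sprintf("(%s, %s, %s, %s)", states$solidity, states$quantity,
                       states$size_bin, states$risk)
  list(ok = all(lengths(hits) == 1),
       uncovered = state_lab[lengths(hits) == 0],
       overlapping = state_lab[lengths(hits) > 1])
}

#' Brute-force recommendation oracle
#'
#' An independent nested-conditional implementation of the follow-up
#' decision logic, written without reference to the rule table or the
#' knowledge graph. It is the ground truth for the synthetic generator and
#' for graph-equivalence tests.
#'
#' @param states tibble of states (columns `present`, `solidity`,
#'   `quantity`, `size_bin`, `risk`), e.g. from [enumerate_states()] or
#'   [fill_slots()].
#' @return character vector of levels (`L1`..`L9` or `NOT_APPLICABLE`).
#' @export
#' @examples
#' oracle_recommend(tibble::tibble(present = TRUE, solidity = "SOLID",
#'   quantity = "MULTIPLE", size_bin = "LT6", risk = "HIGH"))
oracle_recommend <- function(states) {
  one <- function(present, solidity, quantity, size_bin, risk) {
    if (!isTRUE(present)) return("NOT_APPLICABLE")
    if (solidity == "SOLID") {
      if (size_bin == "LT6") {
        if (risk == "HIGH") "L2" else "L1"
      } else if (size_bin == "SIX_TO_8") {
        if (quantity == "SINGLE") "L3" else "L4"
      } else { # GT8
        if (quantity == "SINGLE") "L5" else "L4"
      }
    } else if (solidity == "GROUND_GLASS") {
      if (quantity == "SINGLE") {
        if (size_bin == "LT6") "L1" else "L7"
      } else {
        if (size_bin == "LT6") "L6" else "L9"
      }
    } else { # PART_SOLID
      if (quantity == "SINGLE") {
        if (size_bin == "LT6") "L1" else "L8"
      } else {
        if (size_bin == "LT6") "L6" else "L9"
      }
    }
  }
  purrr::pmap_chr(
    list(states$present, states$solidity, states$quantity,
         states$size_bin, states$risk),
    function(p, s, q, b, r) one(p, s, q, b, r))
}

#' Read / write a decision table as YAML
#'
#' @param rules rules tibble (see [default_rules()]).
#' @param path file path.
#' @return `read_rules()`: rules tibble; `write_rules()`: `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  assert_columns(rules, c("rule_id", "solidity", "quantity", "size_bin",
                          "risk", "level"))
  yaml::write_yaml(purrr::transpose(as.list(rules)), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  obj <- yaml::read_yaml(path)
  dplyr::bind_rows(purrr::map(obj, tibble::as_tibble))
}
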