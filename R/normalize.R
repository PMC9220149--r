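#' Normalize entity mentions to canonical values
#'
#' Maps surface forms to their canonical values via the catalog (the
#' "same_as" layer). Matching is case-insensitive on the exact surface
#' string; a canonical value maps to itself (idempotence); an unseen
#' surface form yields `"UNKNOWN"` with a warning.
#'
#' @param mentions tibble with columns `type` and `text` (e.g. from
#'   [predict.ner_model()]).
#' @param catalog catalog tibble (default [default_vocabulary()]).
#' @return `normalize_mentions()`: `mentions` with a `canonical` column
#'   added (`NA` for `SIZE`, which is parsed numerically instead);
#'   `normalize_mention()`: a single canonical value.
#' @export
#' @examples
#' normalize_mention("ground-glass", "SOLIDITY")
normalize_mentions <- function(mentions, catalog = default_vocabulary()) {
  assert_columns(mentions, c("type", "text"))
  bad_type <- setdiff(unique(mentions$type), entity_types())
  if (length(bad_type) > 0) {
    stop_bad_arg("unknown entity type(s): %s", paste(bad_type, collapse = ", "))
  }
  # compare on tokenized, lower-cased keys so that surface forms survive
  # the token/offset round trip (punctuation spacing is not significant)
  norm_key <- function(x) {
    purrr::map_chr(x, ~ paste(tolower(tokenize_tokens(.x)), collapse = " "))
  }
  key <- paste(mentions$type, norm_key(mentions$text))
  cat_key <- paste(catalog$type, norm_key(catalog$surface))
  canonical <- catalog$canonical[match(key, cat_key)]
  # canonical values normalize to themselves
  self_hit <- paste(mentions$type, tolower(mentions$text)) %in%
    paste(catalog$type, tolower(catalog$canonical))
  canonical[is.na(canonical) & self_hit] <- mentions$text[is.na(canonical) & self_hit]
  unknown <- is.na(canonical) & mentions$type != "SIZE"
  if (any(unknown)) {
    warn(sprintf("%d mention(s) with unseen surface form mapped to UNKNOWN (e.g. \"%s\")",
                 sum(unknown), mentions$text[unknown][1]),
         class = "noduleaudit_unknown_surface")
    canonical[unknown] <- "UNKNOWN"
  }
  canonical[mentions$type == "SIZE"] <- NA_character_
  dplyr::mutate(mentions, canonical = canonical)
}

#' @rdname normalize_mentions
#' @param text a single surface form.
#' @param type its entity type.
#' @export
normalize_mention <- function(text, type, catalog = default_vocabulary()) {
  normalize_mentions(tibble::tibble(type = type, text = text),
                     catalog = catalog)$canonical
}

#' Parse a size mention to millimetres
#'
#' Accepts the common renderings of nodule size: `"6mm"`, `"7 mm"`,
#' `"0.8cm"` (centimetres are converted, x10), and multi-axis expressions
#' such as `"10×8mm"` or `"10 x 8 mm"`, which return the mean of the axes
#' (the usual measurement convention for nodule diameter).
#'
#' @param text character vector of size mentions.
#' @return numeric vector of sizes in millimetres.
#' @export
#' @examples
#' parse_size_mm(c("6mm", "0.8cm", "10×8mm"))
parse_size_mm <- function(text) {
  purrr::map_dbl(text, function(x) {
    nums <- regmatches(x, gregexpr("[0-9]+(?:\\.[0-9]+)?", x))[[1]]
    if (length(nums) == 0) {
      stop_bad_arg("no parsable size in \"%s\"", x)
    }
    mm <- mean(as.numeric(nums))
    if (grepl("cm", x, ignore.case = TRUE)) mm <- mm * 10
    mm
  })
}

#' Assign a guideline size bin
#'
#' Solid nodules fall into three bins: `LT6` (< 6 mm), `SIX_TO_8`
#' (6-8 mm inclusive, matching the guideline's "6-8 mm" phrasing) and
#' `GT8` (> 8 mm). Subsolid nodules (ground-glass and part-solid) use two
#' bins: `LT6` (< 6 mm) and `GE6` (>= 6 mm).
#'
#' @param size_mm numeric vector of sizes in millimetres (> 0).
#' @param solidity canonical solidity values (`SOLID`, `PART_SOLID`,
#'   `GROUND_GLASS`), recycled against `size_mm`.
#' @return character vector of bins.
#' @export
#' @examples
#' assign_size_bin(c(5.9, 6, 8.1), "SOLID")
#' assign_size_bin(6, "GROUND_GLASS")
assign_size_bin <- function(size_mm, solidity) {
  n <- max(length(size_mm), length(solidity))
  size_mm <- rep_len(size_mm, n)
  solidity <- rep_len(solidity, n)
  if (any(!is.finite(size_mm) | size_mm <= 0)) {
    stop_bad_arg("size_mm must be positive and finite")
  }
  bad <- setdiff(unique(solidity), c("SOLID", "PART_SOLID", "GROUND_GLASS"))
  if (length(bad) > 0) {
    stop_bad_arg("unknown solidity value(s): %s", paste(bad, collapse = ", "))
  }
  dplyr::case_when(
    size_mm < 6 ~ "LT6",
    solidity != "SOLID" ~ "GE6",
    size_mm <= 8 ~ "SIX_TO_8",
    TRUE ~ "GT8")
}

empty_state <- function() {
  tibble::tibble(present = FALSE, solidity = NA_character_,
                 size_mm = NA_real_, size_bin = NA_character_,
                 quantity = NA_character_, risk = NA_character_)
}

#' Assemble the nodule state from a report's mentions
#'
#' Fills the five query slots (presence, solidity, size/size bin, quantity,
#' risk level) from the normalized entity mentions of one report. With no
#' nodule-name mention (or only absence forms) the state is absent. When a
#' slot receives conflicting values the "most suspicious" resolution
#' applies: the largest size wins, `MULTIPLE` beats `SINGLE`, `HIGH` beats
#' `LOW`; solidity conflicts keep the first mention and warn. Missing
#' quantity defaults to `SINGLE`, missing risk to `LOW`, missing solidity
#' to `SOLID` and missing size to the smallest bin — each the least
#' escalating branch of the guideline, and each warned about.
#'
#' @param mentions tibble of one report's mentions with columns `type`,
#'   `text` (a `canonical` column is computed if absent).
#' @param catalog catalog tibble.
#' @return one-row tibble with columns `present`, `solidity`, `size_mm`,
#'   `size_bin`, `quantity`, `risk`.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   type = c("NODULE_NAME", "SOLIDITY", "SIZE", "QUANTITY", "RISK_LEVEL"),
#'   text = c("pulmonary nodule", "solid", "7 mm", "single", "low risk"))
#' assemble_state(m)
assemble_state <- function(mentions, catalog = default_vocabulary()) {
  if (nrow(mentions) == 0) return(empty_state())
  if (!"canonical" %in% names(mentions)) {
    mentions <- normalize_mentions(mentions, catalog)
  }
  by_type <- split(mentions$canonical, mentions$type)
  names_canon <- setdiff(by_type[["NODULE_NAME"]], "UNKNOWN")
  if (!any(names_canon == "PRESENT")) return(empty_state())

  fill_default <- function(slot, value) {
    warn(sprintf("no %s mention; defaulting to %s", slot, value),
         class = "noduleaudit_default_fill")
    value
  }
  sol <- setdiff(by_type[["SOLIDITY"]], "UNKNOWN")
  if (length(sol) == 0) {
    sol <- fill_default("solidity", "SOLID")
  } else if (length(unique(sol)) > 1) {
    warn(sprintf("conflicting solidity mentions (%s); keeping the first",
                 paste(unique(sol), collapse = ", ")),
         class = "noduleaudit_conflict")
  }
  sol <- sol[1]
  qty <- setdiff(by_type[["QUANTITY"]], "UNKNOWN")
  qty <- if (length(qty) == 0) fill_default("quantity", "SINGLE") else
    if (any(qty == "MULTIPLE")) "MULTIPLE" else "SINGLE"
  rsk <- setdiff(by_type[["RISK_LEVEL"]], "UNKNOWN")
  rsk <- if (length(rsk) == 0) fill_default("risk", "LOW") else
    if (any(rsk == "HIGH")) "HIGH" else "LOW"
  size_texts <- mentions$text[mentions$type == "SIZE"]
  if (length(size_texts) == 0) {
    warn("no size mention; defaulting to the smallest size bin",
         class = "noduleaudit_default_fill")
    size_mm <- NA_real_
    bin <- "LT6"
  } else {
    size_mm <- max(parse_size_mm(size_texts))
    bin <- assign_size_bin(size_mm, sol)
  }
  tibble::tibble(present = TRUE, solidity = sol, size_mm = size_mm,
                 size_bin = bin, quantity = qty, risk = rsk)
}

#' @rdname assemble_state
#' @details `fill_slots()` applies [assemble_state()] per report to a
#'   multi-report mentions tibble (requires a `report_id` column); it is
#'   the slot-filling stage of the recommendation pipeline.
#' @export
fill_slots <- function(mentions, catalog = default_vocabulary()) {
  assert_columns(mentions, "report_id")
  if (nrow(mentions) == 0) {
    return(dplyr::bind_cols(tibble::tibble(report_id = character()),
                            empty_state()[0, ]))
  }
  if (!"canonical" %in% names(mentions)) {
    mentions <- normalize_mentions(mentions, catalog)
  }
  mentions |>
    dplyr::group_by(.data$report_id) |>
    dplyr::group_modify(~ assemble_state(.x, catalog = catalog)) |>
    dplyr::ungroup()
}
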