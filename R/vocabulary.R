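#' The nine follow-up recommendation levels
#'
#' Canonical follow-up recommendation classes `L1`-`L9`, ordered from least
#' to most escalated, with their full recommendation texts. These follow
#' the Fleischner Society recommendations for incidentally detected
#' pulmonary nodules: solitary solid nodules by size and patient risk
#' (L1-L3, L5), multiple solid nodules (L4), and single or multiple
#' subsolid (ground-glass / part-solid) nodules (L6-L9).
#'
#' @return tibble with columns `level` (`L1`..`L9`), `rank` (1-9) and
#'   `text` (the recommendation wording).
#' @export
#' @examples
#' recommendation_levels()
recommendation_levels <- function() {
  tibble::tibble(
    level = paste0("L", 1:9),
    rank = 1:9,
    text = c(
      "No routine follow up required",
      "CT review at 12 months",
      paste("CT review between 6 and 12 months, and consider a subsequent",
            "CT review between 18 and 24 months"),
      paste("CT review between 3 and 6 months, and a subsequent CT review",
            "between 18 and 24 months"),
      "Consider CT, PET/CT, or tissue biopsy at 3 months",
      paste("CT review between 3 and 6 months, and if stable, consider",
            "subsequent CT reviews at 2 and 4 years"),
      paste("CT review between 6 and 12 months, and if nodule is persistent,",
            "subsequent CT review every 2 years within a 5-year period"),
      paste("CT review between 3 and 6 months, and if nodule is persistent",
            "or solid content < 6 mm, subsequent CT review every year within",
            "a 5-year period"),
      paste("CT review between 3 and 6 months, and then consider subsequent",
            "CT reviews according to status of most suspicious nodule")))
}

recommendation_text <- function(level) {
  lv <- recommendation_levels()
  out <- lv$text[match(level, lv$level)]
  out[level == "NOT_APPLICABLE"] <- "Not applicable: no pulmonary nodule reported"
  out
}

#' Default canonical catalog / surface-form vocabulary
#'
#' The catalog maps every known surface form to its canonical value, one
#' row per surface form. The default contains 97 entries: 37 locations,
#' 11 shapes, 13 nodule names, 7 solidity forms, 6 quantity forms, 14 risk
#' descriptions and 9 follow-up recommendations. Canonical domains are:
#' `SOLIDITY` -> SOLID / PART_SOLID / GROUND_GLASS; `QUANTITY` -> SINGLE /
#' MULTIPLE; `RISK_LEVEL` -> LOW / HIGH; `NODULE_NAME` -> PRESENT / ABSENT;
#' `FOLLOWUP` -> L1..L9; location and shape forms are their own canonical
#' values. `SIZE` mentions are free-form and parsed numerically instead
#' (see [parse_size_mm()]).
#'
#' @return tibble with columns `type`, `surface`, `canonical`.
#' @export
#' @examples
#' dplyr::count(default_vocabulary(), type)
default_vocabulary <- function() {
  locations <- c(
    "right upper lobe", "right middle lobe", "right lower lobe",
    "left upper lobe", "left lower lobe", "lingula",
    "apical segment of right upper lobe",
    "posterior segment of right upper lobe",
    "anterior segment of right upper lobe",
    "superior segment of right lower lobe",
    "basal segment of right lower lobe",
    "apicoposterior segment of left upper lobe",
    "anterior segment of left upper lobe",
    "superior segment of left lower lobe",
    "basal segment of left lower lobe",
    "medial segment of right middle lobe",
    "lateral segment of right middle lobe",
    "right hilum", "left hilum", "right apex", "left apex",
    "subpleural right upper lobe", "subpleural left upper lobe",
    "peripheral right lower lobe", "peripheral left lower lobe",
    "perifissural right middle lobe",
    "right costophrenic angle", "left costophrenic angle",
    "paramediastinal right lung", "paramediastinal left lung",
    "anterior basal segment of left lower lobe",
    "lateral basal segment of right lower lobe",
    "posterior basal segment of left lower lobe",
    "juxtapleural left lower lobe",
    "central right lung", "central left lung", "both lungs")
  shapes <- c("round", "oval", "irregular", "lobulated", "spiculated",
              "polygonal", "triangular", "flat", "smooth-margined",
              "ill-defined", "well-circumscribed")
  names_present <- c("pulmonary nodule", "lung nodule", "small nodule",
                     "tiny nodule", "micronodule", "nodular opacity",
                     "nodular shadow", "nodular lesion", "nodular density",
                     "pulmonary micronodule")
  names_absent <- c("no pulmonary nodules", "no lung nodules",
                    "no nodular opacity")
  solidity <- tibble::tribble(
    ~surface, ~canonical,
    "solid", "SOLID",
    "solid density", "SOLID",
    "ground-glass", "GROUND_GLASS",
    "ground glass opacity", "GROUND_GLASS",
    "pure ground-glass", "GROUND_GLASS",
    "part-solid", "PART_SOLID",
    "mixed ground-glass", "PART_SOLID")
  quantity <- tibble::tribble(
    ~surface, ~canonical,
    "single", "SINGLE", "solitary", "SINGLE", "one", "SINGLE",
    "multiple", "MULTIPLE", "several", "MULTIPLE", "scattered", "MULTIPLE")
  risk <- tibble::tribble(
    ~surface, ~canonical,
    "low risk", "LOW",
    "low-risk profile", "LOW",
    "never smoker", "LOW",
    "no smoking history", "LOW",
    "no risk factors", "LOW",
    "low clinical suspicion", "LOW",
    "minimal risk factors", "LOW",
    "high risk", "HIGH",
    "high-risk profile", "HIGH",
    "heavy smoker", "HIGH",
    "long smoking history", "HIGH",
    "family history of lung cancer", "HIGH",
    "prior malignancy risk factors", "HIGH",
    "marked emphysema", "HIGH")
  followup <- recommendation_levels()
  dplyr::bind_rows(
    tibble::tibble(type = "LOCATION", surface = locations,
                   canonical = locations),
    tibble::tibble(type = "SHAPE", surface = shapes, canonical = shapes),
    tibble::tibble(type = "NODULE_NAME",
                   surface = c(names_present, names_absent),
                   canonical = rep(c("PRESENT", "ABSENT"),
                                   c(length(names_present),
                                     length(names_absent)))),
    tibble::tibble(type = "SOLIDITY", surface = solidity$surface,
                   canonical = solidity$canonical),
    tibble::tibble(type = "QUANTITY", surface = quantity$surface,
                   canonical = quantity$canonical),
    tibble::tibble(type = "RISK_LEVEL", surface = risk$surface,
                   canonical = risk$canonical),
    tibble::tibble(type = "FOLLOWUP", surface = followup$text,
                   canonical = followup$level))
}

#' Read / write a catalog as YAML
#'
#' The YAML layout is a map from entity type to a list of
#' `{surface, canonical}` entries.
#'
#' @param catalog catalog tibble (see [default_vocabulary()]).
#' @param path file path.
#' @return `read_vocabulary()`: catalog tibble; `write_vocabulary()`:
#'   `path` invisibly.
#' @export
write_vocabulary <- function(catalog, path) {
  assert_columns(catalog, c("type", "surface", "canonical"))
  obj <- purrr::map(split(catalog, catalog$type), function(df) {
    purrr::map(seq_len(nrow(df)),
               ~ list(surface = df$surface[.x], canonical = df$canonical[.x]))
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  obj <- yaml::read_yaml(path)
  dplyr::bind_rows(purrr::imap(obj, function(entries, type) {
    tibble::tibble(type = type,
                   surface = purrr::map_chr(entries, "surface"),
                   canonical = purrr::map_chr(entries, "canonical"))
  })) |>
    dplyr::arrange(match(.data$type, entity_types()))
}
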