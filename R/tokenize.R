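#' Tokenize report text
#'
#' Splits free text into tokens with character offsets. Text containing CJK
#' codepoints is tokenized per character (the standard choice for Chinese
#' clinical text, which has no whitespace word boundaries); otherwise tokens
#' are words, numeric size expressions (`7mm`, `0.8cm`, `10×8mm`,
#' hyphenated words) and single punctuation marks. Offsets are 0-based and
#' end-exclusive.
#'
#' @param text a single character string.
#' @return tibble with columns `token`, `start`, `end` (`end` exclusive);
#'   `substr(text, start + 1, end)` reproduces each token.
#' @export
#' @examples
#' tokenize_text("solid nodule, 10×8mm.")
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  if (grepl("[一-鿿]", text)) {
    pattern <- "\\S"
  } else {
    pattern <- paste0(
      "\\p{N}+(?:\\.\\p{N}+)?(?:[×x*]\\p{N}+(?:\\.\\p{N}+)?)*(?:mm|cm)?",
      "|\\p{L}+(?:-\\p{L}+)*",
      "|[^\\p{L}\\p{N}\\s]")
  }
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(token = substring(text, m, m + len - 1),
                 start = as.integer(m - 1L),
                 end = as.integer(m - 1L + len))
}

tokenize_tokens <- function(text) tokenize_text(text)$token
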