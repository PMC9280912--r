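#' Ordinal C-TIRADS / CEUS-TIRADS categories
#'
#' The Chinese Thyroid Imaging Reporting and Data System grades nodules on
#' the ordinal scale 2 < 3 < 4a < 4b < 4c < 5. Categories are represented
#' throughout this package as the character tokens `"2"`, `"3"`, `"4a"`,
#' `"4b"`, `"4c"`, `"5"`; `category_rank()` maps them to the integers 0..5
#' for rank arithmetic and `rank_to_category()` maps back.
#'
#' @return `category_levels()` returns the six tokens in increasing risk
#'   order.
#' @examples
#' category_levels()
#' category_rank(c("4a", "5"))
#' rank_to_category(0:5)
#' @export
category_levels <- function() {
  c("2", "3", "4a", "4b", "4c", "5")
}

#' @rdname category_levels
#' @param x character vector of category tokens (case-insensitive).
#' @return `as_category()` returns `x` normalised to the canonical tokens;
#'   unknown tokens are an error. `NA` passes through.
#' @export
as_category <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% category_levels())
  if (any(bad)) {
    stop("unknown category token(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         "; expected one of ", paste(category_levels(), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname category_levels
#' @param category character vector of category tokens.
#' @return `category_rank()` returns integer ranks 0..5 (`NA` for `NA`).
#' @export
category_rank <- function(category) {
  match(as_category(category), category_levels()) - 1L
}

#' @rdname category_levels
#' @param rank integer vector in 0..5.
#' @export
rank_to_category <- function(rank) {
  rank <- as.integer(rank)
  if (any(!is.na(rank) & (rank < 0L | rank > 5L))) {
    stop("category rank must lie in 0..5", call. = FALSE)
  }
  category_levels()[rank + 1L]
}
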