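# C-TIRADS counting method: US features -> score -> category -> call.

#' C-TIRADS counting score from conventional-ultrasound features
#'
#' One point is added for each of the five suspicious signs — solid
#' composition, markedly hypoechoic echotexture, vertical (taller-than-wide)
#' orientation, microcalcifications, and an ill-defined or irregular margin
#' (including extrathyroidal extension) — and one point is subtracted for
#' the benign comet-tail artifact, giving an integer in -1..5.
#'
#' @param features data.frame (or named logical vector / list, one record)
#'   with the six flag columns `solid`, `markedly_hypoechoic`,
#'   `vertical_orientation`, `microcalcifications`,
#'   `irregular_or_illdefined_margin`, `comet_tail`. All six must be
#'   present and non-missing.
#' @return integer vector of counting scores.
#' @examples
#' us_score(c(solid = TRUE, markedly_hypoechoic = FALSE,
#'            vertical_orientation = FALSE, microcalcifications = FALSE,
#'            irregular_or_illdefined_margin = TRUE, comet_tail = FALSE))
#' @export
us_score <- function(features) {
  df <- as_feature_frame(features, us_feature_names())
  m <- as.matrix(df)
  mode(m) <- "logical"
  if (any(is.na(m))) {
    stop("all six US feature flags must be present and non-missing", call. = FALSE)
  }
  malignant <- setdiff(us_feature_names(), "comet_tail")
  as.integer(rowSums(m[, malignant, drop = FALSE]) - m[, "comet_tail"])
}

#' Map a counting score to a C-TIRADS category
#'
#' A score of 1 is category 4a, 2 is 4b, and 3-4 is 4c. The published
#' counting table this package follows extends the mapping to the full
#' range: -1 or 0 give category 3 and 5 gives category 5.
#'
#' @param score integer vector in -1..5.
#' @return character vector of category tokens.
#' @examples
#' category_from_score(c(0, 1, 2, 3, 4, 5))
#' @export
category_from_score <- function(score) {
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < -1L | score > 5L)) {
    stop("US counting score must lie in -1..5", call. = FALSE)
  }
  c("3", "3", "4a", "4b", "4c", "4c", "5")[score + 2L]
}

#' Dichotomous malignancy call from a category
#'
#' Categories 4b, 4c and 5 are called malignant; 2, 3 and 4a benign. The
#' same dichotomisation applies to C-TIRADS and to the combined
#' CEUS-TIRADS category ([ceus_tirads_call()] is an alias).
#'
#' @param category character vector of category tokens.
#' @return character vector, `"benign"` or `"malignant"`.
#' @examples
#' ctirads_call(c("4a", "4b", "3"))
#' @export
ctirads_call <- function(category) {
  ifelse(category_rank(category) >= category_rank("4b"), "malignant", "benign")
}
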