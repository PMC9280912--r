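# Weighted CEUS diagnostic score with benign overrides.

#' Default CEUS feature weights
#'
#' Integer weights assigned from the multivariable odds ratios of the four
#' retained CEUS risk features: the dominant feature (hypo-enhancement,
#' the largest odds ratio) scores 2 and each of later arrival time,
#' heterogeneous enhancement and centripetal enhancement scores 1, so the
#' total score ranges over 0..5. Washout is recorded in the data model but
#' deliberately carries no weight (it was dropped from the multivariable
#' model).
#'
#' @return named integer vector with elements `hypo_enhancement`,
#'   `later_arrival`, `heterogeneous`, `centripetal`.
#' @seealso [derive_weights()] to re-derive weights from odds ratios.
#' @export
default_weights <- function() {
  c(hypo_enhancement = 2L, later_arrival = 1L,
    heterogeneous = 1L, centripetal = 1L)
}

check_weights <- function(weights) {
  need <- names(default_weights())
  if (is.null(names(weights)) || !all(need %in% names(weights))) {
    stop("weights must be a named vector with elements ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  w <- weights[need]
  if (any(is.na(w)) || any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  w
}

#' CEUS risk score
#'
#' Weighted sum of the four risk indicators: hypo-enhancement, later
#' arrival time (relative to thyroid parenchyma), heterogeneous
#' enhancement, and centripetal enhancement. Washout never contributes.
#' The score is only defined for enhancing nodules; for absent
#' enhancement it is an error — use [benign_override()] / [ceus_call()],
#' which classify such nodules benign directly.
#'
#' @param features data.frame (or single named list) with the CEUS columns
#'   `enhancement_degree`, `arrival`, `homogeneity`, `pattern` (and
#'   optionally `washout`, `peripheral_ring`, which do not affect the
#'   score).
#' @param weights named nonnegative weights, see [default_weights()].
#' @return integer vector of scores in `0..sum(weights)`.
#' @examples
#' ceus_score(list(enhancement_degree = "hypo", arrival = "later",
#'                 homogeneity = "heterogeneous", pattern = "centripetal"))
#' @export
ceus_score <- function(features, weights = default_weights()) {
  df <- as_feature_frame(features, ceus_feature_names())
  w <- check_weights(weights)
  deg <- df$enhancement_degree
  if (any(is.na(deg))) {
    stop("enhancement_degree is required for every record", call. = FALSE)
  }
  if (any(deg == "absent")) {
    stop("CEUS score is undefined for absent enhancement (record ",
         paste(which(deg == "absent"), collapse = ", "),
         "); such nodules are benign by override", call. = FALSE)
  }
  need <- c("arrival", "homogeneity", "pattern")
  for (col in need) {
    if (any(is.na(df[[col]]))) {
      stop("CEUS feature '", col, "' is required for enhancing nodules",
           call. = FALSE)
    }
  }
  as.integer(w[["hypo_enhancement"]] * (deg == "hypo") +
             w[["later_arrival"]]    * (df$arrival == "later") +
             w[["heterogeneous"]]    * (df$homogeneity == "heterogeneous") +
             w[["centripetal"]]      * (df$pattern == "centripetal"))
}

#' Benign overrides of the CEUS score
#'
#' Two CEUS findings are treated as standalone benign indicators,
#' regardless of the weighted score: absent enhancement, and a regular
#' peripheral hyper-enhancement ring. Absent enhancement takes precedence
#' over the ring when both could apply.
#'
#' @inheritParams ceus_score
#' @return data.frame with logical `is_override` and character `reason`
#'   (`"none"`, `"absent_enhancement"` or `"peripheral_ring"`), one row
#'   per record.
#' @export
benign_override <- function(features) {
  df <- as_feature_frame(features, ceus_feature_names())
  absent <- !is.na(df$enhancement_degree) & df$enhancement_degree == "absent"
  ring <- !absent & !is.na(df$peripheral_ring) & df$peripheral_ring
  data.frame(
    is_override = absent | ring,
    reason = ifelse(absent, "absent_enhancement",
                    ifelse(ring, "peripheral_ring", "none")),
    stringsAsFactors = FALSE
  )
}

#' Dichotomous CEUS call
#'
#' A nodule is called benign when a benign override applies (absent
#' enhancement or peripheral hyper-enhancement ring — overrides take
#' precedence over the score) and otherwise malignant if and only if its
#' CEUS score reaches the cutoff (default 2, the ROC-derived operating
#' point).
#'
#' @inheritParams ceus_score
#' @param cutoff integer score threshold for malignancy.
#' @return character vector, `"benign"` or `"malignant"`.
#' @examples
#' ceus_call(list(enhancement_degree = "iso", arrival = "equal_or_earlier",
#'                homogeneity = "homogeneous", pattern = "diffuse"))
#' @export
ceus_call <- function(features, weights = default_weights(), cutoff = 2L) {
  df <- as_feature_frame(features, ceus_feature_names())
  ov <- benign_override(df)
  out <- rep("benign", nrow(df))
  scoreable <- !ov$is_override
  if (any(scoreable)) {
    s <- ceus_score(df[scoreable, , drop = FALSE], weights)
    out[scoreable] <- ifelse(s >= cutoff, "malignant", "benign")
  }
  out
}
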