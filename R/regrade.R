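# CEUS-TIRADS combination rule: shift the C-TIRADS category by at most
# one level according to the CEUS schedule, with the absent-enhancement
# special case, then dichotomise.

#' Re-grade a C-TIRADS category with the CEUS schedule
#'
#' The combination rule, applied per nodule:
#' \itemize{
#'   \item absent enhancement: the combined category is set to 3 outright;
#'   \item peripheral hyper-enhancement ring, or CEUS score < 2: one
#'     category down;
#'   \item CEUS score = 2: category unchanged (deliberately, to avoid
#'     false positives at the borderline score);
#'   \item CEUS score > 2: one category up.
#' }
#' The study scale only feeds categories 4a-4c, where no boundary is hit;
#' for totality the rule is clamped at the ends of the scale: an upgrade
#' from 5 stays 5, a downgrade from 3 stays 3 (the combined scale never
#' produces category 2), and a downgrade from 2 stays 2.
#'
#' @param category character vector of input category tokens.
#' @param features CEUS feature data.frame, one row per category (a
#'   single-row frame or list is recycled against a length-1 category).
#' @param weights CEUS score weights, see [default_weights()].
#' @return data.frame with columns `input_category`, `output_category`,
#'   `action` (`set_to_3`, `downgrade`, `keep`, `upgrade`) and `trigger`
#'   (`absent_enhancement`, `ring`, `score_lt_2`, `score_eq_2`,
#'   `score_gt_2`).
#' @examples
#' ptc_panel <- list(enhancement_degree = "hypo", arrival = "later",
#'              homogeneity = "heterogeneous", pattern = "centripetal")
#' regrade("4b", ptc_panel)
#' @export
regrade <- function(category, features, weights = default_weights()) {
  category <- as_category(category)
  if (any(is.na(category))) stop("input category is required", call. = FALSE)
  df <- as_feature_frame(features, ceus_feature_names())
  if (nrow(df) == 1 && length(category) > 1) {
    df <- df[rep(1, length(category)), , drop = FALSE]
  }
  if (nrow(df) != length(category)) {
    stop("category and features must have matching length", call. = FALSE)
  }
  ov <- benign_override(df)
  n <- length(category)
  score <- rep(NA_integer_, n)
  enhancing <- !(ov$reason == "absent_enhancement")
  if (any(enhancing)) {
    score[enhancing] <- ceus_score(df[enhancing, , drop = FALSE], weights)
  }

  action <- character(n)
  trigger <- character(n)
  out <- character(n)
  r <- category_rank(category)
  for (i in seq_len(n)) {
    if (ov$reason[i] == "absent_enhancement") {
      action[i] <- "set_to_3"; trigger[i] <- "absent_enhancement"; out[i] <- "3"
    } else if (ov$reason[i] == "peripheral_ring" || score[i] < 2L) {
      action[i] <- "downgrade"
      trigger[i] <- if (ov$reason[i] == "peripheral_ring") "ring" else "score_lt_2"
      # downgrade floor: the combined scale bottoms out at 3 (2 stays 2)
      out[i] <- if (r[i] <= category_rank("3")) category[i] else rank_to_category(r[i] - 1L)
    } else if (score[i] == 2L) {
      action[i] <- "keep"; trigger[i] <- "score_eq_2"; out[i] <- category[i]
    } else {
      action[i] <- "upgrade"; trigger[i] <- "score_gt_2"
      out[i] <- rank_to_category(min(r[i] + 1L, category_rank("5")))
    }
  }
  data.frame(input_category = category, output_category = out,
             action = action, trigger = trigger, stringsAsFactors = FALSE)
}

#' @rdname ctirads_call
#' @export
ceus_tirads_call <- function(category) {
  ctirads_call(category)
}

#' Run the full CEUS-TIRADS model over a cohort
#'
#' Validates the cohort, grades US features to a C-TIRADS category where
#' one is not given, scores the CEUS panel, applies the combination rule
#' and dichotomises both the CEUS schedule and the combined category.
#'
#' @param cohort a `ceus_cohort` data.frame (see [read_cohort()]); every
#'   record needs a complete CEUS panel and either US features or a
#'   C-TIRADS category.
#' @param weights CEUS score weights.
#' @param cutoff CEUS dichotomisation cutoff (the re-grading thresholds
#'   themselves are fixed at score 2, as published).
#' @return the cohort with appended columns `ctirads_category`,
#'   `ceus_score` (NA under absent enhancement), `ceus_call`,
#'   `ceus_tirads_category`, `ceus_tirads_call`, in input order.
#' @examples
#' coh <- build_fixture()
#' head(apply_model(coh))
#' @export
apply_model <- function(cohort, weights = default_weights(), cutoff = 2L) {
  stopifnot(is.data.frame(cohort))
  full <- as_feature_frame(cohort, cohort_columns())
  bad <- validate_cohort(full)
  if (nrow(bad)) {
    stop("invalid record(s): ",
         paste(unique(bad$id), collapse = ", "), "; first violation: ",
         bad$violation[1], call. = FALSE)
  }
  cat_in <- full$ctirads_category
  need <- is.na(cat_in)
  if (any(need)) {
    cat_in[need] <- category_from_score(
      us_score(full[need, us_feature_names(), drop = FALSE]))
  }
  ceus <- full[ceus_feature_names()]
  ov <- benign_override(ceus)
  score <- rep(NA_integer_, nrow(full))
  enh <- ov$reason != "absent_enhancement"
  if (any(enh)) score[enh] <- ceus_score(ceus[enh, , drop = FALSE], weights)
  rg <- regrade(cat_in, ceus, weights)

  out <- cohort
  out$ctirads_category <- cat_in
  out$ceus_score <- score
  out$ceus_call <- ceus_call(ceus, weights, cutoff)
  out$ceus_tirads_category <- rg$output_category
  out$ceus_tirads_call <- ceus_tirads_call(rg$output_category)
  out
}
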