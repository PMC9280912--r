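# Shared builders for test cohorts and feature panels.

us_flags <- function(...) {
  flags <- setNames(as.list(rep(FALSE, 6)),
                    c("solid", "markedly_hypoechoic", "vertical_orientation",
                      "microcalcifications", "irregular_or_illdefined_margin",
                      "comet_tail"))
  on <- c(...)
  flags[on] <- TRUE
  flags
}

# Enhancing CEUS panel attaining a given score under default weights
# (2 hypo + 1 later + 1 heterogeneous + 1 centripetal).
score_panel <- function(score, ring = FALSE) {
  stopifnot(score %in% 0:5)
  list(enhancement_degree = if (score >= 2) "hypo" else "iso",
       arrival = if (score %in% c(1, 3, 4, 5)) "later" else "equal_or_earlier",
       homogeneity = if (score >= 4) "heterogeneous" else "homogeneous",
       pattern = if (score == 5) "centripetal" else "diffuse",
       washout = "later_or_equal",
       peripheral_ring = ring)
}

absent_panel <- function() {
  list(enhancement_degree = "absent", arrival = NA_character_,
       homogeneity = NA_character_, pattern = NA_character_,
       washout = NA_character_, peripheral_ring = NA)
}

make_record <- function(id = "r1", us = us_flags("solid"), ceus = score_panel(0),
                        category = NULL, pathology = NA_character_,
                        age = NA_real_, sex = NA_character_, size = NA_real_) {
  if (is.null(us)) us <- setNames(as.list(rep(NA, 6)), names(us_flags()))
  rec <- c(list(id = id, age = age, sex = sex, size_mm = size), us,
           list(ctirads_category = if (is.null(category)) NA_character_ else category),
           ceus, list(pathology = pathology))
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  do.call(rbind, list(...))
}

# Two worked single-nodule cases: solid + irregular margin (C-TIRADS 4b);
# one scores 0 in CEUS (benign histology), one carries all four risk
# features (PTC).
benign_case_record <- function() {
  make_record(id = "benign-case",
              us = us_flags("solid", "irregular_or_illdefined_margin"),
              ceus = list(enhancement_degree = "iso",
                          arrival = "equal_or_earlier",
                          homogeneity = "homogeneous", pattern = "diffuse",
                          washout = "later_or_equal", peripheral_ring = FALSE),
              pathology = "benign")
}

malignant_case_record <- function() {
  make_record(id = "malignant-case",
              us = us_flags("solid", "irregular_or_illdefined_margin"),
              ceus = list(enhancement_degree = "hypo", arrival = "later",
                          homogeneity = "heterogeneous",
                          pattern = "centripetal",
                          washout = "later_or_equal", peripheral_ring = FALSE),
              pathology = "malignant")
}

# independent pairwise-enumeration oracle for the Mann-Whitney AUC
auc_by_enumeration <- function(scores, truth) {
  mal <- scores[truth == "malignant"]
  ben <- scores[truth == "benign"]
  total <- 0
  for (y in mal) for (z in ben) {
    total <- total + if (y > z) 1 else if (y == z) 0.5 else 0
  }
  total / (length(mal) * length(ben))
}
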