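# Parametric cohort simulator and the deterministic feature-marginal
# reconstruction used for the univariate screen.

#' Default parameters of the synthetic cohort generator
#'
#' Encodes the study conditions of the 228-nodule discovery cohort:
#' prevalence 116/228; C-TIRADS per-class category distributions (from
#' the published per-category class splits, normalised — the source
#' splits sum to 115 malignant / 113 benign against totals of 116/112, an
#' off-by-one carried by the source and documented here); absent
#' enhancement in 20/112 benign and 0/116 malignant nodules; enhancing
#' CEUS feature frequencies per class from the published feature table
#' (malignant denominators 116, benign 92); and per-class age/size
#' normals from the covariate table.
#'
#' @return list of class `cohort_params`; see the field names in the
#'   returned object.
#' @seealso [simulate_cohort()]
#' @export
default_params <- function() {
  p <- list(
    n = 228L,
    prevalence = 116 / 228,
    ctirads_probs = list(
      malignant = c("4a" = 7, "4b" = 67, "4c" = 41) / 115,
      benign    = c("4a" = 62, "4b" = 47, "4c" = 4) / 113),
    absent_prob = c(malignant = 0, benign = 20 / 112),
    degree_probs = list(  # among enhancing nodules
      malignant = c(hypo = 73, iso = 26, hyper = 17) / 116,
      benign    = c(hypo = 18, iso = 45, hyper = 29) / 92),
    later_arrival_prob = c(malignant = 52 / 116, benign = 12 / 92),
    heterogeneous_prob = c(malignant = 74 / 116, benign = 19 / 92),
    centripetal_prob   = c(malignant = 88 / 116, benign = 6 / 92),
    earlier_washout_prob = c(malignant = 20 / 116, benign = 8 / 92),
    ring_prob          = c(malignant = 1 / 116, benign = 28 / 92),
    male_prob          = c(malignant = 23 / 116, benign = 20 / 112),
    age = list(malignant = c(mean = 41.6, sd = 11.1),
               benign    = c(mean = 46.9, sd = 12.7)),
    size_mm = list(malignant = c(mean = 9.2, sd = 5.8),
                   benign    = c(mean = 11.1, sd = 8.1))
  )
  class(p) <- "cohort_params"
  p
}

check_params <- function(params) {
  probs <- c(params$prevalence, params$absent_prob,
             params$later_arrival_prob, params$heterogeneous_prob,
             params$centripetal_prob, params$earlier_washout_prob,
             params$ring_prob, params$male_prob,
             unlist(params$ctirads_probs), unlist(params$degree_probs))
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("invalid params: probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (cls in c("malignant", "benign")) {
    if (abs(sum(params$ctirads_probs[[cls]]) - 1) > 1e-8 ||
        abs(sum(params$degree_probs[[cls]]) - 1) > 1e-8) {
      stop("invalid params: class distributions must sum to 1", call. = FALSE)
    }
    if (params$age[[cls]][["sd"]] <= 0 || params$size_mm[[cls]][["sd"]] <= 0) {
      stop("invalid params: sd must be positive", call. = FALSE)
    }
  }
  if (params$n < 1) stop("invalid params: n must be >= 1", call. = FALSE)
  invisible(params)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

sample_level <- function(n, probs) {
  names(probs)[1 + findInterval(stats::runif(n), cumsum(probs)[-length(probs)])]
}

#' Simulate a synthetic nodule cohort
#'
#' Draws class labels Bernoulli(prevalence), a C-TIRADS category from the
#' per-class category distribution with US features back-filled to a
#' random feature set whose counting score matches the category (score 1
#' for 4a, 2 for 4b, 3 or 4 for 4c; no comet tail), absent enhancement
#' per class, and — for enhancing nodules — CEUS features independently
#' per class from the marginal frequencies. Covariates are normal,
#' truncated at 0. Features are conditionally independent given class; the
#' generator reproduces every class-conditional marginal but no joint
#' structure (see [build_fixture()] for cohorts matching printed joint
#' counts).
#'
#' @param params a `cohort_params` list, see [default_params()].
#' @param seed integer seed; the global RNG state is restored afterwards,
#'   and the same seed always yields the same cohort.
#' @return a `ceus_cohort` data.frame of `params$n` records with
#'   pathology labels; provenance records the seed.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' table(coh$pathology)
#' @export
simulate_cohort <- function(params = default_params(), seed) {
  check_params(params)
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  n <- params$n
  with_seed(seed, {
    pathology <- ifelse(stats::runif(n) < params$prevalence, "malignant", "benign")
    df <- data.frame(id = sprintf("sim-%05d", seq_len(n)),
                     stringsAsFactors = FALSE)
    cls <- pathology
    pick <- function(per_class) unname(per_class[cls])

    df$age <- NA_real_
    df$size_mm <- NA_real_
    df$sex <- ifelse(stats::runif(n) < pick(params$male_prob), "male", "female")
    for (cl in c("malignant", "benign")) {
      idx <- cls == cl
      df$age[idx] <- rnorm_pos(sum(idx), params$age[[cl]][["mean"]],
                               params$age[[cl]][["sd"]])
      df$size_mm[idx] <- rnorm_pos(sum(idx), params$size_mm[[cl]][["mean"]],
                                   params$size_mm[[cl]][["sd"]])
    }

    category <- character(n)
    for (cl in c("malignant", "benign")) {
      idx <- cls == cl
      category[idx] <- sample_level(sum(idx), params$ctirads_probs[[cl]])
    }
    target <- ifelse(category == "4a", 1L,
                     ifelse(category == "4b", 2L,
                            3L + (stats::runif(n) < 0.5)))
    # back-fill a random feature subset of the size the category implies:
    # rank uniform draws within each record, switch on the lowest `target`
    malig_feats <- setdiff(us_feature_names(), "comet_tail")
    u <- matrix(stats::runif(n * 5), n, 5)
    rnk <- vapply(1:5, function(j) rowSums(u <= u[, j]), numeric(n))
    for (j in seq_along(malig_feats)) df[[malig_feats[j]]] <- rnk[, j] <= target
    df$comet_tail <- FALSE
    df$ctirads_category <- category

    absent <- stats::runif(n) < pick(params$absent_prob)
    df$enhancement_degree <- NA_character_
    df$arrival <- NA_character_
    df$homogeneity <- NA_character_
    df$pattern <- NA_character_
    df$washout <- NA_character_
    df$peripheral_ring <- NA
    df$enhancement_degree[absent] <- "absent"
    for (cl in c("malignant", "benign")) {
      idx <- which(cls == cl & !absent)
      k <- length(idx)
      if (k == 0) next
      df$enhancement_degree[idx] <- sample_level(k, params$degree_probs[[cl]])
      df$arrival[idx] <- ifelse(stats::runif(k) < params$later_arrival_prob[[cl]],
                                "later", "equal_or_earlier")
      df$homogeneity[idx] <- ifelse(stats::runif(k) < params$heterogeneous_prob[[cl]],
                                    "heterogeneous", "homogeneous")
      df$pattern[idx] <- ifelse(stats::runif(k) < params$centripetal_prob[[cl]],
                                "centripetal", "diffuse")
      df$washout[idx] <- ifelse(stats::runif(k) < params$earlier_washout_prob[[cl]],
                                "earlier", "later_or_equal")
      df$peripheral_ring[idx] <- stats::runif(k) < params$ring_prob[[cl]]
    }
    df$pathology <- pathology
    new_cohort(df[cohort_columns()],
               provenance = sprintf("simulated (seed %d)", as.integer(seed)))
  })
}

# Deterministically spread k positives over n slots (stride pattern), so
# independently assigned feature columns are not artificially nested.
spread_positions <- function(n, k, offset) {
  if (k == 0) return(integer(0))
  sort(((offset + round(seq(0, n - 1, length.out = k))) %% n) + 1L)
}

#' Enhancing cohort reconstructed from the published feature marginals
#'
#' Builds a deterministic 208-record cohort (116 malignant, 92 benign —
#' the enhancing subset of the study) whose class-conditional marginal
#' counts for every CEUS feature equal the published screening table:
#' e.g. 52/116 malignant with later arrival versus 12/92 benign, 73
#' malignant hypo-enhancing versus 18 benign. Feature columns are filled
#' independently within class (staggered, not nested), so univariate
#' per-feature statistics are exact while joint feature combinations are
#' arbitrary; use it for contingency-level checks, not end-to-end
#' pipeline counts.
#'
#' @return a labelled `ceus_cohort` of 208 enhancing records.
#' @examples
#' univariate_screen(table2_cohort())
#' @export
table2_cohort <- function() {
  counts <- list(
    malignant = list(n = 116, later = 52, hypo = 73, iso = 26,
                     heterogeneous = 74, centripetal = 88,
                     earlier_washout = 20, ring = 1),
    benign    = list(n = 92, later = 12, hypo = 18, iso = 45,
                     heterogeneous = 19, centripetal = 6,
                     earlier_washout = 8, ring = 28))
  build_class <- function(cls, tag) {
    ct <- counts[[cls]]
    n <- ct$n
    df <- data.frame(id = sprintf("t2-%s-%03d", tag, seq_len(n)),
                     stringsAsFactors = FALSE)
    lvl <- rep("hyper", n)
    lvl[seq_len(ct$hypo)] <- "hypo"
    lvl[ct$hypo + seq_len(ct$iso)] <- "iso"
    df$enhancement_degree <- lvl
    two_level <- function(k, yes, no, offset) {
      x <- rep(no, n)
      x[spread_positions(n, k, offset)] <- yes
      x
    }
    df$arrival <- two_level(ct$later, "later", "equal_or_earlier", 3)
    df$homogeneity <- two_level(ct$heterogeneous, "heterogeneous", "homogeneous", 17)
    df$pattern <- two_level(ct$centripetal, "centripetal", "diffuse", 31)
    df$washout <- two_level(ct$earlier_washout, "earlier", "later_or_equal", 47)
    df$peripheral_ring <- rep(FALSE, n)
    df$peripheral_ring[spread_positions(n, ct$ring, 59)] <- TRUE
    df$ctirads_category <- "4b"
    df$pathology <- cls
    df
  }
  df <- rbind(build_class("malignant", "m"), build_class("benign", "b"))
  new_cohort(as_feature_frame(df, cohort_columns()),
             provenance = "feature-marginal reconstruction")
}
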