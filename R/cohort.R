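# Cohort container, CSV I/O and validation.
#
# A cohort is a plain data.frame (class "ceus_cohort") with one row per
# nodule and a fixed set of canonical columns. Optional cells are NA.

us_feature_names <- function() {
  c("solid", "markedly_hypoechoic", "vertical_orientation",
    "microcalcifications", "irregular_or_illdefined_margin", "comet_tail")
}

ceus_feature_names <- function() {
  c("enhancement_degree", "arrival", "homogeneity", "pattern",
    "washout", "peripheral_ring")
}

cohort_columns <- function() {
  c("id", "age", "sex", "size_mm", us_feature_names(),
    "ctirads_category", ceus_feature_names(), "pathology")
}

ceus_vocab <- function() {
  list(enhancement_degree = c("absent", "hypo", "iso", "hyper"),
       arrival            = c("later", "equal_or_earlier"),
       homogeneity        = c("homogeneous", "heterogeneous"),
       pattern            = c("centripetal", "diffuse"),
       washout            = c("earlier", "later_or_equal"))
}

new_cohort <- function(df, provenance = "unspecified") {
  rownames(df) <- NULL
  class(df) <- c("ceus_cohort", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

# Coerce loose single-record input (named list / 1-row data.frame) to a
# data.frame restricted to `cols`, NA-filling absent columns.
as_feature_frame <- function(features, cols) {
  if (is.data.frame(features)) {
    df <- features
  } else if (is.list(features) || (!is.null(names(features)) && is.atomic(features))) {
    df <- as.data.frame(as.list(features), stringsAsFactors = FALSE)
  } else {
    stop("features must be a data.frame or a named list/vector", call. = FALSE)
  }
  for (col in setdiff(cols, names(df))) df[[col]] <- NA
  df[cols]
}

parse_flag <- function(x, column) {
  x <- tolower(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("true", "1", "yes")] <- TRUE
  out[x %in% c("false", "0", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("row %d, column '%s': unknown token '%s' (expected true/false)",
                 bad[1], column, x[bad[1]]), call. = FALSE)
  }
  out
}

parse_enum <- function(x, vocab, column) {
  x <- tolower(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  bad <- which(!is.na(x) & !(x %in% vocab))
  if (length(bad)) {
    stop(sprintf("row %d, column '%s': unknown token '%s' (expected one of %s)",
                 bad[1], column, x[bad[1]], paste(vocab, collapse = ", ")),
         call. = FALSE)
  }
  x
}

parse_num <- function(x, column) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("row %d, column '%s': not a number: '%s'",
                 bad[1], column, x[bad[1]]), call. = FALSE)
  }
  out
}

#' Read a nodule cohort from CSV
#'
#' Reads one nodule per row. Canonical columns are `id`, `age`, `sex`,
#' `size_mm`, the six binary conventional-ultrasound features (`solid`,
#' `markedly_hypoechoic`, `vertical_orientation`, `microcalcifications`,
#' `irregular_or_illdefined_margin`, `comet_tail`), `ctirads_category`,
#' the six CEUS features (`enhancement_degree`, `arrival`, `homogeneity`,
#' `pattern`, `washout`, `peripheral_ring`) and `pathology`. Enumerated
#' cells are matched case-insensitively against the documented vocabulary
#' (e.g. `enhancement_degree` is one of `absent`, `hypo`, `iso`, `hyper`);
#' an unknown token is a parse error naming the row and column. Empty
#' cells become `NA`. The `id` column and the six CEUS columns are
#' required; US features and `ctirads_category` may each be omitted as a
#' whole, but every record must carry at least one of the two (checked by
#' [validate_cohort()]).
#'
#' @param source path, connection or literal CSV text (with a header row).
#' @param schema optional named character vector renaming file columns to
#'   canonical ones: names are canonical column names, values the names
#'   used in the file. See [read_schema()] for the YAML form.
#' @param provenance free-text label stored on the cohort.
#' @return A `ceus_cohort` data.frame in input row order.
#' @seealso [write_cohort()], [validate_cohort()]
#' @examples
#' csv <- "id,enhancement_degree,arrival,homogeneity,pattern,washout,peripheral_ring,ctirads_category
#' n1,hypo,later,heterogeneous,centripetal,later_or_equal,false,4b"
#' read_cohort(textConnection(csv))
#' @export
read_cohort <- function(source, schema = NULL, provenance = "csv") {
  if (is.character(source) && length(source) == 1 && !file.exists(source) &&
      grepl("\n", source)) {
    source <- textConnection(source)
  }
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop("schema must be a fully named character vector (canonical = file column)",
           call. = FALSE)
    }
    for (canon in names(schema)) {
      actual <- schema[[canon]]
      if (!actual %in% names(raw)) {
        stop("schema error: column '", actual, "' (for '", canon,
             "') not present in input", call. = FALSE)
      }
      names(raw)[names(raw) == actual] <- canon
    }
  }
  required <- c("id", ceus_feature_names())
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_us <- any(us_feature_names() %in% names(raw))
  if (!has_us && !("ctirads_category" %in% names(raw))) {
    stop("schema error: need either the six US feature columns or 'ctirads_category'",
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("cohort is empty", call. = FALSE)

  df <- data.frame(id = trimws(raw$id), stringsAsFactors = FALSE)
  if (any(df$id == "")) {
    stop(sprintf("row %d, column 'id': empty identifier", which(df$id == "")[1]),
         call. = FALSE)
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("duplicate id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
  df$age <- parse_num(grab("age"), "age")
  df$sex <- parse_enum(grab("sex"), c("male", "female"), "sex")
  df$size_mm <- parse_num(grab("size_mm"), "size_mm")
  for (col in us_feature_names()) df[[col]] <- parse_flag(grab(col), col)
  df$ctirads_category <- as_category(grab("ctirads_category"))
  vocab <- ceus_vocab()
  for (col in names(vocab)) df[[col]] <- parse_enum(grab(col), vocab[[col]], col)
  df$peripheral_ring <- parse_flag(grab("peripheral_ring"), "peripheral_ring")
  df$pathology <- parse_enum(grab("pathology"), c("benign", "malignant"), "pathology")
  new_cohort(df[cohort_columns()], provenance = provenance)
}

#' Read a column-renaming schema from YAML
#'
#' The YAML file maps canonical column names to the names used in a
#' particular CSV export, e.g. `id: patient_no`. Renaming is the only
#' transformation supported.
#'
#' @param path YAML file path.
#' @return named character vector usable as `schema` in [read_cohort()].
#' @export
read_schema <- function(path) {
  x <- yaml::read_yaml(path)
  unlist(x)
}

format_cohort_cell <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(x, "true", "false")
  } else if (is.numeric(x)) {
    out <- vapply(x, function(v) if (is.na(v)) NA_character_ else
      format(v, scientific = FALSE, trim = TRUE), character(1))
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- ""
  out
}

#' Write a nodule cohort to CSV
#'
#' Columns are written in the canonical order with the documented enum
#' tokens; flags become `true`/`false` and absent optional values become
#' empty cells. Output is deterministic: writing the same cohort twice
#' produces byte-identical files, and `read_cohort(write_cohort(x))` is
#' the identity on valid cohorts.
#'
#' @param cohort a `ceus_cohort` data.frame (extra, non-canonical columns
#'   such as the annotation columns added by [apply_model()] are written
#'   after the canonical ones).
#' @param sink path or connection.
#' @return `invisible(cohort)`.
#' @export
write_cohort <- function(cohort, sink) {
  stopifnot(is.data.frame(cohort))
  cols <- c(intersect(cohort_columns(), names(cohort)),
            setdiff(names(cohort), cohort_columns()))
  out <- as.data.frame(lapply(cohort[cols], format_cohort_cell),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- cols
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE, na = "")
  invisible(cohort)
}

validate_one <- function(rec) {
  v <- character(0)
  add <- function(field, rule) sprintf("%s: %s", field, rule)
  if (!is.na(rec$age) && rec$age < 0) v <- c(v, add("age", "must be >= 0"))
  if (!is.na(rec$size_mm) && rec$size_mm <= 0) v <- c(v, add("size_mm", "must be > 0"))

  us <- unlist(rec[us_feature_names()])
  us_complete <- !any(is.na(us))
  us_any <- any(!is.na(us))
  if (us_any && !us_complete) {
    v <- c(v, add("us", "US feature set must be complete (all six flags) when present"))
  }
  has_cat <- !is.na(rec$ctirads_category)
  if (!us_complete && !has_cat) {
    v <- c(v, add("record", "needs US features or ctirads_category"))
  }
  if (us_complete && has_cat) {
    implied <- category_from_score(us_score(rec[us_feature_names()]))
    if (implied != rec$ctirads_category) {
      v <- c(v, add("ctirads_category",
                    sprintf("inconsistent with US features (grading gives %s)", implied)))
    }
  }

  deg <- rec$enhancement_degree
  descr <- c("arrival", "homogeneity", "pattern", "washout", "peripheral_ring")
  if (is.na(deg)) {
    v <- c(v, add("enhancement_degree", "required"))
  } else if (deg == "absent") {
    present <- descr[!vapply(rec[descr], is.na, logical(1))]
    if (length(present)) {
      v <- c(v, add(paste(present, collapse = ","),
                    "descriptor not applicable under absent enhancement"))
    }
  } else {
    missing <- descr[vapply(rec[descr], is.na, logical(1))]
    if (length(missing)) {
      v <- c(v, add(paste(missing, collapse = ","),
                    "required for enhancing nodules"))
    }
  }
  v
}

#' Validate nodule records
#'
#' Checks every type invariant of the cohort data model: covariate ranges,
#' completeness of the US feature set, presence of at least one of US
#' features / C-TIRADS category (and their mutual consistency under the
#' counting method when both are given), and the CEUS panel rules —
#' enhancing nodules must carry the full descriptor panel, while nodules
#' with absent enhancement must have all other descriptors marked
#' not-applicable (empty). Violations are returned, never raised.
#'
#' @param cohort a `ceus_cohort` data.frame.
#' @param record a single record (1-row data.frame or named list).
#' @return `validate_cohort()`: a data.frame with columns `row`, `id`,
#'   `violation` (zero rows when the cohort is valid).
#'   `validate_record()`: a character vector of violations (empty when
#'   valid).
#' @examples
#' rec <- list(id = "n1", enhancement_degree = "absent",
#'             homogeneity = "heterogeneous", ctirads_category = "4b")
#' validate_record(rec)
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  full <- as_feature_frame(cohort, cohort_columns())
  out <- data.frame(row = integer(0), id = character(0),
                    violation = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(full))) {
    v <- validate_one(full[i, ])
    if (length(v)) {
      out <- rbind(out, data.frame(row = i, id = as.character(full$id[i]),
                                   violation = v, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' @rdname validate_cohort
#' @export
validate_record <- function(record) {
  full <- as_feature_frame(record, cohort_columns())
  if (nrow(full) != 1) stop("validate_record() expects a single record", call. = FALSE)
  validate_one(full[1, ])
}
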