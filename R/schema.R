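#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

FEATURE_CATEGORIES <- c(
  "demographics", "admission", "resources", "diagnosis",
  "procedure", "lab", "medication", "outcome"
)
VALUE_KINDS <- c("categorical", "continuous_quartile", "lab_reference", "age")

abort_validation <- function(msg, ...) {
  abort(msg, class = "emr2vec_validation", ...)
}

#' Declare a single feature of the record schema
#'
#' A feature is one column of the wide record table. Its `value_kind` decides
#' how raw values are discretized into medical-concept tokens: categorical
#' values pass through verbatim, `age` uses the fixed age bands, `lab_reference`
#' classifies against a clinical reference range, and `continuous_quartile`
#' uses cohort-fitted quartile edges. Outcome-category features are never
#' tokenized; they are held out for evaluating representations.
#'
#' @param feature_id Character scalar; must not contain whitespace or `=`
#'   (the token delimiter).
#' @param category One of `r paste0('"', FEATURE_CATEGORIES, '"', collapse = ", ")`.
#' @param value_kind One of `r paste0('"', VALUE_KINDS, '"', collapse = ", ")`.
#' @param reference_range Length-2 numeric `(lo, hi)`, `lo < hi`; required for
#'   (and only allowed with) `value_kind = "lab_reference"`.
#' @param n_lab_classes 2 (normal/abnormal) or 3 (low/medium/high); only
#'   meaningful with `value_kind = "lab_reference"`.
#' @return A one-row tibble that can be row-bound into a schema.
#' @examples
#' feature_spec("glucose", "lab", "lab_reference",
#'   reference_range = c(3.9, 6.1), n_lab_classes = 3)
#' @export
feature_spec <- function(feature_id, category, value_kind,
                         reference_range = NULL, n_lab_classes = NULL) {
  if (!is.character(feature_id) || length(feature_id) != 1L || is.na(feature_id) ||
      grepl("[=[:space:]]", feature_id)) {
    abort_validation("`feature_id` must be a single string without '=' or whitespace.")
  }
  category <- match.arg(category, FEATURE_CATEGORIES)
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (value_kind == "lab_reference") {
    if (is.null(reference_range) || length(reference_range) != 2L ||
        !is.numeric(reference_range) || any(!is.finite(reference_range)) ||
        reference_range[1] >= reference_range[2]) {
      abort_validation("`lab_reference` features need a finite reference_range (lo, hi) with lo < hi.")
    }
    if (is.null(n_lab_classes)) n_lab_classes <- 2L
    if (!n_lab_classes %in% c(2L, 3L)) {
      abort_validation("`n_lab_classes` must be 2 or 3.")
    }
  } else {
    if (!is.null(reference_range)) {
      abort_validation("`reference_range` is only valid for lab_reference features.")
    }
    if (!is.null(n_lab_classes)) {
      abort_validation("`n_lab_classes` is only valid for lab_reference features.")
    }
  }
  tibble(
    feature_id = feature_id,
    category = category,
    value_kind = value_kind,
    ref_lo = if (value_kind == "lab_reference") reference_range[1] else NA_real_,
    ref_hi = if (value_kind == "lab_reference") reference_range[2] else NA_real_,
    n_lab_classes = if (value_kind == "lab_reference") as.integer(n_lab_classes) else NA_integer_
  )
}

#' Assemble and validate a feature schema
#'
#' @param ... One-row tibbles from [feature_spec()], or data frames of them.
#' @return A tibble with class `emr_schema`, one row per feature, in the order
#'   given (this order is the deterministic initial token order of sentences).
#' @export
feature_schema <- function(...) {
  sch <- bind_rows(...)
  as_feature_schema(sch)
}

#' @rdname feature_schema
#' @param x A data frame with at least `feature_id`, `category`, `value_kind`
#'   columns (plus `ref_lo`, `ref_hi`, `n_lab_classes` for labs).
#' @export
as_feature_schema <- function(x) {
  x <- as_tibble(x)
  needed <- c("feature_id", "category", "value_kind")
  if (!all(needed %in% names(x))) {
    abort_validation("A schema needs feature_id, category and value_kind columns.")
  }
  for (col in c("ref_lo", "ref_hi")) if (!col %in% names(x)) x[[col]] <- NA_real_
  if (!"n_lab_classes" %in% names(x)) x$n_lab_classes <- NA_integer_
  x$n_lab_classes <- as.integer(x$n_lab_classes)
  if (anyDuplicated(x$feature_id)) {
    abort_validation("Duplicate feature_id in schema.")
  }
  bad <- setdiff(unique(x$category), FEATURE_CATEGORIES)
  if (length(bad)) abort_validation(paste0("Unknown category: ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(x$value_kind), VALUE_KINDS)
  if (length(bad)) abort_validation(paste0("Unknown value_kind: ", paste(bad, collapse = ", ")))
  lab <- x$value_kind == "lab_reference"
  if (any(lab & (!is.finite(x$ref_lo) | !is.finite(x$ref_hi) | x$ref_lo >= x$ref_hi))) {
    abort_validation("Every lab_reference feature needs a finite reference range with lo < hi.")
  }
  if (any(lab & !x$n_lab_classes %in% c(2L, 3L))) {
    abort_validation("lab_reference features need n_lab_classes in {2, 3}.")
  }
  if (any(!lab & !is.na(x$n_lab_classes))) {
    abort_validation("n_lab_classes is defined only for lab_reference features.")
  }
  class(x) <- c("emr_schema", class(tibble()))
  x
}

schema_assert <- function(schema) {
  if (!inherits(schema, "emr_schema")) schema <- as_feature_schema(schema)
  schema
}

#' Read / write a schema as YAML
#'
#' The YAML layout is a `features:` list with one entry per feature carrying
#' `id`, `category`, `value_kind`, and for labs `reference_range: [lo, hi]`
#' and `n_classes`.
#'
#' @param path File path.
#' @return `read_schema_yaml()` returns an `emr_schema` tibble;
#'   `write_schema_yaml()` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  feats <- y$features %||% y
  rows <- purrr::map(feats, function(f) {
    feature_spec(
      feature_id = f$id %||% f$feature_id,
      category = f$category,
      value_kind = f$value_kind,
      reference_range = if (!is.null(f$reference_range)) as.numeric(f$reference_range),
      n_lab_classes = f$n_classes %||% f$n_lab_classes
    )
  })
  feature_schema(!!!rows)
}

#' @rdname read_schema_yaml
#' @param schema An `emr_schema`.
#' @export
write_schema_yaml <- function(schema, path) {
  schema <- schema_assert(schema)
  feats <- purrr::pmap(schema, function(feature_id, category, value_kind,
                                        ref_lo, ref_hi, n_lab_classes, ...) {
    f <- list(id = feature_id, category = category, value_kind = value_kind)
    if (value_kind == "lab_reference") {
      f$reference_range <- c(ref_lo, ref_hi)
      f$n_classes <- n_lab_classes
    }
    f
  })
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write patient records
#'
#' Records travel as one wide table: one row per patient (first admission
#' only), one column per schema feature, `NA` for a feature the patient does
#' not have (missing labs are legal and simply produce no token). JSON-Lines
#' holds one record object per line; absent keys are missing values.
#'
#' @param path File path.
#' @return A tibble of records.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_validation("No records in file.")
  recs <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x[purrr::map_lgl(x, is.null)] <- NA
    as_tibble(x)
  })
  bind_rows(recs)
}

#' @rdname read_records_jsonl
#' @param records A records tibble (must contain `patient_id`).
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    row <- as.list(records[i, ])
    row <- row[!purrr::map_lgl(row, ~ length(.x) == 1L && is.na(.x))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname read_records_jsonl
#' @export
read_records_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname read_records_jsonl
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
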