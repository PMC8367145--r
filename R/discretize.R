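AGE_LABELS <- c("lt18", "18-34", "35-44", "45-59", "ge60")
AGE_BREAKS <- c(0, 18, 35, 45, 60, Inf)

#' Build and parse medical-concept tokens
#'
#' A medical concept is a (feature, discrete value) pair written canonically
#' as `"feature_id=value"`. Formatting then parsing is the identity.
#'
#' @param feature_id,value Character vectors (recycled).
#' @return `concept_token()` a character vector of tokens; `parse_concept()`
#'   a tibble with `feature_id` and `value` columns (split at the first `=`).
#' @examples
#' concept_token("sex", "male")
#' parse_concept("age=ge60")
#' @export
concept_token <- function(feature_id, value) {
  paste0(feature_id, "=", value)
}

#' @rdname concept_token
#' @param token Character vector of canonical tokens.
#' @export
parse_concept <- function(token) {
  pos <- regexpr("=", token, fixed = TRUE)
  if (any(pos < 0)) abort_validation("Token without '=' delimiter.")
  tibble(
    feature_id = substr(token, 1L, pos - 1L),
    value = substr(token, pos + 1L, nchar(token))
  )
}

#' Discretize age into the five standard bands
#'
#' Bands are `<18`, `18-34`, `35-44`, `45-59`, `>=60` years; a boundary age
#' belongs to the upper band (18 is "18-34", 60 is "ge60").
#'
#' @param age Numeric vector of ages in years, all `>= 0`.
#' @param feature_id Token feature id (default `"age"`).
#' @return Character vector of tokens such as `"age=ge60"`; `NA` in, `NA` out.
#' @examples
#' bin_age(c(17, 18, 64))
#' @export
bin_age <- function(age, feature_id = "age") {
  if (!is.numeric(age)) abort_validation("`age` must be numeric.")
  if (any(age < 0, na.rm = TRUE)) abort_validation("Negative age.")
  idx <- findInterval(age, AGE_BREAKS[-1]) + 1L  # boundary -> upper band
  out <- concept_token(feature_id, AGE_LABELS[idx])
  out[is.na(age)] <- NA_character_
  out
}

#' Classify a laboratory value against its reference range
#'
#' With 3 classes the reference interval is closed: `value < lo` is "low",
#' `lo <= value <= hi` is "medium", `value > hi` is "high". With 2 classes,
#' inside the interval (inclusive) is "normal", outside "abnormal".
#'
#' @param value Numeric vector of measured values.
#' @param lo,hi Reference range bounds, `lo < hi`.
#' @param n_classes 2 or 3.
#' @param feature_id Token feature id; when `NULL` the bare class label is
#'   returned instead of a token.
#' @return Character vector; `NA` in, `NA` out. Non-finite (non-`NA`) values
#'   are a validation error.
#' @examples
#' bin_lab(c(7.8, 5.0, 3.9), lo = 3.9, hi = 6.1, n_classes = 3, feature_id = "glucose")
#' @export
bin_lab <- function(value, lo, hi, n_classes = 3L, feature_id = NULL) {
  if (!is.numeric(value)) abort_validation("`value` must be numeric.")
  if (any(!is.finite(value) & !is.na(value))) {
    abort_validation("Non-finite laboratory value.")
  }
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort_validation("Reference range must satisfy lo < hi.")
  }
  if (!n_classes %in% c(2L, 3L)) abort_validation("`n_classes` must be 2 or 3.")
  cls <- if (n_classes == 3L) {
    ifelse(value < lo, "low", ifelse(value > hi, "high", "medium"))
  } else {
    ifelse(value >= lo & value <= hi, "normal", "abnormal")
  }
  if (is.null(feature_id)) cls else {
    out <- concept_token(feature_id, cls)
    out[is.na(value)] <- NA_character_
    out
  }
}

#' Fit and apply cohort quartile bins
#'
#' `fit_quartile_bins()` computes the 25/50/75th percentiles of the fitting
#' cohort; `apply_quartile_bin()` assigns values to `Q1..Q4` with right-closed
#' edges (a value exactly at an edge falls in the lower bin). Values outside
#' the fitted range clamp to the outer bins, so frozen edges can be reapplied
#' to unseen data.
#'
#' @param values Numeric vector with at least 4 distinct finite values.
#' @return `fit_quartile_bins()` the numeric edges `c(q25, q50, q75)`;
#'   `apply_quartile_bin()` tokens `"<feature_id>=Q1"` ... (or bare labels
#'   when `feature_id` is `NULL`).
#' @examples
#' e <- fit_quartile_bins(1:8)
#' apply_quartile_bin(c(1, 4.5, 8), e, feature_id = "los")
#' @export
fit_quartile_bins <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 4L) {
    abort_validation("degenerate feature: need >= 4 distinct values to fit quartiles.")
  }
  stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}

#' @rdname fit_quartile_bins
#' @param value Numeric vector to bin.
#' @param edges Edges from [fit_quartile_bins()].
#' @param feature_id Optional token feature id.
#' @export
apply_quartile_bin <- function(value, edges, feature_id = NULL) {
  if (length(edges) != 3L || any(!is.finite(edges)) || is.unsorted(edges)) {
    abort_validation("`edges` must be the three sorted finite quartile edges.")
  }
  # right-closed: value <= edge goes to the lower bin
  idx <- 1L + (value > edges[1]) + (value > edges[2]) + (value > edges[3])
  lab <- paste0("Q", idx)
  lab[is.na(value)] <- NA_character_
  if (is.null(feature_id)) lab else {
    out <- concept_token(feature_id, lab)
    out[is.na(value)] <- NA_character_
    out
  }
}

#' Fit quartile edges for every continuous_quartile feature of a schema
#'
#' @param records Records tibble (the fitting cohort).
#' @param schema An `emr_schema`.
#' @return Named list of length-3 numeric edge vectors, one per
#'   `continuous_quartile` feature present in `records`.
#' @export
fit_bin_edges <- function(records, schema) {
  schema <- schema_assert(schema)
  feats <- schema$feature_id[schema$value_kind == "continuous_quartile"]
  feats <- intersect(feats, names(records))
  edges <- purrr::map(feats, ~ fit_quartile_bins(as.numeric(records[[.x]])))
  stats::setNames(edges, feats)
}

#' Persist fitted bin edges as JSON
#'
#' @param edges Named list from [fit_bin_edges()].
#' @param path File path.
#' @export
write_bin_edges <- function(edges, path) {
  jsonlite::write_json(edges, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_bin_edges
#' @export
read_bin_edges <- function(path) {
  purrr::map(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}

#' Tokenize patient records into concept sentences
#'
#' Every present, non-outcome feature value becomes exactly one token;
#' missing features yield no token (no imputation on the corpus path).
#' The initial token order is the schema order, so tokenization is fully
#' deterministic given records, schema and fitted edges.
#'
#' @param records Records tibble with `patient_id` plus feature columns.
#' @param schema An `emr_schema` covering every feature column present.
#' @param edges Named list of quartile edges from [fit_bin_edges()]
#'   (required iff the schema has `continuous_quartile` features present).
#' @return A tibble with `patient_id` and a `tokens` list-column of character
#'   vectors (the concept sentences).
#' @examples
#' sch <- feature_schema(
#'   feature_spec("sex", "demographics", "categorical"),
#'   feature_spec("age", "demographics", "age")
#' )
#' tokenize_records(tibble::tibble(patient_id = "p1", sex = "male", age = 64), sch)
#' @export
tokenize_records <- function(records, schema, edges = list()) {
  schema <- schema_assert(schema)
  if (!"patient_id" %in% names(records)) {
    abort_validation("`records` must contain a patient_id column.")
  }
  if (anyDuplicated(records$patient_id)) {
    abort_validation("Duplicate patient_id: keep only the first admission per patient.")
  }
  feat_cols <- setdiff(names(records), "patient_id")
  unknown <- setdiff(feat_cols, schema$feature_id)
  if (length(unknown)) {
    abort_validation(paste0(
      "Record features missing from schema: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  use <- schema[schema$category != "outcome" & schema$feature_id %in% feat_cols, ]
  n <- nrow(records)
  tok <- matrix(NA_character_, nrow = n, ncol = nrow(use))
  for (j in seq_len(nrow(use))) {
    fid <- use$feature_id[j]
    v <- records[[fid]]
    tok[, j] <- switch(use$value_kind[j],
      categorical = {
        v <- as.character(v)
        out <- concept_token(fid, v)
        out[is.na(v) | !nzchar(v)] <- NA_character_
        out
      },
      age = bin_age(as.numeric(v), feature_id = fid),
      lab_reference = bin_lab(as.numeric(v), use$ref_lo[j], use$ref_hi[j],
                              use$n_lab_classes[j], feature_id = fid),
      continuous_quartile = {
        if (is.null(edges[[fid]])) {
          abort_validation(paste0("No fitted quartile edges for feature '", fid, "'."))
        }
        apply_quartile_bin(as.numeric(v), edges[[fid]], feature_id = fid)
      }
    )
  }
  sentences <- purrr::map(seq_len(n), function(i) {
    s <- tok[i, ]
    s[!is.na(s)]
  })
  empty <- lengths(sentences) == 0L
  if (any(empty)) {
    abort_validation(paste0(
      "Records with no tokenizable (non-outcome) feature: ",
      paste(utils::head(records$patient_id[empty], 5), collapse = ", ")
    ))
  }
  tibble(patient_id = as.character(records$patient_id), tokens = sentences)
}
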