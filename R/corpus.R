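#' Build a training corpus from concept sentences
#'
#' The vocabulary is the deduplicated set of tokens, ordered lexicographically
#' (`sort(method = "radix")`, stable across platforms and locales); its length
#' is the one-hot dimension.
#'
#' @param sentences Either the tibble returned by [tokenize_records()]
#'   (`patient_id`, `tokens`) or a (optionally named) list of character
#'   vectors.
#' @return An `emr_corpus`: list with `sentences` (named list of character
#'   vectors), `vocabulary` (character), and `token_counts` (tibble of
#'   `token`, `count`, `index`).
#' @examples
#' build_corpus(list(p1 = c("a", "b"), p2 = c("b", "c")))
#' @export
build_corpus <- function(sentences) {
  if (is.data.frame(sentences)) {
    stopifnot(all(c("patient_id", "tokens") %in% names(sentences)))
    sents <- stats::setNames(sentences$tokens, sentences$patient_id)
  } else if (is.list(sentences)) {
    sents <- sentences
    if (length(sents) && is.null(names(sents))) {
      names(sents) <- paste0("s", seq_along(sents))
    }
  } else {
    abort_validation("`sentences` must be a tokenized tibble or a list of character vectors.")
  }
  sents <- purrr::map(sents, as.character)
  if (!length(sents) || all(lengths(sents) == 0L)) {
    abort_validation("Empty corpus: need at least one nonempty sentence.")
  }
  all_tokens <- unlist(sents, use.names = FALSE)
  counts <- table(all_tokens)
  vocab <- sort(names(counts), method = "radix")
  structure(
    list(
      sentences = sents,
      vocabulary = vocab,
      token_counts = tibble(
        token = vocab,
        count = as.integer(counts[vocab]),
        index = seq_along(vocab)
      )
    ),
    class = "emr_corpus"
  )
}

#' @export
print.emr_corpus <- function(x, ...) {
  cat(sprintf(
    "<emr_corpus> %d sentences, %d unique concepts, %d token occurrences\n",
    length(x$sentences), length(x$vocabulary), sum(x$token_counts$count)
  ))
  invisible(x)
}

#' @export
tidy.emr_corpus <- function(x, ...) x$token_counts

#' @export
glance.emr_corpus <- function(x, ...) {
  tibble(
    n_sentences = length(x$sentences),
    n_concepts = length(x$vocabulary),
    n_tokens = sum(x$token_counts$count),
    max_sentence_length = max(lengths(x$sentences))
  )
}

#' Shuffle token order within every sentence
#'
#' Each sentence is independently and uniformly permuted; the per-sentence
#' token multiset, the sentence order, and the vocabulary are untouched.
#' One master seed spawns a per-sentence seed stream, so the result is
#' deterministic given `seed`.
#'
#' @param corpus An `emr_corpus`.
#' @param seed Integer master seed.
#' @return A new `emr_corpus` with permuted sentences.
#' @export
shuffle_corpus <- function(corpus, seed) {
  stopifnot(inherits(corpus, "emr_corpus"))
  out <- corpus
  n <- length(corpus$sentences)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sentence_seeds <- sample.int(.Machine$integer.max, n)
  out$sentences <- purrr::map2(corpus$sentences, sentence_seeds, function(s, sd) {
    if (length(s) < 2L) return(s)
    set.seed(sd)
    s[sample.int(length(s))]
  })
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' One-hot and multi-hot encodings over a corpus vocabulary
#'
#' `one_hot()` sets the single bit at the token's vocabulary index.
#' `multi_hot()` is the bitwise OR of the one-hots of a record's tokens
#' (duplicates collapse), so its popcount equals the number of distinct
#' concepts. `multi_hot_matrix()` stacks one row per sentence.
#'
#' @param token A token known to the vocabulary.
#' @param corpus An `emr_corpus` (or a bare character vocabulary).
#' @return Integer 0/1 vector(s) named by vocabulary token.
#' @export
one_hot <- function(token, corpus) {
  vocab <- corpus_vocab(corpus)
  idx <- match(token, vocab)
  if (is.na(idx)) abort_validation(paste0("Unknown token: ", token))
  v <- integer(length(vocab))
  v[idx] <- 1L
  stats::setNames(v, vocab)
}

#' @rdname one_hot
#' @param tokens Character vector of a record's tokens.
#' @export
multi_hot <- function(tokens, corpus) {
  vocab <- corpus_vocab(corpus)
  idx <- match(tokens, vocab)
  if (anyNA(idx)) {
    abort_validation(paste0("Unknown token: ", tokens[which(is.na(idx))[1]]))
  }
  v <- integer(length(vocab))
  v[unique(idx)] <- 1L
  stats::setNames(v, vocab)
}

#' @rdname one_hot
#' @param sentences Tokenized tibble or named list of token vectors.
#' @export
multi_hot_matrix <- function(sentences, corpus) {
  if (is.data.frame(sentences)) {
    sents <- stats::setNames(sentences$tokens, sentences$patient_id)
  } else {
    sents <- sentences
  }
  vocab <- corpus_vocab(corpus)
  m <- matrix(0L, nrow = length(sents), ncol = length(vocab),
              dimnames = list(names(sents), vocab))
  for (i in seq_along(sents)) {
    idx <- match(sents[[i]], vocab)
    if (anyNA(idx)) {
      abort_validation(paste0("Unknown token: ", sents[[i]][which(is.na(idx))[1]]))
    }
    m[i, unique(idx)] <- 1L
  }
  m
}

corpus_vocab <- function(corpus) {
  if (inherits(corpus, "emr_corpus")) corpus$vocabulary else as.character(corpus)
}

#' Select the retained lab panel and its imputation medians
#'
#' Keeps the labs observed in at least `coverage_threshold` of cohort
#' records (the mixture representation drops the rest); the imputation value
#' per lab is the median of its observed values. Selection is monotone in the
#' threshold: raising it never adds a lab.
#'
#' @param records Records tibble.
#' @param schema An `emr_schema`.
#' @param coverage_threshold Minimum fraction of records with an observed
#'   value (default 0.90).
#' @return Tibble of `feature_id`, `coverage`, `median`.
#' @export
fit_lab_panel <- function(records, schema, coverage_threshold = 0.90) {
  schema <- schema_assert(schema)
  labs <- intersect(
    schema$feature_id[schema$value_kind == "lab_reference"],
    names(records)
  )
  panel <- purrr::map_dfr(labs, function(fid) {
    v <- as.numeric(records[[fid]])
    tibble(
      feature_id = fid,
      coverage = mean(!is.na(v)),
      median = stats::median(v, na.rm = TRUE)
    )
  })
  panel <- panel[panel$coverage >= coverage_threshold, ]
  if (!nrow(panel)) {
    abort_validation("Empty lab panel: no laboratory item reaches the coverage threshold.")
  }
  panel
}

#' Mixture representation: discrete multi-hot block plus continuous lab block
#'
#' The discrete block is the multi-hot over tokens of non-lab, non-age
#' features; the continuous block holds the raw age and panel lab values,
#' median-imputed where missing and (by default) z-scored so no single item
#' dominates the cosine distance. Labs outside the coverage panel are dropped
#' entirely, mirroring how sparse items cannot be carried as raw columns.
#'
#' @param records Records tibble.
#' @param schema An `emr_schema`.
#' @param panel Lab panel from [fit_lab_panel()].
#' @param edges Quartile edges for any `continuous_quartile` features.
#' @param include_age Keep age as a continuous column (default TRUE).
#' @param standardize z-score the continuous block (default TRUE; recorded in
#'   the result attributes).
#' @return An `emr_mixture`: list with `discrete` (n x V0 binary matrix),
#'   `continuous` (n x p numeric matrix), `panel`, `standardize`.
#' @export
mixture_representation <- function(records, schema, panel,
                                   edges = list(), include_age = TRUE,
                                   standardize = TRUE) {
  schema <- schema_assert(schema)
  lab_ids <- schema$feature_id[schema$value_kind == "lab_reference"]
  age_ids <- if (include_age) schema$feature_id[schema$value_kind == "age"] else character()
  discrete_schema <- schema[!schema$feature_id %in% c(lab_ids, age_ids) &
                              schema$category != "outcome", ]
  keep_cols <- c("patient_id", intersect(discrete_schema$feature_id, names(records)))
  sent <- tokenize_records(records[, keep_cols], discrete_schema, edges)
  dcorp <- build_corpus(sent)
  discrete <- multi_hot_matrix(sent, dcorp)

  cont_ids <- c(intersect(age_ids, names(records)), panel$feature_id)
  cont <- matrix(NA_real_, nrow(records), length(cont_ids),
                 dimnames = list(as.character(records$patient_id), cont_ids))
  for (fid in cont_ids) {
    v <- as.numeric(records[[fid]])
    med <- if (fid %in% panel$feature_id) {
      panel$median[match(fid, panel$feature_id)]
    } else {
      stats::median(v, na.rm = TRUE)
    }
    v[is.na(v)] <- med
    cont[, fid] <- v
  }
  if (standardize) {
    mu <- colMeans(cont)
    sdv <- apply(cont, 2, stats::sd)
    sdv[sdv == 0] <- 1
    cont <- sweep(sweep(cont, 2, mu), 2, sdv, "/")
  }
  structure(
    list(discrete = discrete, continuous = cont, panel = panel,
         standardize = standardize),
    class = "emr_mixture"
  )
}

#' @export
print.emr_mixture <- function(x, ...) {
  cat(sprintf(
    "<emr_mixture> %d records: %d discrete bits + %d continuous items (%s)\n",
    nrow(x$discrete), ncol(x$discrete), ncol(x$continuous),
    if (x$standardize) "z-scored" else "raw"
  ))
  invisible(x)
}

#' Corpus text serialization
#'
#' One sentence per line, whitespace-delimited tokens — loadable by any
#' embedding trainer. The vocabulary export is a TSV of token, count, index.
#'
#' @param corpus An `emr_corpus`.
#' @param path File path.
#' @export
write_corpus_text <- function(corpus, path) {
  writeLines(purrr::map_chr(corpus$sentences, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_corpus_text
#' @export
read_corpus_text <- function(path) {
  build_corpus(strsplit(readLines(path, warn = FALSE), "[[:space:]]+"))
}

#' @rdname write_corpus_text
#' @export
write_vocab_tsv <- function(corpus, path) {
  utils::write.table(corpus$token_counts, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
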