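#' Skip-gram training configuration
#'
#' Defaults follow the standard concept-embedding setup for admission
#' records: 200-dimensional vectors, a symmetric context window of 5,
#' negative sampling with 5 noise draws from the unigram^0.75 distribution,
#' 5 epochs with a linear learning-rate decay, and a 20-run shuffle ensemble.
#' `window = "max"` resolves to the longest sentence of the corpus in use,
#' so the context covers every other concept of the record.
#'
#' @param dim Embedding dimension `d` (default 200).
#' @param window Integer context half-width, or `"max"`.
#' @param epochs Passes over the corpus (default 5).
#' @param negatives Negative samples per positive pair (default 5).
#' @param lr Length-2 numeric `(start, end)` linear learning-rate schedule.
#' @param min_count Drop tokens rarer than this before training (default 1,
#'   i.e. keep everything: medical vocabularies are small).
#' @param seed Integer seed shared by weight initialization and the
#'   negative-sampling stream; shuffle seeds are derived from it.
#' @param n_shuffles Ensemble size for [ensemble_embed()] (default 20).
#' @return A `train_config` list.
#' @export
train_config <- function(dim = 200L, window = 5L, epochs = 5L, negatives = 5L,
                         lr = c(0.025, 1e-4), min_count = 1L, seed = 1L,
                         n_shuffles = 20L) {
  if (!identical(window, "max")) {
    window <- as.integer(window)
    if (is.na(window) || window < 1L) abort_validation("`window` must be >= 1 or \"max\".")
  }
  if (dim < 1L) abort_validation("`dim` must be >= 1.")
  if (n_shuffles < 1L) abort_validation("`n_shuffles` must be >= 1.")
  structure(
    list(dim = as.integer(dim), window = window, epochs = as.integer(epochs),
         negatives = as.integer(negatives), lr = as.numeric(lr),
         min_count = as.integer(min_count), seed = as.integer(seed),
         n_shuffles = as.integer(n_shuffles)),
    class = "train_config"
  )
}

resolve_window <- function(config, corpus) {
  if (identical(config$window, "max")) max(lengths(corpus$sentences)) else config$window
}

prepare_training <- function(corpus, config) {
  keep <- corpus$token_counts$token[corpus$token_counts$count >= config$min_count]
  vocab <- sort(keep, method = "radix")
  sents <- purrr::map(corpus$sentences, function(s) {
    idx <- match(s, vocab)
    as.integer(idx[!is.na(idx)] - 1L)
  })
  if (all(lengths(sents) < 2L)) {
    abort_validation("No training pairs: every sentence has fewer than 2 retained tokens.")
  }
  counts <- corpus$token_counts$count[match(vocab, corpus$token_counts$token)]
  list(vocab = vocab, sents = sents, counts = as.numeric(counts))
}

init_matrix <- function(n_vocab, dim, seed) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  matrix(stats::runif(n_vocab * dim, -0.5, 0.5) / dim, nrow = n_vocab, ncol = dim)
}

new_embedding <- function(vectors, vocab, loss, pairs, provenance) {
  dimnames(vectors) <- list(vocab, NULL)
  structure(
    list(vocabulary = vocab, vectors = vectors, epoch_loss = loss,
         epoch_pairs = pairs, provenance = provenance),
    class = "emr_embedding"
  )
}

#' Train skip-gram concept embeddings on one corpus
#'
#' Stochastic-gradient optimization of the skip-gram objective with negative
#' sampling: for every position the context is up to `window` neighbors on
#' each side within the sentence (fixed window, no random shrinking), each
#' observed pair is contrasted against `negatives` unigram^0.75 noise draws.
#' Single-threaded and bit-deterministic given the seed.
#'
#' @param corpus An `emr_corpus` (already shuffled, if desired).
#' @param config A [train_config()].
#' @param init Optional initialization matrix (used by [ensemble_embed()] to
#'   share one initialization across runs); defaults to uniform
#'   `(-0.5, 0.5)/dim` drawn from `config$seed`.
#' @return An `emr_embedding`: vocabulary, the input-side `|vocab| x dim`
#'   matrix, per-epoch mean loss (`epoch_loss`), per-epoch training-pair
#'   counts (`epoch_pairs`) and a provenance record.
#' @export
train_skipgram <- function(corpus, config = train_config(), init = NULL) {
  stopifnot(inherits(corpus, "emr_corpus"))
  prep <- prepare_training(corpus, config)
  window <- resolve_window(config, corpus)
  if (is.null(init)) init <- init_matrix(length(prep$vocab), config$dim, config$seed)
  stopifnot(nrow(init) == length(prep$vocab), ncol(init) == config$dim)
  fit <- sgns_train_cpp(prep$sents, init, prep$counts, window,
                        config$epochs, config$negatives,
                        config$lr[1], config$lr[2], as.double(config$seed))
  new_embedding(
    fit$vectors, prep$vocab, as.numeric(fit$epoch_loss), as.numeric(fit$epoch_pairs),
    list(config = config, window_resolved = window, ensemble = 1L)
  )
}

#' Shuffle-ensemble embedding: average over repeatedly shuffled corpora
#'
#' Record "sentences" have no natural word order, so a fixed window can miss
#' associated concepts that happen to sit far apart. The ensemble reshuffles
#' every sentence, retrains, and averages the resulting vectors elementwise
#' over `n_shuffles` runs. All runs share one weight initialization (and
#' noise seed); only the token order differs, which keeps the runs in a
#' common coordinate system so their mean is well-posed.
#'
#' @inheritParams train_skipgram
#' @return An `emr_embedding` whose vectors are the elementwise mean across
#'   runs.
#' @export
ensemble_embed <- function(corpus, config = train_config()) {
  stopifnot(inherits(corpus, "emr_corpus"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(config$seed)
  shuffle_seeds <- sample.int(.Machine$integer.max, config$n_shuffles)
  restore_rng(old)

  prep <- prepare_training(corpus, config)
  init <- init_matrix(length(prep$vocab), config$dim, config$seed)
  acc <- NULL
  losses <- vector("list", config$n_shuffles)
  for (r in seq_len(config$n_shuffles)) {
    shuffled <- shuffle_corpus(corpus, shuffle_seeds[r])
    run <- train_skipgram(shuffled, config, init = init)
    stopifnot(identical(run$vocabulary, prep$vocab))
    acc <- if (is.null(acc)) run$vectors else acc + run$vectors
    losses[[r]] <- run$epoch_loss
  }
  new_embedding(
    acc / config$n_shuffles, prep$vocab,
    loss = colMeans(do.call(rbind, losses)),
    pairs = run$epoch_pairs,
    provenance = list(config = config, window_resolved = run$provenance$window_resolved,
                      ensemble = config$n_shuffles, shuffle_seeds = shuffle_seeds)
  )
}

#' @export
print.emr_embedding <- function(x, ...) {
  cat(sprintf(
    "<emr_embedding> %d concepts x %d dims (ensemble of %d run%s)\n",
    nrow(x$vectors), ncol(x$vectors), x$provenance$ensemble,
    if (x$provenance$ensemble == 1) "" else "s"
  ))
  invisible(x)
}

#' @export
tidy.emr_embedding <- function(x, ...) {
  out <- as_tibble(x$vectors, .name_repair = ~ paste0("d", seq_along(.x)))
  dplyr::bind_cols(tibble(token = x$vocabulary), out)
}

#' @export
glance.emr_embedding <- function(x, ...) {
  tibble(
    n_concepts = nrow(x$vectors), dim = ncol(x$vectors),
    ensemble = x$provenance$ensemble,
    window = x$provenance$window_resolved,
    final_loss = utils::tail(x$epoch_loss, 1)
  )
}

#' Average concept vectors into patient vectors
#'
#' A patient with `k` concepts has `k` embedding vectors; their arithmetic
#' mean is the patient representation (order-invariant by construction).
#' Tokens absent from the embedding vocabulary are skipped with a warning;
#' a record with no known token is an error.
#'
#' @param sentences Tokenized tibble from [tokenize_records()] (or named list
#'   of token vectors).
#' @param embedding An `emr_embedding`.
#' @return Numeric matrix, one row per patient (rownames = patient ids).
#' @export
embed_patients <- function(sentences, embedding) {
  stopifnot(inherits(embedding, "emr_embedding"))
  if (is.data.frame(sentences)) {
    sents <- stats::setNames(sentences$tokens, sentences$patient_id)
  } else {
    sents <- sentences
  }
  vocab <- embedding$vocabulary
  vec <- embedding$vectors
  out <- matrix(NA_real_, length(sents), ncol(vec),
                dimnames = list(names(sents), NULL))
  n_skipped <- 0L
  for (i in seq_along(sents)) {
    idx <- match(sents[[i]], vocab)
    miss <- is.na(idx)
    n_skipped <- n_skipped + sum(miss)
    idx <- idx[!miss]
    if (!length(idx)) {
      abort_validation(paste0(
        "Record '", names(sents)[i], "' has no token in the embedding vocabulary."
      ))
    }
    out[i, ] <- colMeans(vec[idx, , drop = FALSE])
  }
  if (n_skipped > 0L) {
    warn(sprintf("embed_patients: skipped %d token occurrence(s) absent from the vocabulary.", n_skipped))
  }
  out
}

#' @rdname embed_patients
#' @param tokens Character vector, one record's tokens.
#' @export
embed_patient <- function(tokens, embedding) {
  drop(embed_patients(list(patient = tokens), embedding))
}

#' Plain-text embedding interchange format
#'
#' Header line `"<vocab_size> <dim>"`, then one line per token:
#' `"<token> <v1> ... <vd>"`.
#'
#' @param embedding An `emr_embedding`.
#' @param path File path.
#' @export
write_embedding_text <- function(embedding, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(nrow(embedding$vectors), ncol(embedding$vectors)), con)
  lines <- vapply(seq_len(nrow(embedding$vectors)), function(i) {
    paste(embedding$vocabulary[i],
          paste(format(embedding$vectors[i, ], digits = 17, scientific = TRUE, trim = TRUE),
                collapse = " "))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_embedding_text
#' @export
read_embedding_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  new_embedding(vec, vocab, loss = NA_real_, pairs = NA_real_,
                provenance = list(config = NULL, ensemble = NA_integer_,
                                  window_resolved = NA_integer_, source = path))
}
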