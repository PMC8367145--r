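#' Cosine similarity between two vectors
#'
#' @param u,w Numeric vectors of equal length, both nonzero.
#' @return `u . w / (|u| |w|)`, in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(u, w) {
  if (length(u) != length(w)) abort_validation("Vectors must have equal length.")
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) abort_validation("Cosine similarity is undefined for a zero vector.")
  sum(u * w) / (nu * nw)
}

row_normalize <- function(x) {
  n <- sqrt(rowSums(x^2))
  if (any(n == 0)) abort_validation("Zero row vector: cosine geometry undefined.")
  x / n
}

#' Closest concepts to a query token
#'
#' Ranks all other vocabulary tokens by cosine similarity to the query
#' (ties broken lexicographically by token), optionally restricted to one
#' feature category via a user-supplied token -> category map; tokens missing
#' from the map are labeled `"other"`.
#'
#' @param query A vocabulary token.
#' @param embedding An `emr_embedding`.
#' @param k Neighbors to keep per query (default 10).
#' @param category_map Optional tibble/data frame with `token` and `category`.
#' @param category_filter Optional single category to restrict neighbors to.
#' @return A tibble of `token`, `similarity`, `category`, sorted by
#'   non-increasing similarity; the mean of the `similarity` column is the
#'   usual summary of a neighbor set.
#' @export
top_k_neighbors <- function(query, embedding, k = 10L,
                            category_map = NULL, category_filter = NULL) {
  stopifnot(inherits(embedding, "emr_embedding"))
  qi <- match(query, embedding$vocabulary)
  if (is.na(qi)) abort_validation(paste0("Unknown query token: ", query))
  x <- row_normalize(embedding$vectors)
  sims <- unname(drop(x %*% x[qi, ]))
  res <- tibble(token = embedding$vocabulary, similarity = sims)
  res <- res[-qi, ]
  res$category <- token_categories(res$token, category_map)
  if (!is.null(category_filter)) res <- res[res$category == category_filter, ]
  res <- res[order(-res$similarity, res$token, method = "radix"), ]
  utils::head(res, k)
}

#' @rdname top_k_neighbors
#' @param queries Character vector of query tokens.
#' @return `neighbor_report()` binds per-query, per-category top-k tables
#'   (one block of up to `k` neighbors for every category present).
#' @export
neighbor_report <- function(queries, embedding, k = 10L, category_map = NULL) {
  purrr::map_dfr(queries, function(q) {
    all_nb <- top_k_neighbors(q, embedding, k = nrow(embedding$vectors),
                              category_map = category_map)
    all_nb %>%
      group_by(.data$category) %>%
      slice_head(n = k) %>%
      ungroup() %>%
      mutate(query = q, .before = 1)
  })
}

token_categories <- function(tokens, category_map = NULL) {
  if (is.null(category_map)) return(rep("other", length(tokens)))
  cat <- category_map$category[match(tokens, category_map$token)]
  cat[is.na(cat)] <- "other"
  cat
}

#' Map schema categories onto corpus tokens
#'
#' Convenience builder of a token -> category map from the feature schema
#' (the category of a token is the category of its feature).
#'
#' @param corpus An `emr_corpus`.
#' @param schema An `emr_schema`.
#' @return Tibble of `token`, `category`.
#' @export
schema_category_map <- function(corpus, schema) {
  schema <- schema_assert(schema)
  parsed <- parse_concept(corpus$vocabulary)
  cat <- schema$category[match(parsed$feature_id, schema$feature_id)]
  cat[is.na(cat)] <- "other"
  tibble(token = corpus$vocabulary, category = cat)
}

#' Export embedding vectors for an external 2-D projection backend
#'
#' Emits the tokens passing a minimum occurrence-count filter together with
#' their vectors and category labels, as input for a stochastic-neighbor
#' projection run externally (conventional settings: perplexity 30, learning
#' rate 200, 1000 iterations). The projection algorithm itself is out of
#' scope here.
#'
#' @param embedding An `emr_embedding`.
#' @param corpus The `emr_corpus` supplying occurrence counts.
#' @param min_count Keep tokens occurring in at least this many records.
#' @param category_map Optional token -> category map; unmapped tokens are
#'   labeled `"other"`.
#' @param path Optional TSV output path (token, category, d1..dd).
#' @return The exported tibble (invisibly if `path` is given).
#' @export
export_projection_input <- function(embedding, corpus, min_count = 10L,
                                    category_map = NULL, path = NULL) {
  counts <- corpus$token_counts
  keep <- counts$token[counts$count >= min_count]
  keep <- intersect(embedding$vocabulary, keep)
  if (!length(keep)) abort_validation("Empty projection subset after min-count filtering.")
  idx <- match(keep, embedding$vocabulary)
  vec <- embedding$vectors[idx, , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble(token = keep, category = token_categories(keep, category_map)),
    as_tibble(vec, .name_repair = ~ paste0("d", seq_along(.x)))
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
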