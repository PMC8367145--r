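SCHEMES <- c("embedding_shuffled", "embedding_unshuffled", "embedding_maxwindow",
             "multi_hot", "mixture")

#' Run the full representation-and-evaluation pipeline for one scheme
#'
#' Tokenize -> corpus -> (train embeddings | baseline encode) -> cluster ->
#' evaluate. The representation schemes are:
#' * `embedding_shuffled` — 20-run shuffle-ensemble skip-gram, window 5
#'   (cosine distance);
#' * `embedding_unshuffled` — single run on the record order as given,
#'   window 5 (cosine);
#' * `embedding_maxwindow` — single unshuffled run with the window set to
#'   the longest record (cosine);
#' * `multi_hot` — binary bag of concepts (Jaccard distance);
#' * `mixture` — multi-hot discrete block plus continuous age/lab block
#'   (Jaccard + cosine mixed distance).
#'
#' Embeddings may be trained on a larger corpus than the cohort being
#' clustered (`train_records`), mirroring training on all admissions while
#' evaluating a disease subset.
#'
#' @param records Records tibble for the cohort to cluster.
#' @param schema The `emr_schema`.
#' @param scheme One of `r paste0('"', SCHEMES, '"', collapse = ", ")`.
#' @param config A [train_config()] (embedding schemes).
#' @param train_records Optional larger training cohort (embedding schemes);
#'   defaults to `records`. Quartile edges are fitted on it.
#' @param k_range Candidate cluster counts (default `2:15`).
#' @param true_labels Optional tibble `patient_id`, `label` for external
#'   scoring.
#' @param coverage_threshold Lab-panel coverage for the mixture scheme.
#' @param weights Mixed-distance weights.
#' @param seed Clustering / Hopkins seed.
#' @param output_dir Optional directory; when given, artifacts (corpus,
#'   embedding, patient matrix, assignments, report JSON) and a provenance
#'   manifest are written there.
#' @return An `emr_pipeline_result`: list with `scheme`, `distance`,
#'   `representation`, `embedding` (or NULL), `selection`
#'   (a `select_k_result`), `solution`, and `report` (a `validity_report`).
#' @export
run_pipeline <- function(records, schema, scheme = "embedding_shuffled",
                         config = train_config(), train_records = NULL,
                         k_range = 2:15, true_labels = NULL,
                         coverage_threshold = 0.90, weights = c(1, 1),
                         seed = 1L, output_dir = NULL) {
  scheme <- match.arg(scheme, SCHEMES)
  schema <- schema_assert(schema)
  if (is.null(train_records)) train_records <- records
  edges <- fit_bin_edges(train_records, schema)
  sentences <- tokenize_records(records, schema, edges)

  embedding <- NULL
  if (scheme %in% c("embedding_shuffled", "embedding_unshuffled", "embedding_maxwindow")) {
    train_sentences <- if (identical(train_records, records)) sentences else {
      tokenize_records(train_records, schema, edges)
    }
    corpus <- build_corpus(train_sentences)
    embedding <- switch(scheme,
      embedding_shuffled = ensemble_embed(corpus, config),
      embedding_unshuffled = train_skipgram(corpus, config),
      embedding_maxwindow = {
        cfg <- config; cfg$window <- "max"
        train_skipgram(corpus, cfg)
      }
    )
    representation <- embed_patients(sentences, embedding)
    distance <- "cosine"
  } else if (scheme == "multi_hot") {
    corpus <- build_corpus(sentences)
    representation <- multi_hot_matrix(sentences, corpus)
    distance <- "jaccard"
  } else {
    corpus <- build_corpus(sentences)
    panel <- fit_lab_panel(records, schema, coverage_threshold)
    representation <- mixture_representation(records, schema, panel, edges)
    distance <- "mixed"
  }

  selection <- select_k(representation, distance, k_range = k_range,
                        seed = seed, weights = weights)
  solution <- selection$solution
  D <- pairwise_distances(representation, distance, weights = weights)
  report <- validity_report(representation, solution, true_labels = true_labels,
                            D = D, seed = seed, weights = weights)

  result <- structure(
    list(scheme = scheme, distance = distance, corpus = corpus,
         embedding = embedding, representation = representation,
         selection = selection, solution = solution, report = report,
         config = config, seed = seed),
    class = "emr_pipeline_result"
  )
  if (!is.null(output_dir)) write_pipeline_artifacts(result, sentences, output_dir)
  result
}

#' @export
print.emr_pipeline_result <- function(x, ...) {
  cat(sprintf("<emr_pipeline_result> scheme %s (%s distance), k* = %d\n",
              x$scheme, x$distance, x$selection$k_star))
  print(x$report)
  invisible(x)
}

#' @export
glance.emr_pipeline_result <- function(x, ...) {
  out <- tibble(scheme = x$scheme, distance = x$distance,
                k_star = x$selection$k_star)
  dplyr::bind_cols(out, glance(x$report))
}

write_pipeline_artifacts <- function(result, sentences, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus_text(result$corpus, file.path(output_dir, "corpus.txt"))
  write_vocab_tsv(result$corpus, file.path(output_dir, "vocabulary.tsv"))
  if (!is.null(result$embedding)) {
    write_embedding_text(result$embedding, file.path(output_dir, "embedding.txt"))
  }
  if (is.matrix(result$representation)) {
    utils::write.csv(result$representation,
                     file.path(output_dir, "patient_matrix.csv"))
  }
  utils::write.csv(result$solution$assignments,
                   file.path(output_dir, "assignments.csv"), row.names = FALSE)
  rep_json <- list(
    scheme = result$scheme, distance = result$distance,
    k_star = result$selection$k_star,
    hopkins = result$report$hopkins, silhouette = result$report$silhouette,
    dbi = result$report$dbi,
    per_class = if (!is.null(result$report$per_class)) {
      as.data.frame(result$report$per_class)
    },
    silhouette_sweep = as.data.frame(result$selection$sweep)
  )
  jsonlite::write_json(rep_json, file.path(output_dir, "validity_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    scheme = result$scheme,
    seed = result$seed,
    config = unclass(result$config),
    config_hash = rlang::hash(result$config),
    n_patients = nrow(result$solution$assignments),
    package_version = as.character(utils::packageVersion("emr2vec")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Compare representation schemes on one cohort
#'
#' Runs [run_pipeline()] for each requested scheme and stacks one summary
#' row per scheme (Hopkins, selected k, silhouette, DBI, and per-class F1
#' when labels are given). Supplying `full_records` additionally runs the
#' three embedding schemes with embeddings trained on that larger corpus,
#' giving the familiar eight-row comparison (3 embedding schemes x 2
#' training corpora + 2 baselines).
#'
#' @inheritParams run_pipeline
#' @param schemes Character vector of schemes (default all five).
#' @param full_records Optional larger training cohort for extra embedding
#'   rows.
#' @return A tibble, one row per (scheme, training corpus).
#' @export
compare_schemes <- function(records, schema, schemes = SCHEMES,
                            config = train_config(), full_records = NULL,
                            k_range = 2:15, true_labels = NULL,
                            coverage_threshold = 0.90, weights = c(1, 1),
                            seed = 1L) {
  grid <- tibble(scheme = schemes, corpus = "cohort")
  if (!is.null(full_records)) {
    extra <- intersect(schemes, c("embedding_shuffled", "embedding_unshuffled",
                                  "embedding_maxwindow"))
    grid <- bind_rows(grid, tibble(scheme = extra, corpus = "full"))
  }
  purrr::pmap_dfr(grid, function(scheme, corpus) {
    res <- run_pipeline(
      records, schema, scheme, config = config,
      train_records = if (corpus == "full") full_records else NULL,
      k_range = k_range, true_labels = true_labels,
      coverage_threshold = coverage_threshold, weights = weights, seed = seed
    )
    row <- glance(res) %>% mutate(corpus = corpus, .after = "scheme")
    if (!is.null(res$report$per_class)) {
      pc <- res$report$per_class
      wide <- tibble(
        f1_majority = pc$f1[which.max(pc$support)],
        f1_minority = pc$f1[which.min(pc$support)]
      )
      row <- dplyr::bind_cols(row, wide)
    }
    row
  })
}
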