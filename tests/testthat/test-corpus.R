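test_that("build_corpus: vocabulary, counts, errors", {
  corp <- build_corpus(list(s1 = c("A", "B"), s2 = c("B", "C")))
  expect_equal(corp$vocabulary, c("A", "B", "C"))
  expect_equal(corp$token_counts$count[corp$token_counts$token == "B"], 2L)
  expect_equal(build_corpus(list(c("A")))$vocabulary, "A")
  expect_error(build_corpus(list()), class = "emr2vec_validation")
  expect_error(build_corpus(list(character())), class = "emr2vec_validation")
})

test_that("corpus vocabulary matches the generator's concept ledger", {
  coh <- small_cohort()
  sent <- tokenize_records(coh$records, coh$schema,
                           fit_bin_edges(coh$records, coh$schema))
  corp <- build_corpus(sent)
  # every emitted code token is in the ledger; no outcome tokens anywhere
  code_tokens <- corp$vocabulary[grepl("^(dx|px|rx)", corp$vocabulary)]
  expect_true(all(code_tokens %in% coh$concept_ledger$token))
  cats <- schema_category_map(corp, coh$schema)
  expect_false(any(cats$category == "outcome"))
})

test_that("shuffling conserves multisets, order of sentences, and is seeded", {
  corp <- build_corpus(list(a = LETTERS[1:8], b = letters[1:10], c = "H"))
  s1 <- shuffle_corpus(corp, seed = 7)
  s2 <- shuffle_corpus(corp, seed = 7)
  expect_identical(s1$sentences, s2$sentences)
  expect_identical(names(s1$sentences), names(corp$sentences))
  for (nm in names(corp$sentences)) {
    expect_equal(sort(s1$sentences[[nm]]), sort(corp$sentences[[nm]]))
  }
  expect_identical(s1$token_counts, corp$token_counts)
  # different seeds give distinct corpus copies (20 of 20 distinct here)
  copies <- lapply(1:20, function(sd) shuffle_corpus(corp, sd)$sentences)
  expect_equal(length(unique(copies)), 20L)
})

test_that("shuffling conserves corpus-level counts on a generated cohort", {
  coh <- small_cohort()
  sent <- tokenize_records(coh$records, coh$schema,
                           fit_bin_edges(coh$records, coh$schema))
  corp <- build_corpus(sent)
  sh <- shuffle_corpus(corp, seed = 3)
  expect_identical(build_corpus(sh$sentences)$token_counts, corp$token_counts)
})

test_that("one-hot: single bit at the vocabulary index, completeness", {
  corp <- build_corpus(list(c("A", "B", "C")))
  expect_equal(unname(one_hot("A", corp)), c(1L, 0L, 0L))
  for (tok in corp$vocabulary) expect_equal(sum(one_hot(tok, corp)), 1L)
  total <- Reduce(`+`, lapply(corp$vocabulary, one_hot, corp = corp))
  expect_equal(unname(total), rep(1L, 3))
  expect_error(one_hot("Z", corp), class = "emr2vec_validation")
})

test_that("multi-hot: OR semantics, order invariance, popcount", {
  corp <- build_corpus(list(c("A", "B", "C", "D")))
  v <- multi_hot(c("A", "C", "B"), corp)
  expect_equal(sum(v), 3L)
  expect_equal(multi_hot(c("A", "A", "B"), corp), multi_hot(c("B", "A"), corp))
  # disjoint records have Jaccard distance 1
  expect_equal(jaccard_distance(multi_hot("A", corp), multi_hot(c("B", "C"), corp)), 1)
  expect_error(multi_hot("Z", corp), class = "emr2vec_validation")

  m <- multi_hot_matrix(list(r1 = c("A", "B"), r2 = c("C", "C")), corp)
  expect_equal(rowSums(m), c(r1 = 2, r2 = 1))
})

test_that("multi-hot popcount equals distinct-concept count per record", {
  coh <- small_cohort()
  sent <- tokenize_records(coh$records, coh$schema,
                           fit_bin_edges(coh$records, coh$schema))
  corp <- build_corpus(sent)
  m <- multi_hot_matrix(sent, corp)
  expect_equal(unname(rowSums(m)),
               vapply(sent$tokens, function(t) length(unique(t)), numeric(1)))
  # shuffled sentences map to identical multi-hot vectors
  sh <- shuffle_corpus(corp, seed = 5)
  m2 <- multi_hot_matrix(stats::setNames(sh$sentences, rownames(m)), corp)
  expect_equal(m, m2)
})

test_that("lab panel selection honors and is monotone in the threshold", {
  coh <- small_cohort()
  p90 <- fit_lab_panel(coh$records, coh$schema, 0.90)
  expect_true(all(p90$coverage >= 0.90))
  p92 <- fit_lab_panel(coh$records, coh$schema, 0.92)
  expect_true(all(p92$feature_id %in% p90$feature_id))
  expect_lte(nrow(p92), nrow(p90))
  expect_error(fit_lab_panel(coh$records, coh$schema, 0.9999),
               class = "emr2vec_validation")
})

test_that("mixture representation: imputation, z-scoring, block contents", {
  coh <- small_cohort()
  rec <- coh$records
  panel <- fit_lab_panel(rec, coh$schema, 0.90)
  edges <- fit_bin_edges(rec, coh$schema)
  mx <- mixture_representation(rec, coh$schema, panel, edges, standardize = FALSE)
  lab1 <- panel$feature_id[1]
  miss <- which(is.na(rec[[lab1]]))
  expect_gt(length(miss), 0)
  expect_equal(unname(mx$continuous[miss, lab1]),
               rep(panel$median[panel$feature_id == lab1], length(miss)))
  obs <- which(!is.na(rec[[lab1]]))
  expect_equal(unname(mx$continuous[obs, lab1]), rec[[lab1]][obs])
  expect_false(anyNA(mx$continuous))
  # no lab or age tokens in the discrete block
  expect_false(any(grepl("^lab|^age=", colnames(mx$discrete))))
  # z-scored variant has mean ~0 / sd ~1 columns
  mz <- mixture_representation(rec, coh$schema, panel, edges, standardize = TRUE)
  expect_lt(max(abs(colMeans(mz$continuous))), 1e-10)
  expect_equal(unname(apply(mz$continuous, 2, sd)), rep(1, ncol(mz$continuous)))
})

test_that("corpus text and vocabulary TSV round-trip", {
  corp <- build_corpus(list(c("A", "B"), c("C")))
  cp <- withr::local_tempfile(fileext = ".txt")
  write_corpus_text(corp, cp)
  back <- read_corpus_text(cp)
  expect_equal(unname(back$sentences), unname(corp$sentences))
  expect_equal(back$token_counts, corp$token_counts)
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_vocab_tsv(corp, vp)
  tsv <- read.delim(vp)
  expect_equal(tsv$token, corp$vocabulary)
})
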