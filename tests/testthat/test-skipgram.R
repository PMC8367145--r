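test_that("co-occurrence structure orders cosine similarities", {
  tb <- toy_block_corpus(seed = 4)
  emb <- train_skipgram(tb$corpus, train_config(dim = 16, epochs = 10, seed = 3))
  v <- emb$vectors
  cs <- function(a, b) cosine_similarity(v[a, ], v[b, ])
  # within-block pairs beat across-block pairs
  expect_gt(cs("a1", "a2"), cs("a1", "b1"))
  expect_gt(cs("b1", "b2"), cs("b1", "a2"))
  within <- mean(c(cs("a1", "a3"), cs("a2", "a4"), cs("b1", "b3"), cs("b2", "b4")))
  between <- mean(c(cs("a1", "b3"), cs("a2", "b2"), cs("a3", "b4")))
  expect_gt(within, between)
})

test_that("configured dimension and per-epoch loss decrease", {
  tb <- toy_block_corpus(seed = 4)
  emb <- train_skipgram(tb$corpus, train_config(dim = 37, epochs = 8, seed = 1))
  expect_equal(ncol(emb$vectors), 37L)
  expect_equal(nrow(emb$vectors), 10L)
  expect_true(all(is.finite(emb$vectors)))
  expect_lt(tail(emb$epoch_loss, 1), emb$epoch_loss[1])
})

test_that("training is bit-deterministic given the seed", {
  tb <- toy_block_corpus(seed = 4)
  cfg <- train_config(dim = 12, epochs = 3, seed = 99)
  e1 <- train_skipgram(tb$corpus, cfg)
  e2 <- train_skipgram(tb$corpus, cfg)
  expect_identical(e1$vectors, e2$vectors)
  expect_identical(e1$epoch_loss, e2$epoch_loss)
  en1 <- ensemble_embed(tb$corpus, train_config(dim = 12, epochs = 2, seed = 5, n_shuffles = 3))
  en2 <- ensemble_embed(tb$corpus, train_config(dim = 12, epochs = 2, seed = 5, n_shuffles = 3))
  expect_identical(en1$vectors, en2$vectors)
})

test_that("window = 'max' trains on exactly all ordered within-sentence pairs", {
  corp <- build_corpus(list(c("A", "B", "C", "D", "E", "F", "G"),
                            c("H", "I"), c("J", "K", "L")))
  emb <- train_skipgram(corp, train_config(dim = 4, window = "max", epochs = 2, seed = 1))
  brute_pairs <- sum(sapply(lengths(corp$sentences), function(L) L * (L - 1)))
  expect_equal(unname(emb$epoch_pairs), rep(brute_pairs, 2))
  # window 1 sees only adjacent pairs: 2*(L-1) per sentence
  emb1 <- train_skipgram(corp, train_config(dim = 4, window = 1, epochs = 1, seed = 1))
  expect_equal(unname(emb1$epoch_pairs),
               sum(sapply(lengths(corp$sentences), function(L) 2 * (L - 1))))
})

test_that("min_count drops rare tokens; all-short corpora are rejected", {
  corp <- build_corpus(list(c("A", "B"), c("A", "B"), c("A", "C")))
  emb <- train_skipgram(corp, train_config(dim = 4, epochs = 1, seed = 1, min_count = 2))
  expect_equal(rownames(emb$vectors), c("A", "B"))
  expect_error(
    train_skipgram(build_corpus(list("A", "B")), train_config(dim = 4, epochs = 1)),
    class = "emr2vec_validation"
  )
})

test_that("ensemble with n_shuffles = 1 equals a single run on the shuffled corpus", {
  tb <- toy_block_corpus(n_per_block = 100, seed = 2)
  cfg <- train_config(dim = 8, epochs = 2, seed = 17, n_shuffles = 1)
  ens <- ensemble_embed(tb$corpus, cfg)
  set.seed(cfg$seed)
  derived <- sample.int(.Machine$integer.max, 1)
  single <- train_skipgram(shuffle_corpus(tb$corpus, derived), cfg)
  expect_identical(ens$vectors, single$vectors)
})

test_that("ensemble averaging stabilizes within-block similarity", {
  tb <- toy_block_corpus(n_per_block = 150, seed = 6)
  sim_ab <- function(emb) cosine_similarity(emb$vectors["a1", ], emb$vectors["a2", ])
  single <- sapply(1:8, function(s) {
    sim_ab(train_skipgram(shuffle_corpus(tb$corpus, 1000 + s),
                          train_config(dim = 8, epochs = 2, seed = s)))
  })
  ens <- sapply(1:8, function(s) {
    sim_ab(ensemble_embed(tb$corpus, train_config(dim = 8, epochs = 2, seed = s,
                                                  n_shuffles = 5)))
  })
  expect_lte(var(ens), var(single))
})

test_that("patient vectors are token means: identity, average, order-invariance", {
  vocab <- c("t1", "t2", "t3")
  vec <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE,
                dimnames = list(vocab, NULL))
  emb <- structure(list(vocabulary = vocab, vectors = vec,
                        provenance = list(ensemble = 1L)),
                   class = "emr_embedding")
  expect_equal(embed_patient("t1", emb), c(1, 0, 0))
  expect_equal(embed_patient(c("t1", "t2"), emb), c(0.5, 0.5, 0))
  expect_equal(embed_patient(c("t2", "t1"), emb), embed_patient(c("t1", "t2"), emb))
  expect_warning(got <- embed_patient(c("t1", "zzz"), emb), "skipped")
  expect_equal(got, c(1, 0, 0))
  expect_error(suppressWarnings(embed_patient("zzz", emb)),
               class = "emr2vec_validation")
  m <- embed_patients(list(pA = c("t1", "t3"), pB = "t2"), emb)
  expect_equal(rownames(m), c("pA", "pB"))
  expect_equal(unname(m[1, ]), c(0.5, 0, 0.5))
})

test_that("embedding text format round-trips", {
  tb <- toy_block_corpus(n_per_block = 50, seed = 3)
  emb <- train_skipgram(tb$corpus, train_config(dim = 6, epochs = 1, seed = 1))
  p <- withr::local_tempfile(fileext = ".vec")
  write_embedding_text(emb, p)
  hdr <- strsplit(readLines(p, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(10L, 6L))
  back <- read_embedding_text(p)
  expect_equal(back$vocabulary, emb$vocabulary)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-12)
})

test_that("trainer agrees with an independent full-softmax factorization", {
  corp <- toy_chain_corpus(seed = 9)
  emb <- train_skipgram(corp, train_config(dim = 16, epochs = 15, seed = 2))
  ref <- reference_softmax_skipgram(corp, window = 5, dim = 16,
                                    iters = 400, lr = 0.5, seed = 11)
  ref <- ref[emb$vocabulary, ]
  rho <- cor(pairwise_cosine_vec(emb$vectors), pairwise_cosine_vec(ref),
             method = "spearman")
  expect_gte(rho, 0.8)
})
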