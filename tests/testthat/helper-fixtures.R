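# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

toy_schema <- function() {
  feature_schema(
    feature_spec("sex", "demographics", "categorical"),
    feature_spec("age", "demographics", "age"),
    feature_spec("los_pre", "resources", "continuous_quartile"),
    feature_spec("glucose", "lab", "lab_reference",
                 reference_range = c(3.9, 6.1), n_lab_classes = 3L),
    feature_spec("wbc", "lab", "lab_reference",
                 reference_range = c(4, 10), n_lab_classes = 2L),
    feature_spec("dx_a", "diagnosis", "categorical"),
    feature_spec("cost", "outcome", "continuous_quartile"),
    feature_spec("death", "outcome", "categorical")
  )
}

toy_records <- function() {
  tibble::tibble(
    patient_id = paste0("p", 1:8),
    sex = c("male", "female", "male", "male", "female", "male", "female", "male"),
    age = c(64, 17, 18, 35, 44.5, 59, 60, 30),
    los_pre = 1:8,
    glucose = c(7.8, 5.0, 3.9, NA, 2.1, 6.2, 5.5, 6.1),
    wbc = c(5, 11, NA, 3.2, 7, 10, 4, 12),
    dx_a = c("I60.9", NA, "I63.0", "I63.0", NA, "I60.9", NA, "I63.0"),
    cost = runif(8, 1, 100),
    death = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# two-block token corpus where within-block tokens share contexts
toy_block_corpus <- function(n_per_block = 500, seed = 1) {
  set.seed(seed)
  blkA <- paste0("a", 1:5)
  blkB <- paste0("b", 1:5)
  mk <- function(blk) replicate(n_per_block, sample(blk, 4), simplify = FALSE)
  list(corpus = build_corpus(c(mk(blkA), mk(blkB))), blocks = list(A = blkA, B = blkB))
}

# chain-structured corpus: co-occurrence strength decays with |i - j|,
# giving graded pairwise similarities whose ranking both estimators resolve
toy_chain_corpus <- function(seed = 1, V = 12, n = 1500) {
  set.seed(seed)
  toks <- sprintf("t%02d", seq_len(V))
  sents <- lapply(seq_len(n), function(i) {
    c0 <- sample.int(V, 1)
    idx <- unique(pmin(pmax(c0 + sample(-2:2, 4, replace = TRUE), 1), V))
    toks[idx]
  })
  build_corpus(sents)
}

small_cohort <- function() {
  fixture("small_cohort", function() generate_cohort(cohort_spec(n_patients = 400, seed = 101)))
}

cohort_labels <- function(cohort) {
  dplyr::rename(cohort$truth, label = class)
}

random_mixture <- function(n, p_disc = 6, p_cont = 3, seed = 1) {
  set.seed(seed)
  disc <- matrix(rbinom(n * p_disc, 1, 0.5), n, p_disc)
  disc[rowSums(disc) == 0, 1] <- 1L
  cont <- matrix(rnorm(n * p_cont) + 2, n, p_cont)
  structure(list(discrete = disc, continuous = cont,
                 panel = NULL, standardize = FALSE),
            class = "emr_mixture")
}
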