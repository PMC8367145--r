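#' Specify a synthetic cohort with planted latent disease classes
#'
#' The default cohort emulates a two-class cerebrovascular inpatient
#' population in shape: an 83/17 mix of an ischemic-stroke-like majority
#' class and a hemorrhagic-stroke-like minority class, ~400 diagnosis
#' concepts, procedure and medication panels, ~60 laboratory items with
#' reference ranges and missing-at-random gaps at ~90% coverage, and
#' class-dependent outcome fields (length of stay, cost, death, discharge
#' route) that are never tokenized. Each class carries a set of signature
#' diagnosis/procedure/medication concepts with high prevalence in its own
#' class and near-zero in the other, plus shared low-prevalence background
#' concepts; a subset of labs has class-shifted means relative to their
#' reference ranges.
#'
#' @param n_patients Cohort size (default 8000).
#' @param class_names Two class names.
#' @param mixing Mixing proportions (sum to 1); default `c(0.83, 0.17)`.
#' @param n_diagnosis,n_procedure,n_medication Concept panel sizes.
#' @param n_signature Signature concepts per class within each code panel
#'   (list with `diagnosis`, `procedure`, `medication`).
#' @param n_labs Laboratory items (default 60).
#' @param n_discriminative_labs Labs whose class-2 mean sits above the
#'   reference range (default 15).
#' @param lab_missingness Per-item missing-at-random rate (default 0.08,
#'   i.e. ~92% coverage).
#' @param seed Master seed; named substreams (classes, concepts, labs,
#'   missingness, outcomes) are derived from it.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 8000L,
                        class_names = c("IS_like", "HS_like"),
                        mixing = c(0.83, 0.17),
                        n_diagnosis = 400L, n_procedure = 80L, n_medication = 120L,
                        n_signature = list(diagnosis = 30L, procedure = 12L, medication = 18L),
                        n_labs = 60L, n_discriminative_labs = 15L,
                        lab_missingness = 0.08, seed = 20210723L) {
  if (length(class_names) != 2L || length(mixing) != 2L) {
    abort_validation("The generator plants exactly two latent classes.")
  }
  if (abs(sum(mixing) - 1) > 1e-8 || any(mixing <= 0)) {
    abort_validation("Mixing proportions must be positive and sum to 1.")
  }
  if (lab_missingness < 0 || lab_missingness >= 1) {
    abort_validation("lab_missingness must be in [0, 1).")
  }
  structure(
    list(n_patients = as.integer(n_patients), class_names = class_names,
         mixing = as.numeric(mixing), n_diagnosis = as.integer(n_diagnosis),
         n_procedure = as.integer(n_procedure), n_medication = as.integer(n_medication),
         n_signature = n_signature, n_labs = as.integer(n_labs),
         n_discriminative_labs = as.integer(n_discriminative_labs),
         lab_missingness = as.numeric(lab_missingness), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

substream_seed <- function(seed, name) {
  # stable named substreams below 2^31
  (as.double(seed) * 7919 + sum(utf8ToInt(name)) * 104729) %% 2147483647
}

code_panel <- function(prefix, n, n_sig, class_names, seed) {
  set.seed(substream_seed(seed, paste0("panel_", prefix)))
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  assoc <- rep("background", n)
  assoc[seq_len(n_sig)] <- class_names[1]
  assoc[n_sig + seq_len(n_sig)] <- class_names[2]
  prev <- matrix(NA_real_, n, 2, dimnames = list(ids, class_names))
  bg <- stats::runif(n, 0.005, 0.05)
  prev[, 1] <- bg
  prev[, 2] <- bg
  own <- stats::runif(2 * n_sig, 0.15, 0.55)
  prev[seq_len(n_sig), 1] <- own[seq_len(n_sig)]
  prev[seq_len(n_sig), 2] <- own[seq_len(n_sig)] * 0.04
  prev[n_sig + seq_len(n_sig), 2] <- own[n_sig + seq_len(n_sig)]
  prev[n_sig + seq_len(n_sig), 1] <- own[n_sig + seq_len(n_sig)] * 0.04
  tibble(feature_id = ids, association = assoc,
         prev_1 = prev[, 1], prev_2 = prev[, 2])
}

lab_panel_spec <- function(spec) {
  set.seed(substream_seed(spec$seed, "labdefs"))
  n <- spec$n_labs
  ids <- sprintf("lab%02d", seq_len(n))
  lo <- stats::runif(n, 1, 50)
  width <- stats::runif(n, 2, 20)
  hi <- lo + width
  mid <- (lo + hi) / 2
  n_classes <- ifelse(seq_len(n) %% 3 == 0, 2L, 3L)
  disc <- seq_len(n) <= spec$n_discriminative_labs
  mean_1 <- mid
  mean_2 <- ifelse(disc, hi + 0.8 * width, mid)   # class 2 shifted high
  sd_ <- width / 4
  tibble(feature_id = ids, lo = lo, hi = hi, n_classes = n_classes,
         discriminative = disc, mean_1 = mean_1, mean_2 = mean_2, sd = sd_)
}

#' Generate a reproducible synthetic cohort
#'
#' Per patient: draw the latent class, demographic/admission/resource values,
#' include each diagnosis/procedure/medication concept independently with its
#' class-conditional prevalence, draw lab values from class-conditional
#' normals and apply the missingness mask, and draw outcome fields from
#' class-conditional distributions. Fully deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `records` (wide tibble, one row per patient), `truth`
#'   (tibble `patient_id`, `class`), `schema` (the matching `emr_schema`),
#'   and `concept_ledger` (every code concept the generator can emit with its
#'   true class association and class-conditional prevalences).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  n <- spec$n_patients
  cls_names <- spec$class_names

  set.seed(substream_seed(spec$seed, "classes"))
  cls <- sample(1:2, n, replace = TRUE, prob = spec$mixing)

  dx <- code_panel("dx", spec$n_diagnosis, spec$n_signature$diagnosis, cls_names, spec$seed)
  px <- code_panel("px", spec$n_procedure, spec$n_signature$procedure, cls_names, spec$seed + 1L)
  rx <- code_panel("rx", spec$n_medication, spec$n_signature$medication, cls_names, spec$seed + 2L)
  labs <- lab_panel_spec(spec)

  records <- tibble(patient_id = sprintf("pt%06d", seq_len(n)))

  set.seed(substream_seed(spec$seed, "demographics"))
  records$sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.55, 0.45))
  records$age <- pmax(0, stats::rnorm(n, mean = c(66, 58)[cls], sd = c(12, 14)[cls]))
  records$bmi <- stats::rnorm(n, 24.5, 3.5)

  set.seed(substream_seed(spec$seed, "admission"))
  records$admission_type <- sample(c("emergency", "outpatient", "referral"),
                                   n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  dept_prob <- rbind(c(0.75, 0.05, 0.20), c(0.10, 0.70, 0.20))
  records$department <- vapply(cls, function(g) {
    sample(c("neurology", "neurosurgery", "emergency"), 1L, prob = dept_prob[g, ])
  }, character(1))

  set.seed(substream_seed(spec$seed, "resources"))
  records$ventilator <- ifelse(stats::runif(n) < c(0.015, 0.415)[cls], "yes", "no")
  records$icu <- ifelse(stats::runif(n) < c(0.051, 0.782)[cls], "yes", "no")
  records$n_prior_visits <- stats::rpois(n, lambda = 1.2)

  draw_panel <- function(panel, stream) {
    set.seed(substream_seed(spec$seed, stream))
    prev <- cbind(panel$prev_1, panel$prev_2)
    u <- matrix(stats::runif(n * nrow(panel)), n, nrow(panel))
    present <- u < prev[cbind(rep(seq_len(nrow(panel)), each = n), cls[row(u)])]
    dim(present) <- dim(u)
    colnames(present) <- panel$feature_id
    present
  }
  dx_m <- draw_panel(dx, "concepts_dx")
  px_m <- draw_panel(px, "concepts_px")
  rx_m <- draw_panel(rx, "concepts_rx")
  for (m in list(dx_m, px_m, rx_m)) {
    for (j in colnames(m)) records[[j]] <- ifelse(m[, j], "present", NA_character_)
  }

  set.seed(substream_seed(spec$seed, "labs"))
  for (j in seq_len(nrow(labs))) {
    mu <- c(labs$mean_1[j], labs$mean_2[j])[cls]
    records[[labs$feature_id[j]]] <- stats::rnorm(n, mu, labs$sd[j])
  }
  set.seed(substream_seed(spec$seed, "missingness"))
  for (j in seq_len(nrow(labs))) {
    gap <- stats::runif(n) < spec$lab_missingness
    records[[labs$feature_id[j]]][gap] <- NA_real_
  }

  set.seed(substream_seed(spec$seed, "outcomes"))
  records$length_of_stay <- round(stats::rlnorm(n, log(c(9.8, 12.6))[cls], 0.5), 1)
  records$cost <- round(stats::rlnorm(n, log(c(17.7, 113.0))[cls], 0.6), 1)
  records$death <- stats::runif(n) < c(0.0065, 0.0695)[cls]
  records$discharge_route <- ifelse(records$death, "died",
    ifelse(stats::runif(n) < 0.9, "home", "transfer"))

  schema <- synthetic_schema(dx, px, rx, labs)
  ledger <- bind_rows(
    dx %>% mutate(category = "diagnosis"),
    px %>% mutate(category = "procedure"),
    rx %>% mutate(category = "medication")
  ) %>%
    mutate(token = concept_token(.data$feature_id, "present")) %>%
    select("token", "feature_id", "category", "association", "prev_1", "prev_2")

  list(
    records = records,
    truth = tibble(patient_id = records$patient_id, class = cls_names[cls]),
    schema = schema,
    concept_ledger = ledger,
    lab_definitions = labs
  )
}

synthetic_schema <- function(dx, px, rx, labs) {
  base <- list(
    feature_spec("sex", "demographics", "categorical"),
    feature_spec("age", "demographics", "age"),
    feature_spec("bmi", "demographics", "continuous_quartile"),
    feature_spec("admission_type", "admission", "categorical"),
    feature_spec("department", "admission", "categorical"),
    feature_spec("ventilator", "resources", "categorical"),
    feature_spec("icu", "resources", "categorical"),
    feature_spec("n_prior_visits", "resources", "continuous_quartile")
  )
  codes <- c(
    purrr::map(dx$feature_id, ~ feature_spec(.x, "diagnosis", "categorical")),
    purrr::map(px$feature_id, ~ feature_spec(.x, "procedure", "categorical")),
    purrr::map(rx$feature_id, ~ feature_spec(.x, "medication", "categorical"))
  )
  lab_specs <- purrr::pmap(labs, function(feature_id, lo, hi, n_classes, ...) {
    feature_spec(feature_id, "lab", "lab_reference",
                 reference_range = c(lo, hi), n_lab_classes = n_classes)
  })
  outcomes <- list(
    feature_spec("length_of_stay", "outcome", "continuous_quartile"),
    feature_spec("cost", "outcome", "continuous_quartile"),
    feature_spec("death", "outcome", "categorical"),
    feature_spec("discharge_route", "outcome", "categorical")
  )
  feature_schema(!!!c(base, codes, lab_specs, outcomes))
}

#' Planted-block corpus for order-robustness experiments
#'
#' Builds sentences whose informative tokens come predominantly from one of
#' `n_blocks` token blocks, with the block tokens deliberately separated by
#' runs of `gap` shared background-noise tokens. With `gap >= window`, an
#' unshuffled fixed-window trainer never sees two block tokens in the same
#' context, while shuffling re-mixes them — the fixture behind the
#' shuffle-ensemble robustness checks.
#'
#' @param n_blocks Number of token blocks (default 4).
#' @param tokens_per_block Tokens per block (default 10).
#' @param n_sentences Sentences (default 2000).
#' @param block_tokens_per_sentence Distinct same-block tokens per sentence
#'   (default 4).
#' @param gap Noise tokens inserted between consecutive block tokens
#'   (default 5; 0 gives pure single-block sentences with no noise).
#' @param n_noise_tokens Size of the shared background vocabulary.
#' @param seed Integer seed.
#' @return A list: `corpus` (`emr_corpus`) and `block_map` (tibble of
#'   `token`, `block`; noise tokens are block `"noise"`).
#' @export
make_planted_block_corpus <- function(n_blocks = 4L, tokens_per_block = 10L,
                                      n_sentences = 2000L,
                                      block_tokens_per_sentence = 4L,
                                      gap = 5L, n_noise_tokens = 60L,
                                      seed = 1L) {
  if (any(c(n_blocks, tokens_per_block, n_sentences, block_tokens_per_sentence) < 1L)) {
    abort_validation("Block-corpus parameters must be positive.")
  }
  block_tokens_per_sentence <- min(block_tokens_per_sentence, tokens_per_block)
  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    sprintf("blk%d_t%02d", b, seq_len(tokens_per_block))
  })
  noise <- if (gap > 0L) sprintf("noise_%02d", seq_len(n_noise_tokens)) else character()
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sentences <- purrr::map(seq_len(n_sentences), function(i) {
    b <- sample.int(n_blocks, 1L)
    toks <- sample(blocks[[b]], block_tokens_per_sentence)
    if (gap == 0L) return(toks)
    out <- character(0)
    for (j in seq_along(toks)) {
      out <- c(out, toks[j])
      if (j < length(toks)) out <- c(out, sample(noise, gap, replace = TRUE))
    }
    out
  })
  block_map <- bind_rows(
    purrr::imap_dfr(blocks, ~ tibble(token = .x, block = paste0("block", .y))),
    tibble(token = noise, block = rep("noise", length(noise)))
  )
  list(corpus = build_corpus(sentences), block_map = block_map)
}

#' Top-k neighbor block precision on a planted-block embedding
#'
#' For every block token, the fraction of its top-k cosine neighbors that
#' belong to the same block, averaged over all block tokens — the ground-truth
#' recovery score for the planted-block fixture.
#'
#' @param embedding An `emr_embedding` trained on a planted-block corpus.
#' @param block_map The `block_map` from [make_planted_block_corpus()].
#' @param k Neighbors per query (default 10).
#' @return Mean same-block precision in `[0, 1]`.
#' @export
block_neighbor_precision <- function(embedding, block_map, k = 10L) {
  members <- block_map[block_map$block != "noise", ]
  members <- members[members$token %in% embedding$vocabulary, ]
  prec <- purrr::map_dbl(seq_len(nrow(members)), function(i) {
    nb <- top_k_neighbors(members$token[i], embedding, k = k)
    nb_block <- block_map$block[match(nb$token, block_map$token)]
    mean(nb_block == members$block[i], na.rm = FALSE)
  })
  mean(prec)
}
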