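Package: emr2vec
Title: Embedding-Based Patient Representations from Structured
    Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts heterogeneous per-admission patient records into
    medical-concept tokens (age bands, reference-range lab classes,
    cohort quartiles, categorical pass-through), trains skip-gram
    embeddings with negative sampling over repeatedly shuffled record
    "sentences", and averages concept vectors into low-dimensional
    patient representations.  Ships the matching evaluation battery:
    cosine nearest-neighbor queries per feature category, k-means /
    k-medoids clustering under cosine, Jaccard and mixed distances,
    Hopkins, Silhouette and Davies-Bouldin validity indices, and
    majority-label precision/recall/F1 against diagnosis classes, plus
    a reproducible synthetic cohort generator with planted disease
    classes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
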