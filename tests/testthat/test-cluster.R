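test_that("jaccard distance: identity, forced counts, disjoint sets, triangle", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 1, 0), c(0, 1, 1)), 2 / 3)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), class = "emr2vec_validation")
  # triangle inequality over every triple of nonempty subsets of a 4-universe
  subsets <- lapply(1:15, function(m) as.integer(intToBits(m)[1:4]))
  for (a in subsets) for (b in subsets) for (c_ in subsets) {
    expect_lte(jaccard_distance(a, c_),
               jaccard_distance(a, b) + jaccard_distance(b, c_) + 1e-12)
  }
})

test_that("mixed distance: zero at identity, weights act as stated", {
  p <- list(discrete = c(1, 0, 1), continuous = c(1, 0))
  q_same <- list(discrete = c(1, 0, 1), continuous = c(2, 0))
  expect_equal(mixed_distance(p, p), 0)
  # identical discrete, orthogonal continuous, weights (1,1) -> 1
  q_orth <- list(discrete = c(1, 0, 1), continuous = c(0, 3))
  expect_equal(mixed_distance(p, q_orth), 1)
  # weights (1,0) reduce to pure Jaccard
  q2 <- list(discrete = c(0, 1, 1), continuous = c(0, 3))
  expect_equal(mixed_distance(p, q2, weights = c(1, 0)),
               jaccard_distance(p$discrete, q2$discrete))
  expect_equal(mixed_distance(p, q_same), 0)
})

test_that("pairwise matrices agree with scalar definitions", {
  set.seed(21)
  x <- matrix(rnorm(50), 10, 5)
  Dc <- pairwise_distances(x, "cosine")
  expect_equal(Dc[2, 7], 1 - cosine_similarity(x[2, ], x[7, ]), tolerance = 1e-12)
  b <- matrix(rbinom(60, 1, 0.5), 12, 5)
  b[rowSums(b) == 0, 1] <- 1
  Dj <- pairwise_distances(b, "jaccard")
  expect_equal(Dj[3, 9], brute_jaccard(b[3, ], b[9, ]), tolerance = 1e-12)
  mx <- random_mixture(8, seed = 3)
  Dm <- pairwise_distances(mx, "mixed")
  expect_equal(Dm[1, 5],
               mixed_distance(list(discrete = mx$discrete[1, ], continuous = mx$continuous[1, ]),
                              list(discrete = mx$discrete[5, ], continuous = mx$continuous[5, ])),
               tolerance = 1e-12)
})

test_that("clustering: duplicated points separate perfectly; k = 1 works", {
  x <- rbind(matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0), 10), ncol = 3, byrow = TRUE))
  sol <- cluster_patients(x, 2, "cosine", seed = 1)
  expect_equal(length(unique(sol$assignments$cluster[1:10])), 1L)
  expect_equal(length(unique(sol$assignments$cluster[11:20])), 1L)
  expect_true(sol$assignments$cluster[1] != sol$assignments$cluster[11])
  expect_lt(sol$objective, 1e-10)
  sol1 <- cluster_patients(x, 1, "cosine", seed = 1)
  expect_equal(unique(sol1$assignments$cluster), 1L)
  expect_error(cluster_patients(x, 21, "cosine"), class = "emr2vec_validation")
})

test_that("spherical k-means objective is non-increasing over Lloyd iterations", {
  set.seed(30)
  x <- rbind(matrix(rnorm(100, 3), 25, 4), matrix(rnorm(100, -3), 25, 4))
  objs <- sapply(1:6, function(m) {
    cluster_patients(x, 3, "cosine", seed = 7, n_init = 1, max_iter = m)$objective
  })
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("well-separated blobs are recovered across seeds", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(60, mean = 0, sd = 0.5), 30, 2),
               matrix(rnorm(60, mean = 6, sd = 0.5), 30, 2))
    truth <- rep(1:2, each = 30)
    sol <- cluster_patients(x, 2, "euclidean", seed = s)
    cl <- sol$assignments$cluster
    max(mean(cl == truth), mean(cl == 3 - truth))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("k-medoids under jaccard separates planted binary groups", {
  set.seed(11)
  a <- matrix(rbinom(20 * 12, 1, prob = rep(c(0.9, 0.05), each = 6)), 20, 12, byrow = TRUE)
  b <- matrix(rbinom(20 * 12, 1, prob = rep(c(0.05, 0.9), each = 6)), 20, 12, byrow = TRUE)
  x <- rbind(a, b); x[rowSums(x) == 0, 1] <- 1
  sol <- cluster_patients(x, 2, "jaccard", seed = 2)
  cl <- sol$assignments$cluster
  truth <- rep(1:2, each = 20)
  expect_gte(max(mean(cl == truth), mean(cl == 3 - truth)), 0.95)
})

test_that("hopkins: uniform null ~ 0.5, clustered blobs high, errors", {
  hs <- sapply(1:20, function(s) {
    set.seed(s)
    hopkins_statistic(matrix(runif(400), 200, 2), "euclidean", seed = s)
  })
  expect_lt(abs(mean(hs) - 0.5), 0.1)
  set.seed(2)
  blobs <- rbind(matrix(rnorm(200, 0, 0.05), 100, 2),
                 matrix(rnorm(200, 5, 0.05), 100, 2))
  expect_gte(hopkins_statistic(blobs, "euclidean", seed = 1), 0.75)
  # m = n/2 boundary on 4 points is computable
  h4 <- hopkins_statistic(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2), m = 2, seed = 1)
  expect_true(h4 > 0 && h4 < 1)
  expect_error(hopkins_statistic(matrix(1, 5, 2)), class = "emr2vec_validation")
  expect_error(hopkins_statistic(matrix(runif(20), 10, 2), m = 9),
               class = "emr2vec_validation")
})

test_that("silhouette: worked 1-D example, conventions, brute-force equality", {
  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  D <- pairwise_distances(x, "euclidean")
  cl <- c(1, 1, 2, 2)
  si <- silhouette_index(D, cl)
  # exact hand value: mean of 9.95/10.05, 9.85/9.95, 9.85/9.95, 9.95/10.05
  expect_equal(si, (9.95 / 10.05 + 9.85 / 9.95) / 2, tolerance = 1e-12)
  expect_equal(si, 0.99005, tolerance = 1e-4)
  expect_equal(si, brute_silhouette(D, cl), tolerance = 1e-12)
  # identical points, any 2-way split -> 0 by the a=b=0 convention
  Dz <- matrix(0, 6, 6)
  expect_equal(silhouette_index(Dz, rep(1:2, 3)), 0)
  # singleton clusters score 0
  D3 <- pairwise_distances(matrix(c(0, 5, 100), 3, 1), "euclidean")
  expect_equal(silhouette_index(D3, c(1, 1, 2)),
               brute_silhouette(D3, c(1, 1, 2)), tolerance = 1e-12)
  expect_error(silhouette_index(D, rep(1, 4)), class = "emr2vec_validation")
})

test_that("silhouette matches cluster::silhouette on euclidean data", {
  set.seed(14)
  x <- matrix(rnorm(60), 20, 3)
  cl <- sample(1:3, 20, replace = TRUE)
  cl[1:3] <- 1:3   # ensure nonempty
  D <- pairwise_distances(x, "euclidean")
  ref <- mean(cluster::silhouette(cl, stats::as.dist(D))[, "sil_width"])
  expect_equal(silhouette_index(D, cl), ref, tolerance = 1e-12)
})

test_that("DBI: zero-scatter case, brute-force equality, merging penalty", {
  # identical points per cluster, distinct centers -> DBI 0
  x <- rbind(matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(4, 4), 5), 5, 2, byrow = TRUE))
  sol <- cluster_patients(x, 2, "euclidean", seed = 1)
  expect_equal(davies_bouldin_index(x, sol), 0, tolerance = 1e-12)

  set.seed(9)
  y <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2), matrix(rnorm(40, 5, 0.3), 20, 2))
  sol2 <- cluster_patients(y, 2, "euclidean", seed = 1)
  expect_equal(davies_bouldin_index(y, sol2), brute_dbi(y, sol2), tolerance = 1e-9)
  # overlapping clusters score worse than separated ones
  yo <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2), matrix(rnorm(40, 0.5, 0.3), 20, 2))
  solo <- cluster_patients(yo, 2, "euclidean", seed = 1)
  expect_gt(davies_bouldin_index(yo, solo), davies_bouldin_index(y, sol2))
})

test_that("validity indices match brute force across distance kinds", {
  set.seed(77)
  for (rep_i in 1:40) {
    n <- sample(6:12, 1)
    kind <- c("cosine", "jaccard", "mixed")[1 + rep_i %% 3]
    if (kind == "cosine") {
      x <- matrix(rnorm(n * 3) + 1, n, 3)
    } else if (kind == "jaccard") {
      x <- matrix(rbinom(n * 6, 1, 0.5), n, 6); x[rowSums(x) == 0, 1] <- 1
    } else {
      x <- random_mixture(n, seed = rep_i)
    }
    D <- pairwise_distances(x, kind)
    k <- sample(2:3, 1)
    cl <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    expect_equal(silhouette_index(D, cl), brute_silhouette(D, cl), tolerance = 1e-9)
    sol <- cluster_patients(x, k, kind, seed = rep_i)
    expect_equal(davies_bouldin_index(x, sol, D = D), brute_dbi(x, sol, D = D),
                 tolerance = 1e-9)
  }
})

test_that("select_k sweeps the range and picks planted k with smaller-k ties", {
  set.seed(5)
  x <- rbind(matrix(rnorm(80, 0, 0.2), 40, 2), matrix(rnorm(80, 6, 0.2), 40, 2))
  sel <- select_k(x, "euclidean", k_range = 2:6, seed = 3)
  expect_equal(sel$k_star, 2L)
  expect_equal(sel$sweep$k, 2:6)
  expect_equal(nrow(sel$sweep), 5L)
  sel1 <- select_k(x, "euclidean", k_range = 2, seed = 3)
  expect_equal(sel1$k_star, 2L)
  expect_error(select_k(x, "euclidean", k_range = 2:200),
               class = "emr2vec_validation")
})

test_that("map_and_score reproduces the printed-count scores", {
  cl <- rep(c(1L, 2L), c(6922L, 1310L))
  lab <- c(rep("IS", 6495), rep("HS", 427), rep("IS", 340), rep("HS", 970))
  sc <- map_and_score(cl, lab)
  expect_equal(round(sc$f1[sc$label == "IS"], 3), 0.944)
  expect_equal(round(sc$f1[sc$label == "HS"], 3), 0.717)
  expect_equal(round(100 * sc$recall[sc$label == "IS"], 1), 95.0)
  expect_equal(sc$recall[sc$label == "IS"], 6495 / 6835, tolerance = 1e-12)
  map <- attr(sc, "cluster_label_map")
  expect_equal(unname(map[c("1", "2")]), c("IS", "HS"))
  # f1 is the harmonic mean of its own precision and recall
  expect_equal(sc$f1, 2 * sc$precision * sc$recall / (sc$precision + sc$recall))
})

test_that("map_and_score: perfect assignment and unmapped labels", {
  sc <- map_and_score(c(1, 1, 2, 2), c("x", "x", "y", "y"))
  expect_equal(sc$precision, c(1, 1))
  expect_equal(sc$recall, c(1, 1))
  expect_equal(sc$f1, c(1, 1))
  # a label no cluster maps to: recall 0, precision reported 0 with warning
  expect_warning(sc2 <- map_and_score(c(1, 1, 1), c("x", "x", "y")), "mapped to no cluster")
  expect_equal(sc2$f1[sc2$label == "y"], 0)
  expect_equal(sc2$recall[sc2$label == "y"], 0)
})
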