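#' Jaccard distance between two binary vectors
#'
#' `1 - |a AND b| / |a OR b|`; an error when both vectors are all-zero
#' (the ratio is undefined).
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 1, 0), c(0, 1, 1))  # sets {x,y} vs {y,z} -> 2/3
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) abort_validation("Vectors must have equal length.")
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0) abort_validation("Jaccard distance is undefined for two empty sets.")
  1 - sum(a & b) / un
}

#' Mixed distance for the mixture representation
#'
#' Weighted sum of the Jaccard distance between the discrete blocks and the
#' cosine distance (1 - cosine similarity) between the continuous blocks;
#' default weights (1, 1) take the combination literally as a plain sum.
#'
#' @param p,q `list(discrete =, continuous =)` vectors, or two rows of an
#'   [mixture_representation()] object.
#' @param weights Length-2 numeric `(w_discrete, w_continuous)`.
#' @return Non-negative real.
#' @export
mixed_distance <- function(p, q, weights = c(1, 1)) {
  weights[1] * jaccard_distance(p$discrete, q$discrete) +
    weights[2] * (1 - cosine_similarity(p$continuous, q$continuous))
}

cosine_distance_matrix <- function(x) {
  s <- tcrossprod(row_normalize(as.matrix(x)))
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

jaccard_distance_matrix <- function(x) {
  x <- (as.matrix(x) != 0) * 1
  inter <- tcrossprod(x)
  sizes <- rowSums(x)
  if (any(sizes == 0)) abort_validation("All-zero row: Jaccard geometry undefined.")
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d
}

euclidean_distance_matrix <- function(x) {
  as.matrix(stats::dist(as.matrix(x)))
}

#' Pairwise distance matrix under a named distance kind
#'
#' `"cosine"` and `"euclidean"` expect a numeric matrix (rows = items);
#' `"jaccard"` a binary matrix; `"mixed"` an [mixture_representation()]
#' object (weighted Jaccard on the discrete block plus cosine distance on
#' the continuous block).
#'
#' @param x Representation matrix or `emr_mixture`.
#' @param kind One of `"cosine"`, `"jaccard"`, `"mixed"`, `"euclidean"`.
#' @param weights Mixed-distance weights `(w_discrete, w_continuous)`.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
pairwise_distances <- function(x, kind = c("cosine", "jaccard", "mixed", "euclidean"),
                               weights = c(1, 1)) {
  kind <- match.arg(kind)
  switch(kind,
    cosine = cosine_distance_matrix(x),
    euclidean = euclidean_distance_matrix(x),
    jaccard = jaccard_distance_matrix(x),
    mixed = {
      stopifnot(inherits(x, "emr_mixture"))
      weights[1] * jaccard_distance_matrix(x$discrete) +
        weights[2] * cosine_distance_matrix(x$continuous)
    }
  )
}

new_cluster_solution <- function(k, cluster, ids, centers, medoid_ids, distance,
                                 seed, objective, iterations, converged) {
  structure(
    list(
      k = k,
      assignments = tibble(patient_id = ids, cluster = as.integer(cluster)),
      centers = centers, medoid_ids = medoid_ids, distance = distance,
      seed = seed, objective = objective, iterations = iterations,
      converged = converged
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, %s distance, objective %.4f\n",
              x$k, x$distance, x$objective))
  print(table(x$assignments$cluster))
  invisible(x)
}

#' @export
tidy.cluster_solution <- function(x, ...) x$assignments

#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(k = x$k, distance = x$distance, objective = x$objective,
         iterations = x$iterations, converged = x$converged,
         n = nrow(x$assignments))
}

spherical_kmeans_once <- function(xn, k, seed, max_iter, tol) {
  n <- nrow(xn)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  centers <- xn[sample.int(n, k), , drop = FALSE]
  obj_prev <- Inf
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    sims <- xn %*% t(centers)
    assign <- max.col(sims, ties.method = "first")
    best <- sims[cbind(seq_len(n), assign)]
    # repair empties by reseeding from the point farthest from every center
    for (g in setdiff(seq_len(k), unique(assign))) {
      far <- which.min(best)
      assign[far] <- g
      best[far] <- 1
    }
    obj <- sum(1 - sims[cbind(seq_len(n), assign)])
    for (g in seq_len(k)) {
      m <- colMeans(xn[assign == g, , drop = FALSE])
      nm <- sqrt(sum(m^2))
      centers[g, ] <- if (nm > 0) m / nm else xn[sample.int(n, 1), ]
    }
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, 1e-12)) {
      return(list(assign = assign, centers = centers, objective = obj,
                  iterations = it, converged = TRUE))
    }
    obj_prev <- obj
  }
  list(assign = assign, centers = centers, objective = obj_prev,
       iterations = max_iter, converged = FALSE)
}

#' Cluster patients under a representation-appropriate distance
#'
#' Cosine uses spherical k-means (unit-normalized points, Lloyd iterations
#' with renormalized mean centroids, assignment by maximum cosine; best of
#' `n_init` seeded restarts by total within-cluster cosine distance).
#' Jaccard and mixed distances use PAM k-medoids (build + swap on the
#' precomputed distance matrix; deterministic, so restarts are moot).
#' Euclidean delegates to [stats::kmeans()].
#'
#' @param x Representation matrix (rows = patients) or `emr_mixture`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param distance `"cosine"`, `"jaccard"`, `"mixed"` or `"euclidean"`.
#' @param seed Integer seed for restarts.
#' @param n_init Restarts for the k-means paths (default 10).
#' @param max_iter,tol Lloyd stopping rule (default 300 iterations,
#'   relative objective change 1e-4).
#' @param weights Mixed-distance weights.
#' @param D Optional precomputed distance matrix (skips recomputation for
#'   the medoid paths).
#' @return A `cluster_solution`.
#' @export
cluster_patients <- function(x, k, distance = c("cosine", "jaccard", "mixed", "euclidean"),
                             seed = 1L, n_init = 10L, max_iter = 300L, tol = 1e-4,
                             weights = c(1, 1), D = NULL) {
  distance <- match.arg(distance)
  ids <- representation_ids(x)
  n <- length(ids)
  if (k < 1L || k > n) abort_validation("Need 1 <= k <= number of points.")
  if (distance == "cosine") {
    xn <- row_normalize(as.matrix(x))
    if (k == 1L) {
      m <- colMeans(xn); m <- m / sqrt(sum(m^2))
      obj <- sum(1 - drop(xn %*% m))
      return(new_cluster_solution(1L, rep(1L, n), ids, matrix(m, 1), NULL,
                                  distance, seed, obj, 0L, TRUE))
    }
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    set.seed(seed)
    restart_seeds <- sample.int(.Machine$integer.max, n_init)
    restore_rng(old)
    best <- NULL
    for (s in restart_seeds) {
      fit <- spherical_kmeans_once(xn, k, s, max_iter, tol)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    new_cluster_solution(k, best$assign, ids, best$centers, NULL, distance,
                         seed, best$objective, best$iterations, best$converged)
  } else if (distance == "euclidean") {
    xm <- as.matrix(x)
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    set.seed(seed)
    fit <- stats::kmeans(xm, centers = k, nstart = n_init, iter.max = max_iter)
    restore_rng(old)
    new_cluster_solution(k, fit$cluster, ids, fit$centers, NULL, distance,
                         seed, fit$tot.withinss, fit$iter, TRUE)
  } else {
    if (is.null(D)) D <- pairwise_distances(x, distance, weights = weights)
    if (k == 1L) {
      med <- which.min(rowSums(D))
      return(new_cluster_solution(1L, rep(1L, n), ids, NULL, med, distance,
                                  seed, sum(D[, med]), 0L, TRUE))
    }
    fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE, pamonce = 5)
    new_cluster_solution(k, fit$clustering, ids, NULL, as.integer(fit$id.med),
                         distance, seed, sum(fit$clusinfo[, "av_diss"] * fit$clusinfo[, "size"]),
                         NA_integer_, TRUE)
  }
}

representation_ids <- function(x) {
  if (inherits(x, "emr_mixture")) {
    rownames(x$discrete) %||% paste0("p", seq_len(nrow(x$discrete)))
  } else {
    rownames(x) %||% paste0("p", seq_len(nrow(x)))
  }
}

representation_n <- function(x) {
  if (inherits(x, "emr_mixture")) nrow(x$discrete) else nrow(as.matrix(x))
}

#' Hopkins statistic of clustering tendency
#'
#' `H = sum(u) / (sum(u) + sum(w))` where `u` are distances from `m` points
#' sampled uniformly in the data's per-dimension bounding box to their
#' nearest real data point, and `w` are distances from `m` sampled real
#' points to their nearest *other* real point. `H ~ 0.5` for spatially
#' uniform data, approaching 1 for clustered data.
#'
#' @param x Numeric matrix (rows = points).
#' @param distance `"euclidean"` or `"cosine"` (pseudo-points are sampled in
#'   the coordinate bounding box in both cases).
#' @param m Sample size; default `min(floor(0.1 n), 100)`, at least 1, at
#'   most `n/2`.
#' @param seed Integer seed.
#' @return A number in `(0, 1)`.
#' @export
hopkins_statistic <- function(x, distance = c("euclidean", "cosine"),
                              m = NULL, seed = 1L) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) abort_validation("Need at least 2 points.")
  rng <- apply(x, 2, range)
  if (all(rng[1, ] == rng[2, ])) abort_validation("Degenerate data: all points identical.")
  if (is.null(m)) m <- max(1L, min(floor(0.1 * n), 100L))
  m <- as.integer(m)
  if (m < 1L || m > n / 2) abort_validation("Need 1 <= m <= n/2.")
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  pseudo <- sapply(seq_len(ncol(x)), function(j) stats::runif(m, rng[1, j], rng[2, j]))
  pseudo <- matrix(pseudo, nrow = m)
  real_idx <- sample.int(n, m)

  cross_d <- function(a, b) {
    if (distance == "euclidean") {
      a2 <- rowSums(a^2); b2 <- rowSums(b^2)
      d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
      sqrt(pmax(d2, 0))
    } else {
      1 - tcrossprod(row_normalize(a), row_normalize(b))
    }
  }
  u <- apply(cross_d(pseudo, x), 1, min)
  dw <- cross_d(x[real_idx, , drop = FALSE], x)
  dw[cbind(seq_len(m), real_idx)] <- Inf
  w <- apply(dw, 1, min)
  sum(u) / (sum(u) + sum(w))
}

#' Silhouette index over an arbitrary distance matrix
#'
#' Mean over points of `(b - a) / max(a, b)` with `a` the mean distance to
#' the point's own cluster (excluding itself) and `b` the smallest mean
#' distance to another cluster. Conventions: a point in a singleton cluster
#' scores 0, and `a = b = 0` scores 0.
#'
#' @param D Symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param assignments Integer cluster labels (or a `cluster_solution`).
#' @return A number in `[-1, 1]`.
#' @export
silhouette_index <- function(D, assignments) {
  cl <- assignment_vector(assignments)
  D <- as.matrix(D)
  n <- length(cl)
  stopifnot(nrow(D) == n)
  ks <- sort(unique(cl))
  if (length(ks) < 2L) abort_validation("Silhouette needs at least 2 clusters.")
  G <- outer(cl, ks, "==") * 1
  sizes <- colSums(G)
  Tm <- D %*% G                       # n x k sums of distances to each cluster
  mean_other <- sweep(Tm, 2, sizes, "/")
  gi <- match(cl, ks)
  own_size <- sizes[gi]
  a <- Tm[cbind(seq_len(n), gi)] / pmax(own_size - 1, 1)
  mean_other[cbind(seq_len(n), gi)] <- Inf
  b <- apply(mean_other, 1, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[own_size == 1] <- 0
  mean(s)
}

assignment_vector <- function(assignments) {
  if (inherits(assignments, "cluster_solution")) {
    assignments$assignments$cluster
  } else {
    as.integer(assignments)
  }
}

#' Davies-Bouldin index
#'
#' `(1/k) * sum_i max_{j != i} (s_i + s_j) / d(center_i, center_j)` with
#' `s_i` the mean distance of cluster members to their center. Centers are
#' the solution's centroids for the k-means paths (cosine/euclidean) and its
#' medoids for the k-medoids paths, keeping the index internal to the
#' distance space. Lower is better; the index is unbounded above and is
#' reported unclamped.
#'
#' @param x The representation that was clustered (matrix or `emr_mixture`).
#' @param solution A `cluster_solution`.
#' @param D Optional precomputed distance matrix (required information for
#'   medoid solutions can be taken from it instead of recomputing).
#' @param weights Mixed-distance weights (medoid paths).
#' @return Non-negative real; error if two centers coincide.
#' @export
davies_bouldin_index <- function(x, solution, D = NULL, weights = c(1, 1)) {
  stopifnot(inherits(solution, "cluster_solution"))
  cl <- solution$assignments$cluster
  ks <- sort(unique(cl))
  k <- length(ks)
  if (k < 2L) abort_validation("DBI needs at least 2 clusters.")
  if (!is.null(solution$centers)) {
    xm <- as.matrix(x)
    centers <- solution$centers
    if (solution$distance == "cosine") {
      xm <- row_normalize(xm)
      member_d <- 1 - xm %*% t(centers)
      center_d <- 1 - tcrossprod(row_normalize(centers))
    } else {
      member_d <- sqrt(pmax(outer(rowSums(xm^2), rowSums(centers^2), "+") -
                              2 * tcrossprod(xm, centers), 0))
      center_d <- as.matrix(stats::dist(centers))
    }
  } else {
    if (is.null(D)) D <- pairwise_distances(x, solution$distance, weights = weights)
    member_d <- D[, solution$medoid_ids, drop = FALSE]
    center_d <- D[solution$medoid_ids, solution$medoid_ids, drop = FALSE]
  }
  sig <- vapply(seq_len(k), function(g) mean(member_d[cl == ks[g], g]), numeric(1))
  off <- center_d; diag(off) <- Inf
  if (any(off[upper.tri(off)] == 0)) abort_validation("degenerate solution: coincident cluster centers.")
  ratios <- outer(sig, sig, "+") / center_d
  diag(ratios) <- -Inf
  mean(apply(ratios, 1, max))
}

#' Silhouette-guided choice of the number of clusters
#'
#' Clusters at every `k` in `k_range`, scores each solution with the
#' silhouette index over the (computed once) distance matrix, and returns
#' the `k` with the highest silhouette (ties go to the smaller `k`).
#'
#' @inheritParams cluster_patients
#' @param k_range Candidate cluster counts (default `2:15`).
#' @return A `select_k_result`: list with `k_star`, `sweep` (tibble of `k`,
#'   `silhouette`, `objective`), and the winning `solution`.
#' @export
select_k <- function(x, distance = c("cosine", "jaccard", "mixed", "euclidean"),
                     k_range = 2:15, seed = 1L, n_init = 10L, weights = c(1, 1),
                     D = NULL) {
  distance <- match.arg(distance)
  n <- representation_n(x)
  if (max(k_range) > n) abort_validation("max(k_range) exceeds the number of points.")
  if (is.null(D)) D <- pairwise_distances(x, distance, weights = weights)
  fits <- purrr::map(k_range, function(k) {
    sol <- cluster_patients(x, k, distance, seed = seed, n_init = n_init,
                            weights = weights, D = D)
    list(sol = sol, si = silhouette_index(D, sol))
  })
  sweep_tbl <- tibble(
    k = as.integer(k_range),
    silhouette = purrr::map_dbl(fits, "si"),
    objective = purrr::map_dbl(fits, ~ .x$sol$objective)
  )
  best <- which.max(sweep_tbl$silhouette)  # first max -> smaller k on ties
  structure(
    list(k_star = sweep_tbl$k[best], sweep = sweep_tbl,
         solution = fits[[best]]$sol, distance = distance),
    class = "select_k_result"
  )
}

#' @export
print.select_k_result <- function(x, ...) {
  cat(sprintf("<select_k_result> k* = %d by silhouette (%s distance)\n",
              x$k_star, x$distance))
  print(x$sweep, n = nrow(x$sweep))
  invisible(x)
}

#' @export
tidy.select_k_result <- function(x, ...) x$sweep

#' Majority-label mapping and per-class precision/recall/F1
#'
#' Labels each cluster with its majority true label, then scores every label:
#' precision = correctly-labeled members / size of the predicted set, recall
#' = correctly-labeled members / label prevalence, F1 their harmonic mean.
#' A label that no cluster maps to gets recall 0 and (with a warning)
#' precision and F1 reported as 0.
#'
#' @param solution A `cluster_solution`, or a vector/tibble of cluster
#'   assignments aligned with `true_labels`.
#' @param true_labels Character/factor vector of true labels, or a tibble
#'   with `patient_id` and `label` columns.
#' @return A `class_scores` tibble of `label`, `precision`, `recall`, `f1`,
#'   `support`, with the `cluster -> label` map in
#'   `attr(, "cluster_label_map")` and the confusion table in
#'   `attr(, "confusion")`.
#' @examples
#' cl <- rep(c(1, 2), c(6922, 1310))
#' lab <- c(rep("IS", 6495), rep("HS", 427), rep("IS", 340), rep("HS", 970))
#' map_and_score(cl, lab)
#' @export
map_and_score <- function(solution, true_labels) {
  cl <- if (inherits(solution, "cluster_solution")) {
    solution$assignments$cluster
  } else if (is.data.frame(solution)) {
    solution$cluster
  } else {
    as.integer(solution)
  }
  if (is.data.frame(true_labels)) {
    if (inherits(solution, "cluster_solution")) {
      ord <- match(solution$assignments$patient_id, true_labels$patient_id)
      if (anyNA(ord)) abort_validation("Labels missing for some clustered patients.")
      true_labels <- true_labels$label[ord]
    } else {
      true_labels <- true_labels$label
    }
  }
  lab <- as.character(true_labels)
  if (length(lab) != length(cl) || anyNA(lab)) {
    abort_validation("Need one non-missing true label per clustered patient.")
  }
  conf <- table(cluster = cl, label = lab)
  maj <- colnames(conf)[max.col(conf, ties.method = "first")]
  cluster_label_map <- stats::setNames(maj, rownames(conf))
  labels <- sort(unique(lab))
  scores <- purrr::map_dfr(labels, function(L) {
    pred <- maj[match(as.character(cl), rownames(conf))] == L
    support <- sum(lab == L)
    tp <- sum(pred & lab == L)
    if (!any(pred)) {
      warn(paste0("Label '", L, "' is mapped to no cluster; precision reported as 0."))
      return(tibble(label = L, precision = 0, recall = 0, f1 = 0, support = support))
    }
    precision <- tp / sum(pred)
    recall <- tp / support
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(label = L, precision = precision, recall = recall, f1 = f1, support = support)
  })
  attr(scores, "cluster_label_map") <- cluster_label_map
  attr(scores, "confusion") <- conf
  class(scores) <- c("class_scores", class(scores))
  scores
}

#' Full validity report for one clustering solution
#'
#' Bundles the three internal indices (Hopkins, silhouette, Davies-Bouldin)
#' with the external majority-label scores when true labels are supplied.
#'
#' @param x Representation matrix or `emr_mixture`.
#' @param solution A `cluster_solution`.
#' @param true_labels Optional labels (see [map_and_score()]).
#' @param D Optional precomputed distance matrix.
#' @param seed Seed for the Hopkins sampling.
#' @param weights Mixed-distance weights.
#' @return A `validity_report` list: `hopkins`, `silhouette`, `dbi`,
#'   `per_class`, `cluster_label_map`.
#' @export
validity_report <- function(x, solution, true_labels = NULL, D = NULL,
                            seed = 1L, weights = c(1, 1)) {
  if (is.null(D)) D <- pairwise_distances(x, solution$distance, weights = weights)
  hop_x <- if (inherits(x, "emr_mixture")) {
    cbind(x$discrete, x$continuous)
  } else {
    as.matrix(x)
  }
  hop_kind <- if (solution$distance == "cosine") "cosine" else "euclidean"
  rep_out <- list(
    hopkins = hopkins_statistic(hop_x, hop_kind, seed = seed),
    silhouette = silhouette_index(D, solution),
    dbi = davies_bouldin_index(x, solution, D = D, weights = weights),
    per_class = NULL, cluster_label_map = NULL
  )
  if (!is.null(true_labels)) {
    sc <- map_and_score(solution, true_labels)
    rep_out$per_class <- sc
    rep_out$cluster_label_map <- attr(sc, "cluster_label_map")
  }
  structure(rep_out, class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> Hopkins %.3f | silhouette %.3f | DBI %.3f\n",
              x$hopkins, x$silhouette, x$dbi))
  if (!is.null(x$per_class)) print(as_tibble(x$per_class))
  invisible(x)
}

#' @export
glance.validity_report <- function(x, ...) {
  tibble(hopkins = x$hopkins, silhouette = x$silhouette, dbi = x$dbi)
}

#' @export
tidy.validity_report <- function(x, ...) {
  if (is.null(x$per_class)) tibble() else as_tibble(x$per_class)
}
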