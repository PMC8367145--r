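# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain double loops and naive formulas.

brute_silhouette <- function(D, cl) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(D[i, cl == g]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# DBI recomputed naively from a cluster_solution's own centers/medoids.
brute_dbi <- function(x, solution, D = NULL) {
  cl <- solution$assignments$cluster
  ks <- sort(unique(cl))
  k <- length(ks)
  if (!is.null(solution$centers)) {
    xm <- as.matrix(x)
    cosd <- function(u, w) 1 - sum(u * w) / sqrt(sum(u^2) * sum(w^2))
    eucd <- function(u, w) sqrt(sum((u - w)^2))
    dfun <- if (solution$distance == "cosine") cosd else eucd
    centers <- lapply(seq_len(k), function(g) solution$centers[g, ])
  } else {
    dfun <- NULL
    centers <- solution$medoid_ids
  }
  sig <- numeric(k)
  for (g in seq_len(k)) {
    members <- which(cl == ks[g])
    sig[g] <- mean(sapply(members, function(i) {
      if (is.null(dfun)) D[i, centers[g]] else dfun(as.matrix(x)[i, ], centers[[g]])
    }))
  }
  cd <- matrix(0, k, k)
  for (g in seq_len(k)) for (h in seq_len(k)) {
    cd[g, h] <- if (is.null(dfun)) D[centers[g], centers[h]] else dfun(centers[[g]], centers[[h]])
  }
  total <- 0
  for (g in seq_len(k)) {
    best <- -Inf
    for (h in seq_len(k)) {
      if (h == g) next
      best <- max(best, (sig[g] + sig[h]) / cd[g, h])
    }
    total <- total + best
  }
  total / k
}

brute_jaccard <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  1 - length(intersect(A, B)) / length(union(A, B))
}

# Full-batch full-softmax skip-gram on windowed co-occurrence counts:
# maximizes sum_ij N_ij log softmax_j(u_i . v_j) by plain gradient ascent.
# An independent route to skip-gram geometry (exact objective, no sampling).
reference_softmax_skipgram <- function(corpus, window = 5L, dim = 16L,
                                       iters = 300L, lr = 0.5, seed = 42L) {
  vocab <- corpus$vocabulary
  V <- length(vocab)
  N <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (s in corpus$sentences) {
    idx <- match(s, vocab)
    Tn <- length(idx)
    for (t in seq_len(Tn)) {
      for (j in max(1, t - window):min(Tn, t + window)) {
        if (j != t) N[idx[t], idx[j]] <- N[idx[t], idx[j]] + 1
      }
    }
  }
  set.seed(seed)
  U <- matrix(rnorm(V * dim, sd = 0.1), V, dim)
  Vm <- matrix(rnorm(V * dim, sd = 0.1), V, dim)
  rowtot <- rowSums(N)
  for (it in seq_len(iters)) {
    scores <- U %*% t(Vm)
    scores <- scores - apply(scores, 1, max)
    P <- exp(scores); P <- P / rowSums(P)
    G <- N - rowtot * P
    gU <- G %*% Vm / sum(N)
    gV <- t(G) %*% U / sum(N)
    U <- U + lr * gU
    Vm <- Vm + lr * gV
  }
  rownames(U) <- vocab
  U
}

pairwise_cosine_vec <- function(M) {
  Mn <- M / sqrt(rowSums(M^2))
  S <- Mn %*% t(Mn)
  S[upper.tri(S)]
}
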