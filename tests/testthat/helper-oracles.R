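# Brute-force reference implementations used as independent oracles.
# All are deliberately naive (loops, enumeration) and never share code with
# the package internals they check.

l1 <- function(a, b) sum(abs(a - b))

# Full pairwise L1 distance matrix by double loop.
brute_l1_matrix <- function(x) {
  m <- nrow(x)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) d[i, j] <- l1(x[i, ], x[j, ])
  }
  d
}

brute_silhouette <- function(x, labels) {
  d <- brute_l1_matrix(x)
  m <- nrow(x)
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- which(labels == labels[i] & seq_len(m) != i)
    if (!length(own)) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- Inf
    for (c in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == c]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

brute_dunn <- function(x, labels) {
  d <- brute_l1_matrix(x)
  clusters <- unique(labels)
  sep <- Inf
  diam <- 0
  for (ci in clusters) {
    ii <- which(labels == ci)
    for (i in ii) for (j in ii) diam <- max(diam, d[i, j])
    for (cj in setdiff(clusters, ci)) {
      for (i in ii) for (j in which(labels == cj)) sep <- min(sep, d[i, j])
    }
  }
  if (diam <= 0) {
    return(if (sep > 0) 1e6 else 0)
  }
  sep / diam
}

brute_davies_bouldin <- function(x, labels, centroids) {
  k <- nrow(centroids)
  s <- numeric(k)
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    s[c] <- mean(vapply(idx, function(i) l1(x[i, ], centroids[c, ]), 1))
  }
  worst <- numeric(k)
  for (i in seq_len(k)) {
    r <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- l1(centroids[i, ], centroids[j, ])
      r <- max(r, if (dij > 0) (s[i] + s[j]) / dij else 1e6)
    }
    worst[i] <- r
  }
  mean(worst)
}

# Global optimum of 2-cluster L1 k-means by enumerating all 2-partitions;
# centroids are coordinate-wise medians.
brute_kmeans2_cost <- function(x) {
  m <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(m - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    if (!any(g) || all(g)) next
    cost <- 0
    for (grp in list(which(g), which(!g))) {
      cen <- apply(x[grp, , drop = FALSE], 2, median)
      cost <- cost + sum(abs(sweep(x[grp, , drop = FALSE], 2, cen)))
    }
    best <- min(best, cost)
  }
  best
}

# All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# Asymmetric signed modularity written directly from the definition
# (independent of the package's matrix formulation).
direct_signed_q <- function(w, partition, gamma = 1) {
  n <- nrow(w)
  wp <- pmax(w, 0)
  wn <- pmax(-w, 0)
  vp <- sum(wp)
  vn <- sum(wn)
  sp <- rowSums(wp)
  sn <- rowSums(wn)
  qp <- 0
  qn <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (partition[i] != partition[j]) next
      if (vp > 0) qp <- qp + wp[i, j] - gamma * sp[i] * sp[j] / vp
      if (vn > 0) qn <- qn + wn[i, j] - gamma * sn[i] * sn[j] / vn
    }
  }
  (if (vp > 0) qp / vp else 0) - (if (vn > 0) qn / (vp + vn) else 0)
}

# Exhaustive-search maximum of the signed modularity over all partitions.
brute_max_q <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) direct_signed_q(w, p, gamma), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# Tiny deterministic cohort used across tests.
tiny_cohort <- function(n_subjects = c(2, 2), n_volumes = 80, seed = 42,
                        ...) {
  simulate_cohort(cohort_spec(
    n_subjects = n_subjects,
    n_volumes = n_volumes, seed = seed, ...
  ))
}

# A small two-network parcellation for hand-checkable metric tests.
toy_parcellation <- function() {
  parcellation(
    c("a1", "a2", "a3", "b1", "b2"),
    c("A", "A", "A", "B", "B")
  )
}
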