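#' Cluster validity indices under the L1 metric
#'
#' The four ingredients of the mixed performance criterion used for choosing
#' the number of connectivity states. All pointwise distances are Manhattan
#' (cityblock), the same metric used for clustering.
#'
#' @name cluster_validity
NULL

#' @describeIn cluster_validity Average cluster size: total observations / k.
#' @param labels Integer cluster labels in `1..k`.
#' @param k Number of clusters.
#' @export
average_cluster_size <- function(labels, k) {
  stopifnot(all(labels >= 1), all(labels <= k))
  length(labels) / k
}

# Per-point sums of distances to each cluster: M x k matrix from a full
# symmetric distance matrix (fast path via rowsum).
cluster_dist_sums <- function(d, labels, k) {
  s <- rowsum(d, group = labels) # k x M sums over rows by cluster
  t(s)[, seq_len(k), drop = FALSE]
}

#' @describeIn cluster_validity Average silhouette width in `[-1, 1]`:
#'   mean over points of `(b - a) / max(a, b)` with `a` the mean distance to
#'   the point's own cluster and `b` the smallest mean distance to another
#'   cluster. A point whose `max(a, b)` is 0 and members of singleton
#'   clusters contribute 0.
#' @param features Numeric M x P matrix (ignored when `d` is supplied).
#' @param d Optional precomputed full M x M L1 distance matrix.
#' @export
average_silhouette <- function(features, labels, k = max(labels), d = NULL) {
  if (is.null(d)) d <- l1_distance_matrix(features)
  m <- nrow(d)
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) abort("Every cluster must be non-empty.")
  sums <- cluster_dist_sums(d, labels, k)
  own <- sums[cbind(seq_len(m), labels)]
  a <- ifelse(sizes[labels] > 1, own / (sizes[labels] - 1), 0)
  mean_other <- sweep(sums, 2, sizes, "/")
  mean_other[cbind(seq_len(m), labels)] <- Inf
  b <- apply(mean_other, 1, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[sizes[labels] == 1] <- 0
  mean(s)
}

#' @describeIn cluster_validity Dunn index: smallest between-cluster
#'   point-to-point distance divided by the largest cluster diameter. A zero
#'   diameter with positive separation is capped at 1e6. For more than
#'   `max_points` observations the index is computed on a stratified
#'   subsample (documented approximation; an attribute `subsampled` flags it).
#' @param max_points Subsampling threshold for the Dunn index.
#' @param seed Seed for the stratified subsample (only used when subsampling).
#' @export
dunn_index <- function(features, labels, k = max(labels), d = NULL,
                       max_points = 6000L, seed = 1L) {
  subsampled <- FALSE
  if (is.null(d)) {
    if (nrow(features) > max_points) {
      subsampled <- TRUE
      keep <- withr::with_seed(seed, {
        unlist(lapply(seq_len(k), function(c) {
          idx <- which(labels == c)
          n_c <- max(2L, round(length(idx) / nrow(features) * max_points))
          if (length(idx) > n_c) sample(idx, n_c) else idx
        }))
      })
      features <- features[keep, , drop = FALSE]
      labels <- labels[keep]
    }
    d <- l1_distance_matrix(features)
  }
  sep <- Inf
  diam <- 0
  for (ci in seq_len(k)) {
    ii <- which(labels == ci)
    if (!length(ii)) next
    diam <- max(diam, max(d[ii, ii]))
    for (cj in seq_len(k)) {
      if (cj <= ci) next
      jj <- which(labels == cj)
      if (length(jj)) sep <- min(sep, min(d[ii, jj]))
    }
  }
  out <- if (diam <= 0) {
    if (sep > 0) 1e6 else 0
  } else {
    sep / diam
  }
  attr(out, "subsampled") <- subsampled
  out
}

#' @describeIn cluster_validity Davies-Bouldin index (> 0, lower is better):
#'   mean over clusters of the worst `(s_i + s_j) / d_ij` ratio, where `s`
#'   is the mean L1 distance of members to their centroid and `d_ij` the L1
#'   distance between centroids. Coincident centroids cap the ratio at 1e6
#'   with a warning.
#' @param centroids k x P matrix of cluster centroids.
#' @export
davies_bouldin <- function(features, labels, centroids, k = max(labels)) {
  stopifnot(nrow(centroids) == k)
  features <- as.matrix(features)
  dc <- cross_l1(features, as.matrix(centroids))
  s <- vapply(
    seq_len(k),
    function(c) mean(dc[labels == c, c]),
    numeric(1)
  )
  dcent <- cross_l1(as.matrix(centroids), as.matrix(centroids))
  r <- matrix(0, k, k)
  capped <- FALSE
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (dcent[i, j] <= 0) {
        r[i, j] <- 1e6
        capped <- TRUE
      } else {
        r[i, j] <- (s[i] + s[j]) / dcent[i, j]
      }
    }
  }
  if (capped) warn("Coincident centroids; Davies-Bouldin ratio capped at 1e6.")
  mean(apply(r, 1, max))
}

#' Mixed performance criterion for choosing the number of states
#'
#' `MPFC = CS * AS * DI / DB`: average cluster size times average silhouette
#' times Dunn index, divided by the Davies-Bouldin index. Silhouette and
#' Dunn reward compact, separated clusters; DB (lower is better) divides;
#' CS penalizes fragmenting the windows into many small clusters. The
#' optimal k is the peak of MPFC over the scanned range.
#'
#' @param cs Average cluster size.
#' @param as_ Average silhouette.
#' @param di Dunn index.
#' @param db Davies-Bouldin index (> 0).
#' @return The scalar criterion.
#' @examples
#' mpfc(10, 0.5, 2, 0.8) # 12.5
#' @export
mpfc <- function(cs, as_, di, db) {
  if (!is.finite(db) || db <= 0) abort("`db` must be positive.")
  cs * as_ * di / db
}

# Full symmetric L1 distance matrix.
l1_distance_matrix <- function(features) {
  as.matrix(stats::dist(as.matrix(features), method = "manhattan"))
}

#' Scan cluster numbers and select the MPFC peak
#'
#' Runs [kmeans_manhattan()] for each candidate k, computes average cluster
#' size, average silhouette, Dunn and Davies-Bouldin indices (all under L1)
#' and their MPFC product, and returns the model at the MPFC peak together
#' with the full quality table.
#'
#' @param features M x P feature matrix (windowed FC upper triangles).
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param n_init Restarts per k (default 50).
#' @param seed Integer seed.
#' @param dunn_max_points Subsampling threshold passed to [dunn_index()].
#' @return List of class `dfc_k_selection`: `k_opt`, `quality` (tibble with
#'   one row per k: `k, cs, as_, di, db, mpfc`), `model` (the
#'   `dfc_kmeans` fit at `k_opt`).
#' @export
select_k <- function(features, k_range = 2:6, n_init = 50L,
                     seed = 20230502L, dunn_max_points = 6000L) {
  features <- as.matrix(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) abort("`k_range` must be >= 2.")
  k_range <- k_range[k_range <= nrow(features)]
  if (!length(k_range)) abort("No feasible k in `k_range`.")
  d <- if (nrow(features) <= dunn_max_points) {
    l1_distance_matrix(features)
  } else {
    NULL
  }
  fits <- list()
  rows <- purrr::map(k_range, function(k) {
    fit <- kmeans_manhattan(features, k, n_init = n_init, seed = seed + k)
    fits[[as.character(k)]] <<- fit
    cs <- average_cluster_size(fit$labels, k)
    as_ <- average_silhouette(features, fit$labels, k, d = d)
    di <- dunn_index(features, fit$labels, k,
      d = d,
      max_points = dunn_max_points, seed = seed
    )
    db <- davies_bouldin(features, fit$labels, fit$centers, k)
    tibble(
      k = k, cs = cs, as_ = as_, di = as.numeric(di), db = db,
      mpfc = mpfc(cs, as_, as.numeric(di), db),
      dunn_subsampled = isTRUE(attr(di, "subsampled"))
    )
  })
  quality <- bind_rows(rows)
  k_opt <- quality$k[which.max(quality$mpfc)]
  structure(
    list(
      k_opt = k_opt,
      quality = quality,
      model = fits[[as.character(k_opt)]]
    ),
    class = "dfc_k_selection"
  )
}

#' @export
print.dfc_k_selection <- function(x, ...) {
  cat("<dfc_k_selection> MPFC peak at k =", x$k_opt, "\n")
  print(x$quality)
  invisible(x)
}
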