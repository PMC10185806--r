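#' K-means clustering under the Manhattan (cityblock) distance
#'
#' Lloyd-style alternation in which assignment minimizes the L1 distance and
#' the centroid update is the coordinate-wise median (the L1 minimizer), so
#' the algorithm is a k-medians. Initialization is k-means++-style seeding
#' adapted to L1 (new centers drawn with probability proportional to the L1
#' distance to the nearest chosen center); the best of `n_init` restarts by
#' total within-cluster L1 cost is returned. Deterministic given `seed`.
#' A cluster emptied during iteration is re-seeded at the point farthest
#' (L1) from its current centroid.
#'
#' @param x Numeric M x P feature matrix (M observations).
#' @param k Number of clusters, `1 <= k <= M`.
#' @param n_init Number of random restarts (default 50).
#' @param seed Integer seed (default 20230502).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return A list of class `dfc_kmeans`: `labels` (integer in `1..k`),
#'   `centers` (k x P), `cost` (total within-cluster L1), `k`, `n_init`,
#'   `seed`, `distance = "manhattan"`.
#' @examples
#' x <- rbind(
#'   matrix(rnorm(40, 0), 20, 2),
#'   matrix(rnorm(40, 10), 20, 2)
#' )
#' fit <- kmeans_manhattan(x, k = 2, n_init = 5, seed = 1)
#' table(fit$labels)
#' @export
kmeans_manhattan <- function(x, k, n_init = 50L, seed = 20230502L,
                             max_iter = 100L) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (k > m) abort("`k` cannot exceed the number of observations.")
  if (k < 1) abort("`k` must be >= 1.")
  if (k == 1) {
    center <- matrix(apply(x, 2, median), 1, ncol(x))
    cost <- sum(abs(sweep(x, 2, center[1, ])))
    return(structure(
      list(
        labels = rep(1L, m), centers = center, cost = cost, k = 1L,
        n_init = 0L, seed = seed, distance = "manhattan", iterations = 0L
      ),
      class = "dfc_kmeans"
    ))
  }
  unif <- withr::with_seed(seed, matrix(runif(k * n_init), k, n_init))
  inits <- kmeanspp_l1_seed(x, as.integer(k), as.integer(n_init), unif)
  fit <- kmeans_l1_run(x, inits, as.integer(k), as.integer(max_iter))
  structure(
    list(
      labels = as.integer(fit$labels), centers = fit$centers,
      cost = fit$cost, k = as.integer(k), n_init = as.integer(n_init),
      seed = as.integer(seed), distance = "manhattan",
      iterations = fit$iterations
    ),
    class = "dfc_kmeans"
  )
}

#' @export
print.dfc_kmeans <- function(x, ...) {
  cat(
    "<dfc_kmeans> k = ", x$k, ", ", length(x$labels),
    " observations, total L1 cost = ", format(x$cost, digits = 6),
    " (", x$n_init, " restarts, seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
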