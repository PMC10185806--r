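test_that("two separated clouds are split perfectly with median centroids", {
  withr::local_seed(1)
  x <- rbind(
    matrix(stats::runif(40, -0.1, 0.1), 20, 2),
    matrix(10 + stats::runif(40, -0.1, 0.1), 20, 2)
  )
  fit <- kmeans_manhattan(x, 2, n_init = 10, seed = 2)
  expect_equal(length(unique(fit$labels[1:20])), 1)
  expect_equal(length(unique(fit$labels[21:40])), 1)
  expect_false(fit$labels[1] == fit$labels[21])
  med1 <- apply(x[1:20, ], 2, median)
  med2 <- apply(x[21:40, ], 2, median)
  got <- fit$centers[order(fit$centers[, 1]), ]
  expect_lt(sum(abs(got[1, ] - med1)), 0.2)
  expect_lt(sum(abs(got[2, ] - med2)), 0.2)
})

test_that("k = 1 returns the coordinate-wise median", {
  withr::local_seed(2)
  x <- matrix(rnorm(60), 20, 3)
  fit <- kmeans_manhattan(x, 1)
  expect_equal(fit$centers[1, ], apply(x, 2, median))
  expect_equal(fit$labels, rep(1L, 20))
})

test_that("duplicated rows always share a label", {
  withr::local_seed(3)
  x <- matrix(rnorm(24), 12, 2)
  x2 <- rbind(x, x)
  fit <- kmeans_manhattan(x2, 3, n_init = 10, seed = 4)
  expect_equal(fit$labels[1:12], fit$labels[13:24])
})

test_that("k exceeding the number of observations is rejected", {
  expect_error(kmeans_manhattan(matrix(1:6, 3, 2), 4), "exceed")
  expect_error(kmeans_manhattan(matrix(1:6, 3, 2), 0), ">= 1")
})

test_that("best restart attains the exhaustive-search L1 optimum (k = 2)", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    x <- matrix(rnorm(24), 12, 2)
    fit <- kmeans_manhattan(x, 2, n_init = 20, seed = seed + 100)
    expect_equal(fit$cost, brute_kmeans2_cost(x), tolerance = 1e-10)
  }
})

test_that("determinism: same seed gives identical fits", {
  withr::local_seed(9)
  x <- matrix(rnorm(200), 50, 4)
  a <- kmeans_manhattan(x, 3, n_init = 8, seed = 77)
  b <- kmeans_manhattan(x, 3, n_init = 8, seed = 77)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})

test_that("average cluster size is total windows over k", {
  expect_equal(average_cluster_size(rep(1:2, c(2410, 2410)), 2), 2410)
  expect_equal(average_cluster_size(rep(1:4, each = 25), 4), 25)
  expect_equal(average_cluster_size(rep(1:3, c(40, 30, 30)), 3), 100 / 3)
})

test_that("validity indices match brute-force oracles on small examples", {
  withr::local_seed(21)
  for (rep in 1:4) {
    x <- matrix(rnorm(20), 10, 2)
    labels <- sample(1:3, 10, replace = TRUE)
    labels[1:3] <- 1:3 # keep all clusters non-empty
    cents <- do.call(rbind, lapply(1:3, function(c) {
      apply(x[labels == c, , drop = FALSE], 2, median)
    }))
    expect_equal(
      average_silhouette(x, labels, 3),
      brute_silhouette(x, labels),
      tolerance = 1e-12
    )
    expect_equal(
      as.numeric(dunn_index(x, labels, 3)),
      brute_dunn(x, labels),
      tolerance = 1e-12
    )
    expect_equal(
      davies_bouldin(x, labels, cents, 3),
      brute_davies_bouldin(x, labels, cents),
      tolerance = 1e-12
    )
  }
})

test_that("silhouette agrees with cluster::silhouette under L1", {
  withr::local_seed(8)
  x <- matrix(rnorm(60), 30, 2)
  labels <- kmeans_manhattan(x, 3, n_init = 5, seed = 1)$labels
  d <- stats::dist(x, method = "manhattan")
  ref <- mean(cluster::silhouette(labels, d)[, "sil_width"])
  expect_equal(average_silhouette(x, labels, 3), ref, tolerance = 1e-10)
})

test_that("validity indices behave on constructed geometries", {
  withr::local_seed(13)
  tight <- rbind(
    matrix(stats::runif(40, 0, 0.25), 20, 2), # L1 diameter ~ 1
    matrix(c(
      stats::runif(20, 10, 10.25),
      stats::runif(20, 0, 0.25)
    ), 20, 2)
  )
  labels <- rep(1:2, each = 20)
  cents <- rbind(
    apply(tight[1:20, ], 2, median),
    apply(tight[21:40, ], 2, median)
  )
  expect_gt(average_silhouette(tight, labels, 2), 0.9)
  di <- as.numeric(dunn_index(tight, labels, 2))
  expect_gt(di, 8)
  expect_lt(davies_bouldin(tight, labels, cents, 2), 0.2)

  overlap <- matrix(rnorm(120), 60, 2)
  lab2 <- rep(1:2, 30)
  cents2 <- rbind(
    apply(overlap[lab2 == 1, ], 2, median),
    apply(overlap[lab2 == 2, ], 2, median)
  )
  expect_lt(as.numeric(dunn_index(overlap, lab2, 2)), 0.2)
  expect_gt(davies_bouldin(overlap, lab2, cents2, 2), 1)
})

test_that("degenerate geometries use the documented conventions", {
  # all points identical: silhouette 0 by the a = b = 0 convention
  x <- matrix(1, 6, 2)
  labels <- rep(1:2, 3)
  expect_equal(average_silhouette(x, labels, 2), 0)
  # zero diameter with positive separation: Dunn capped at 1e6
  x2 <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  expect_equal(as.numeric(dunn_index(x2, rep(1:2, each = 3), 2)), 1e6)
  # coincident centroids cap the DB ratio with a warning
  expect_warning(
    db <- davies_bouldin(
      matrix(rnorm(20), 10, 2), rep(1:2, 5),
      matrix(1, 2, 2), 2
    ),
    "Coincident"
  )
  expect_gte(db, 1e5)
})

test_that("MPFC is CS * AS * DI / DB", {
  expect_equal(mpfc(10, 0.5, 2, 0.8), 12.5)
  expect_equal(mpfc(2410, 0, 1.5, 1.2), 0)
  expect_equal(mpfc(2410, 0.4, 1.5, 1.2), 1205)
  expect_error(mpfc(10, 0.5, 2, 0), "positive")
  expect_error(mpfc(10, 0.5, 2, -1), "positive")
})

test_that("indices are invariant to relabeling the clusters", {
  withr::local_seed(6)
  x <- matrix(rnorm(60), 20, 3)
  labels <- sample(1:3, 20, replace = TRUE)
  labels[1:3] <- 1:3
  perm <- c(3L, 1L, 2L)
  relab <- perm[labels]
  cents <- do.call(rbind, lapply(1:3, function(c) {
    apply(x[labels == c, , drop = FALSE], 2, median)
  }))
  cents_relab <- do.call(rbind, lapply(1:3, function(c) {
    apply(x[relab == c, , drop = FALSE], 2, median)
  }))
  expect_equal(average_silhouette(x, labels, 3), average_silhouette(x, relab, 3))
  expect_equal(
    as.numeric(dunn_index(x, labels, 3)),
    as.numeric(dunn_index(x, relab, 3))
  )
  expect_equal(
    davies_bouldin(x, labels, cents, 3),
    davies_bouldin(x, relab, cents_relab, 3)
  )
})

test_that("select_k recovers the number of well-separated clouds", {
  withr::local_seed(41)
  x <- rbind(
    matrix(rnorm(60, 0, 0.3), 30, 2),
    matrix(rnorm(60, 6, 0.3), 30, 2),
    matrix(c(rnorm(30, 12, 0.3), rnorm(30, 0, 0.3)), 30, 2)
  )
  sel <- select_k(x, k_range = 2:5, n_init = 10, seed = 3)
  expect_equal(sel$k_opt, 3)
  expect_equal(nrow(sel$quality), 4)
  expect_equal(sel$model$k, 3)
})

test_that("MPFC decays with k on a structureless high-dimensional cloud", {
  # in the feature regime of windowed FC (hundreds of dimensions) the
  # validity indices concentrate and the CS penalty dominates
  withr::local_seed(52)
  x <- matrix(rnorm(800 * 50), 800, 50)
  sel <- select_k(x, k_range = 2:6, n_init = 10, seed = 5)
  m <- sel$quality$mpfc[sel$quality$k >= 3]
  expect_true(all(diff(m) < 0))
})
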