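two_block <- function(within = 1, between = 0, n_per = 3) {
  m <- rbind(
    cbind(
      matrix(within, n_per, n_per),
      matrix(between, n_per, n_per)
    ),
    cbind(
      matrix(between, n_per, n_per),
      matrix(within, n_per, n_per)
    )
  )
  diag(m) <- 0
  m
}

test_that("signed quality function matches the direct definition", {
  withr::local_seed(14)
  for (rep in 1:5) {
    w <- matrix(rnorm(49), 7, 7)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    part <- sample(1:3, 7, replace = TRUE)
    expect_equal(
      modularity_signed(w, part),
      direct_signed_q(w, part),
      tolerance = 1e-12
    )
    expect_equal(
      modularity_signed(w, part, gamma = 1.3),
      direct_signed_q(w, part, gamma = 1.3),
      tolerance = 1e-12
    )
  }
})

test_that("Louvain recovers a perfect two-block partition at the global optimum", {
  m <- two_block(within = 1, between = 0)
  res <- louvain_modularity(m, n_runs = 20, seed = 1)
  expect_equal(res$q, 0.5, tolerance = 1e-12) # hand-derived for this matrix
  expect_equal(res$q, brute_max_q(m)$q, tolerance = 1e-9)
  expect_equal(length(unique(res$partition[1:3])), 1)
  expect_equal(length(unique(res$partition[4:6])), 1)
  expect_false(res$partition[1] == res$partition[4])

  # anti-correlated between-blocks increases Q under the signed quality
  m_neg <- two_block(within = 1, between = -1)
  res_neg <- louvain_modularity(m_neg, n_runs = 20, seed = 1)
  expect_gt(res_neg$q, res$q)
  expect_equal(res_neg$q, brute_max_q(m_neg)$q, tolerance = 1e-9)
})

test_that("uniform positive coupling collapses to one module with Q ~ 0", {
  m <- matrix(1, 6, 6)
  diag(m) <- 0
  res <- louvain_modularity(m, n_runs = 10, seed = 2)
  expect_equal(res$n_modules, 1)
  expect_equal(res$q, 0, tolerance = 1e-12)
})

test_that("all-zero connectivity yields Q = 0 and a single module", {
  res <- louvain_modularity(matrix(0, 5, 5), n_runs = 5, seed = 1)
  expect_equal(res$q, 0)
  expect_equal(res$partition, rep(1L, 5))
})

test_that("Louvain attains the exhaustive-search optimum on signed graphs", {
  withr::local_seed(33)
  for (rep in 1:6) {
    n <- sample(6:8, 1)
    w <- matrix(rnorm(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    got <- louvain_modularity(w, n_runs = 25, seed = rep)
    want <- brute_max_q(w)
    expect_equal(got$q, want$q, tolerance = 1e-9)
  }
})

test_that("negative weights can be zeroed via the config switch", {
  m <- two_block(within = 1, between = -1)
  m_zeroed <- two_block(within = 1, between = 0)
  a <- louvain_modularity(m, n_runs = 10, seed = 3, negative_weights = "zero")
  b <- louvain_modularity(m_zeroed, n_runs = 10, seed = 3)
  expect_equal(a$q, b$q, tolerance = 1e-12)
})

test_that("matrix validation rejects asymmetry and non-zero diagonals", {
  m <- matrix(rnorm(16), 4, 4)
  expect_error(louvain_modularity(m), "symmetric")
  m2 <- (m + t(m)) / 2
  expect_error(louvain_modularity(m2), "Diagonal")
})

test_that("within/between network FC are plain block means", {
  p <- toy_parcellation() # A = {a1,a2,a3}, B = {b1,b2}
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  m[4, 5] <- m[5, 4] <- 0.5
  between <- rbind(c(0.1, 0.3), c(0.1, 0.3), c(0.1, 0.3))
  m[1:3, 4:5] <- between
  m[4:5, 1:3] <- t(between)
  expect_equal(within_network_fc(m, "A", p), 0.4)
  expect_equal(within_network_fc(m, "B", p), 0.5)
  expect_equal(between_network_fc(m, "A", p), 0.2)
  expect_equal(between_network_fc(m, "B", p), 0.2)
  expect_error(within_network_fc(m, "C", p), "network")
})

test_that("system segregation matches the (WNFC - BNFC)/WNFC form", {
  p <- toy_parcellation()
  m <- matrix(0.2, 5, 5)
  m[1:3, 1:3] <- 0.6
  m[4:5, 4:5] <- 0.6
  diag(m) <- 0
  expect_equal(
    as.numeric(system_segregation(m, p)),
    (0.6 - 0.2) / 0.6,
    tolerance = 1e-12
  )
  # zero between-network FC: perfect segregation
  m2 <- m
  m2[1:3, 4:5] <- 0
  m2[4:5, 1:3] <- 0
  expect_equal(as.numeric(system_segregation(m2, p)), 1)
  # equal within and between: zero segregation
  m3 <- matrix(0.4, 5, 5)
  diag(m3) <- 0
  expect_equal(as.numeric(system_segregation(m3, p)), 0)
})

test_that("networks with non-positive WNFC are excluded with a warning", {
  p <- toy_parcellation()
  m <- matrix(0.1, 5, 5)
  m[1:3, 1:3] <- 0.5
  m[4:5, 4:5] <- -0.2 # network B has negative WNFC
  diag(m) <- 0
  expect_warning(s <- system_segregation(m, p), "non-positive WNFC")
  expect_equal(attr(s, "n_excluded"), 1)
  expect_equal(as.numeric(s), (0.5 - 0.1) / 0.5, tolerance = 1e-12)
})

test_that("segregation is scale invariant and monotone in between-network FC", {
  p <- default_parcellation()
  z <- fisher_z(default_state_covariances(p)[[2]] - diag(30))
  s1 <- as.numeric(system_segregation(z, p))
  expect_equal(as.numeric(system_segregation(3.7 * z, p)), s1, tolerance = 1e-12)

  nets <- as.character(p$network)
  bump <- 0.02 * outer(nets, nets, "!=")
  expect_lt(as.numeric(system_segregation(z + bump, p)), s1)
})

test_that("segregated state beats diffuse state on both graph metrics", {
  p <- default_parcellation()
  covs <- default_state_covariances(p)
  z1 <- fisher_z(covs[[1]] - diag(30))
  z2 <- fisher_z(covs[[2]] - diag(30))
  q1 <- louvain_modularity(z1, n_runs = 30, seed = 4)$q
  q2 <- louvain_modularity(z2, n_runs = 30, seed = 4)$q
  expect_gt(q1, q2)
  expect_gt(
    suppressWarnings(as.numeric(system_segregation(z1, p))),
    suppressWarnings(as.numeric(system_segregation(z2, p)))
  )
})

test_that("graph_metrics annotates a fc list-column table", {
  p <- toy_parcellation()
  m <- matrix(0.2, 5, 5)
  m[1:3, 1:3] <- 0.6
  m[4:5, 4:5] <- 0.6
  diag(m) <- 0
  tab <- tibble::tibble(subject = c("s1", "s2"), state = 1L, fc = list(m, 2 * m))
  out <- graph_metrics(tab, p, n_runs = 10, seed = 1)
  expect_equal(names(out), c(
    "subject", "state", "fc", "modularity",
    "n_modules", "segregation", "n_networks_excluded"
  ))
  expect_equal(out$segregation[1], out$segregation[2], tolerance = 1e-12)
})
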