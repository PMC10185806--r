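test_that("default state covariances have the designed block structure", {
  p <- default_parcellation()
  covs <- default_state_covariances(p)
  s1 <- covs[[1]]
  s2 <- covs[[2]]
  nets <- as.character(p$network)
  same <- outer(nets, nets, "==") & !diag(30)
  expect_equal(dim(s1), c(30, 30))
  expect_equal(diag(s1), rep(1, 30), ignore_attr = TRUE)
  # within-network coupling exceeds between-network coupling in both states
  expect_gt(mean(s1[same]), mean(s1[!same & !diag(30)]))
  expect_gt(mean(s2[same]), mean(s2[!same & !diag(30)]))
  # segregated state has anti-correlations, diffuse state has none
  expect_lt(min(s1), -0.1)
  expect_gte(min(s2), 0)
  # both PSD
  expect_gte(min(eigen(s1, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_gte(min(eigen(s2, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("zero block values give the identity covariance", {
  p <- default_parcellation()
  covs <- default_state_covariances(
    p,
    within_r = 0, anti_r = 0, set_r = 0,
    diffuse_within_r = 0, diffuse_between_r = 0
  )
  expect_equal(covs[[1]], diag(30), ignore_attr = TRUE)
  expect_equal(covs[[2]], diag(30), ignore_attr = TRUE)
})

test_that("segregated state scores higher system segregation by construction", {
  p <- default_parcellation()
  covs <- default_state_covariances(p)
  z1 <- fisher_z(covs[[1]] - diag(30))
  z2 <- fisher_z(covs[[2]] - diag(30))
  expect_gt(
    suppressWarnings(system_segregation(z1, p)),
    suppressWarnings(system_segregation(z2, p))
  )
})

test_that("non-repairable covariances are rejected", {
  p <- default_parcellation()
  expect_error(
    default_state_covariances(p, within_r = 0.9, anti_r = -0.9, set_r = -0.9),
    "repair"
  )
})

test_that("Markov sequences start at and converge to the stationary law", {
  # absorbing chain is constant
  absorbing <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(simulate_state_sequence(absorbing, 50, 3), rep(1L, 50))

  # symmetric chain: occupancy ~ 0.5 within 3 binomial SEs at n = 10,000
  sym <- matrix(0.5, 2, 2)
  s <- simulate_state_sequence(sym, 10000, 11)
  expect_lt(abs(mean(s == 1) - 0.5), 3 * sqrt(0.25 / 10000))

  # asymmetric chain with pi = (0.3, 0.7); autocorrelated, so the binomial
  # SE is inflated by the chain factor sqrt((1+lambda)/(1-lambda)), where
  # lambda = 1 - (p12 + p21) = 0.7 is the second eigenvalue
  asym <- matrix(c(0.79, 0.21, 0.09, 0.91), 2, 2, byrow = TRUE)
  pi_ <- stationary_distribution(asym)
  expect_equal(pi_, c(0.3, 0.7), tolerance = 1e-12)
  s2 <- simulate_state_sequence(asym, 10000, 12)
  se <- sqrt(0.3 * 0.7 / 10000) * sqrt((1 + 0.7) / (1 - 0.7))
  expect_lt(abs(mean(s2 == 1) - 0.3), 3 * se)

  expect_error(
    simulate_state_sequence(matrix(c(0.5, 0.4, 0.5, 0.5), 2), 10, 1)
  )
})

test_that("subject simulation is deterministic and has the declared shape", {
  spec <- cohort_spec(n_subjects = c(1, 1), n_volumes = 260, seed = 5)
  a <- simulate_subject(spec, "neglect", 1)
  b <- simulate_subject(spec, "neglect", 1)
  expect_identical(a, b)
  expect_equal(dim(a$timeseries), c(260, 33)) # subject, run, volume + 30 ROIs
  expect_equal(nrow(a$truth), 260)
  expect_true(all(a$truth$state %in% 1:2))
  # different subject index gives different data
  c_ <- simulate_subject(spec, "neglect", 2)
  expect_false(isTRUE(all.equal(a$timeseries$DMN_PCC, c_$timeseries$DMN_PCC)))
})

test_that("noise-free single-state samples recover the state correlation", {
  spec <- cohort_spec(
    n_subjects = c(1, 1), n_volumes = 50000,
    observation_noise_sd = 0,
    transitions = list(
      neglect = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
      non_neglect = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
    ),
    seed = 17
  )
  sub <- simulate_subject(spec, "neglect", 1)
  x <- as.matrix(sub$timeseries[spec$parcellation$roi])
  truth <- stats::cov2cor(spec$state_covariances[[1]])
  expect_lt(max(abs(stats::cor(x) - truth)), 0.02)
})

test_that("CoC scores follow the linear severity model", {
  f <- c(0.2, 0.5, 0.9)
  s0 <- generate_coc_scores(f, baseline = 0.05, slope = 0, noise_sd = 0, seed = 1)
  expect_equal(s0$coc_bells, rep(0.05, 3))
  expect_equal(s0$coc_letter, rep(0.05, 3))

  s1 <- generate_coc_scores(f, baseline = 0.05, slope = 0.4, noise_sd = 0, seed = 1)
  expect_equal(stats::cor(s1$coc_bells, f, method = "spearman"), 1)

  cohort <- simulate_cohort(cohort_spec(seed = 23))
  frac2 <- cohort$truth |>
    dplyr::group_by(subject) |>
    dplyr::summarise(f = mean(state == 2))
  joined <- dplyr::left_join(cohort$behavior, frac2, by = "subject")
  expect_gt(stats::cor(joined$coc_bells, joined$f, method = "spearman"), 0)
  # neglect-like group calibrated to mostly exceed the clinical cut-offs
  flag <- classify_neglect(joined$coc_bells, joined$coc_letter)
  expect_gte(mean(flag[joined$group == "neglect"]), 0.8)
})

test_that("majority-vote window truth handles ties toward the earlier state", {
  truth <- tibble::tibble(
    subject = "s1", run = 1L, volume = 1:6,
    state = c(1L, 1L, 2L, 2L, 2L, 1L)
  )
  lab <- truth_window_labels(truth, window_length = 4, step = 1)
  # windows: 1122 -> tie, earlier state 1; 1222 -> 2; 2221 -> 2
  expect_equal(lab$state, c(1L, 2L, 2L))
  expect_equal(lab$pure, c(FALSE, FALSE, FALSE))

  pure <- tibble::tibble(
    subject = "s1", run = 1L, volume = 1:5,
    state = rep(2L, 5)
  )
  lab2 <- truth_window_labels(pure, window_length = 4, step = 1)
  expect_equal(lab2$state, c(2L, 2L))
  expect_true(all(lab2$pure))
})

test_that("derived per-subject seeds are valid 32-bit integers and distinct", {
  seeds <- outer(1:20, 1:3, function(i, r) subject_seed(20230502L, i, r))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_equal(anyDuplicated(as.vector(seeds)), 0L)
  # reproducible in isolation
  expect_identical(subject_seed(1L, 5L, 2L), subject_seed(1L, 5L, 2L))
})

test_that("cohort spec validates transitions and covariances", {
  expect_error(
    cohort_spec(transitions = list(
      neglect = matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2),
      non_neglect = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
    )),
    "stochastic"
  )
  bad_cov <- default_state_covariances()
  bad_cov[[1]][1, 2] <- 5
  expect_error(cohort_spec(state_covariances = bad_cov), "symmetric")
})
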