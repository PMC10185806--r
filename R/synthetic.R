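#' Specification of a synthetic state-switching cohort
#'
#' Describes a cohort of subjects whose ROI time series alternate between
#' latent covariance states according to a first-order Markov chain, with
#' group-specific transition matrices. Defaults emulate a 20-subject stroke
#' cohort (11 "neglect"-like, 9 "non-neglect"-like), 260 volumes per run at
#' TR = 1.714 s, 30 ROIs in 7 networks, and two latent states: one
#' modular/segregated (strong within-network coupling, task-positive vs
#' task-negative anti-correlation) and one weakly coupled/diffuse. The
#' neglect-like group preferentially occupies the diffuse state (stationary
#' occupancy about 0.65) and the control-like group the segregated state
#' (about 0.65), a 0.3 occupancy gap.
#'
#' @param n_subjects Integer pair: subjects in the (neglect-like,
#'   control-like) groups.
#' @param n_volumes Volumes per run.
#' @param tr_seconds Repetition time in seconds.
#' @param n_runs Runs per subject (windowing never crosses run boundaries).
#' @param parcellation ROI/network scheme; default [default_parcellation()].
#' @param state_covariances List of N x N positive-semidefinite matrices, one
#'   per latent state; default [default_state_covariances()]. State 1 must be
#'   the segregated state, state 2 the diffuse state.
#' @param transitions Named list of row-stochastic transition matrices, one
#'   per group (`neglect`, `non_neglect`).
#' @param observation_noise_sd Isotropic Gaussian noise added to every
#'   volume (default 0.4, i.e. noise variance about 14 percent of signal
#'   variance).
#' @param coc Parameters of the behavioral score generator; see
#'   [generate_coc_scores()].
#' @param seed Master seed; all per-subject/per-run randomness derives from
#'   it (see [subject_seed()]).
#' @return A list of class `dfc_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(11L, 9L),
                        n_volumes = 260L,
                        tr_seconds = 1.714,
                        n_runs = 1L,
                        parcellation = default_parcellation(),
                        state_covariances = default_state_covariances(parcellation),
                        transitions = default_transitions(),
                        observation_noise_sd = 0.4,
                        coc = list(baseline = -0.1, slope = 0.4, noise_sd = 0.03),
                        seed = 20230502L) {
  stopifnot(
    length(n_subjects) == 2, all(n_subjects >= 1),
    n_volumes >= 2, tr_seconds > 0, n_runs >= 1,
    length(state_covariances) >= 2,
    observation_noise_sd >= 0
  )
  n <- nrow(parcellation)
  for (s in state_covariances) {
    stopifnot(is.matrix(s), nrow(s) == n, ncol(s) == n)
    if (max(abs(s - t(s))) > 1e-8) abort("State covariances must be symmetric.")
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("State covariances must be positive semidefinite.")
    }
  }
  k <- length(state_covariances)
  for (p in transitions) {
    stopifnot(is.matrix(p), nrow(p) == k, ncol(p) == k)
    if (max(abs(rowSums(p) - 1)) > 1e-10 || any(p < 0)) {
      abort("Transition matrices must be row-stochastic.")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_volumes = as.integer(n_volumes),
      tr_seconds = tr_seconds,
      n_runs = as.integer(n_runs),
      parcellation = parcellation,
      state_covariances = state_covariances,
      transitions = transitions,
      observation_noise_sd = observation_noise_sd,
      coc = coc,
      seed = as.integer(seed)
    ),
    class = "dfc_cohort_spec"
  )
}

#' @export
print.dfc_cohort_spec <- function(x, ...) {
  cat(
    "<dfc_cohort_spec> ", sum(x$n_subjects), " subjects (",
    x$n_subjects[1], " neglect-like / ", x$n_subjects[2], " control-like), ",
    x$n_runs, " run(s) x ", x$n_volumes, " volumes, ",
    length(x$state_covariances), " latent states, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Default group-specific Markov transition matrices
#'
#' Sticky two-state chains whose stationary occupancy of the segregated
#' state (state 1) is 0.35 for the neglect-like group and 0.65 for the
#' control-like group — a 0.3 gap in diffuse-state occupancy, in the
#' direction of the empirical group difference. Switch rates (0.0325 out of
#' the segregated state, 0.0175 out of the diffuse state, mirrored across
#' groups) put the mean dwell at roughly 31 and 57 volumes (53 and 98 s at
#' TR = 1.714 s), comfortably above the 20-TR analysis window — a
#' prerequisite for sliding-window state detection, and in the range
#' reported for resting-state connectivity states.
#'
#' @return Named list of 2 x 2 row-stochastic matrices.
#' @export
default_transitions <- function() {
  list(
    neglect = matrix(
      c(1 - 0.0325, 0.0325, 0.0175, 1 - 0.0175), 2, 2,
      byrow = TRUE
    ),
    non_neglect = matrix(
      c(1 - 0.0175, 0.0175, 0.0325, 1 - 0.0325), 2, 2,
      byrow = TRUE
    )
  )
}

#' Construct block-structured state correlation matrices
#'
#' Builds the two default latent-state matrices from a parcellation:
#' * State 1 (segregated): within-network correlation `within_r` (0.6),
#'   anti-correlation `anti_r` (-0.3) between the task-positive set
#'   \{DAN, SMN, CON\} and the task-negative set \{FPN, DMN\}, and mild
#'   positive coupling (`set_r`, 0.2) between different networks inside each
#'   of those two sets. Other between-network entries are 0.
#' @param parcellation A [parcellation()]; defaults assume networks named
#'   DAN, SMN, CON, FPN, DMN (others are treated as unaffiliated).
#' @param within_r,anti_r,set_r State-1 block values.
#' @param diffuse_within_r,diffuse_between_r State-2 block values.
#' @details
#' * State 2 (diffuse): weak within-network correlation
#'   `diffuse_within_r` (0.2) and `diffuse_between_r` (0.1) everywhere else.
#'
#' Both matrices have unit diagonal and are repaired to positive
#' semidefiniteness by clipping negative eigenvalues at a small floor and
#' rescaling to a correlation matrix; non-repairable inputs error.
#' @return List of two N x N correlation matrices (segregated, diffuse).
#' @export
default_state_covariances <- function(parcellation = default_parcellation(),
                                      within_r = 0.6, anti_r = -0.3,
                                      set_r = 0.2,
                                      diffuse_within_r = 0.2,
                                      diffuse_between_r = 0.1) {
  stopifnot(
    abs(within_r) < 1, abs(anti_r) < 1, abs(set_r) < 1,
    abs(diffuse_within_r) < 1, abs(diffuse_between_r) < 1
  )
  nets <- as.character(parcellation$network)
  n <- length(nets)
  same_net <- outer(nets, nets, "==")
  task_pos <- nets %in% c("DAN", "SMN", "CON")
  task_neg <- nets %in% c("FPN", "DMN")
  cross <- outer(task_pos, task_neg, "&") | outer(task_neg, task_pos, "&")
  within_set <- (outer(task_pos, task_pos, "&") | outer(task_neg, task_neg, "&")) &
    !same_net

  s1 <- matrix(0, n, n)
  s1[within_set] <- set_r
  s1[cross] <- anti_r
  s1[same_net] <- within_r
  diag(s1) <- 1

  s2 <- matrix(diffuse_between_r, n, n)
  s2[same_net] <- diffuse_within_r
  diag(s2) <- 1

  lapply(list(s1, s2), function(m) {
    dimnames(m) <- list(parcellation$roi, parcellation$roi)
    repair_psd(m)
  })
}

# Clip eigenvalues below `floor_ev` and rescale to unit diagonal. Errors if
# the repair changes the matrix beyond `max_change`.
repair_psd <- function(m, floor_ev = 1e-6, max_change = 0.2) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor_ev) {
    return(m)
  }
  v <- pmax(e$values, floor_ev)
  r <- e$vectors %*% (v * t(e$vectors))
  r <- stats::cov2cor(r)
  if (max(abs(r - m)) > max_change) {
    abort("Covariance is too far from positive semidefinite to repair.")
  }
  dimnames(r) <- dimnames(m)
  r
}

#' Stationary distribution of a row-stochastic matrix
#' @param p Row-stochastic transition matrix.
#' @return Probability vector pi with `pi %*% p == pi`.
#' @export
stationary_distribution <- function(p) {
  e <- eigen(t(p))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Simulate a first-order Markov state sequence
#'
#' The chain starts from the stationary distribution of `transition`.
#'
#' @param transition Row-stochastic k x k matrix.
#' @param n_volumes Sequence length.
#' @param seed Seed (integer); the draw is deterministic given it.
#' @return Integer vector of states in `1..k`.
#' @export
simulate_state_sequence <- function(transition, n_volumes, seed) {
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-10), all(transition >= 0))
  k <- nrow(transition)
  withr::with_seed(seed, {
    s <- integer(n_volumes)
    s[1] <- sample.int(k, 1, prob = stationary_distribution(transition))
    if (n_volumes > 1) {
      u <- runif(n_volumes - 1)
      cum <- t(apply(transition, 1, cumsum))
      for (t in 2:n_volumes) {
        s[t] <- findInterval(u[t - 1], cum[s[t - 1], ]) + 1L
      }
    }
    s
  })
}

#' Derive a per-subject / per-run seed from the master seed
#'
#' Fixed affine-mod derivation so any single subject/run is reproducible in
#' isolation; results stay below 2^31.
#'
#' @param seed Master seed.
#' @param subject_index Subject number (1-based).
#' @param run Run number (1-based).
#' @return Integer seed.
#' @export
subject_seed <- function(seed, subject_index, run = 1L) {
  as.integer(
    (as.double(seed) + 7919 * subject_index + 104729 * run) %% 2147483647
  )
}

# Draw T x N Gaussian volumes with per-volume state covariances.
draw_states_mvn <- function(states, chols, noise_sd) {
  n <- ncol(chols[[1]])
  t_n <- length(states)
  z <- matrix(rnorm(t_n * n), t_n, n)
  x <- matrix(0, t_n, n)
  for (s in unique(states)) {
    idx <- states == s
    x[idx, ] <- z[idx, , drop = FALSE] %*% chols[[s]]
  }
  if (noise_sd > 0) x <- x + noise_sd * matrix(rnorm(t_n * n), t_n, n)
  x
}

#' Simulate one subject
#'
#' Each volume is drawn from a zero-mean multivariate normal with the
#' covariance of its latent state plus isotropic observation noise.
#' Deterministic given the cohort spec's master seed and the subject index.
#'
#' @param spec A [cohort_spec()].
#' @param group `"neglect"` or `"non_neglect"` (selects the transition
#'   matrix).
#' @param subject_index 1-based subject number (drives seed derivation).
#' @param subject Subject identifier string.
#' @return List with `timeseries` (tibble: `subject`, `run`, `volume`, ROI
#'   columns) and `truth` (tibble: `subject`, `run`, `volume`, `state`).
#' @export
simulate_subject <- function(spec, group, subject_index,
                             subject = sprintf("sub-%02d", subject_index)) {
  stopifnot(inherits(spec, "dfc_cohort_spec"))
  if (!group %in% names(spec$transitions)) {
    abort(paste0("Unknown group: ", group))
  }
  chols <- lapply(spec$state_covariances, chol)
  rois <- spec$parcellation$roi
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    s_run <- subject_seed(spec$seed, subject_index, r)
    states <- simulate_state_sequence(
      spec$transitions[[group]], spec$n_volumes, s_run
    )
    x <- withr::with_seed(
      subject_seed(spec$seed, subject_index, r + 1000L),
      draw_states_mvn(states, chols, spec$observation_noise_sd)
    )
    colnames(x) <- rois
    list(
      timeseries = dplyr::bind_cols(
        tibble(subject = subject, run = r, volume = seq_len(spec$n_volumes)),
        as_tibble(x)
      ),
      truth = tibble(
        subject = subject, run = r,
        volume = seq_len(spec$n_volumes), state = states
      )
    )
  })
  list(
    timeseries = bind_rows(purrr::map(runs, "timeseries")),
    truth = bind_rows(purrr::map(runs, "truth"))
  )
}

#' Generate behavioral cancellation scores from diffuse-state occupancy
#'
#' Center-of-cancellation (CoC) scores increase linearly with the fraction
#' of time spent in the diffuse state:
#' `CoC = baseline + slope * fraction + N(0, noise_sd^2)`, truncated at 0.
#' With the defaults (baseline -0.1, slope 0.4, noise sd 0.03) subjects whose
#' diffuse-state occupancy is near 0.65 mostly exceed the clinical cut-offs
#' (0.081 Bells / 0.083 Letter) while subjects near 0.35 mostly stay below.
#'
#' @param fraction_diffuse Per-subject fraction of volumes in the diffuse
#'   state, in `[0, 1]`.
#' @param baseline,slope,noise_sd Linear model parameters.
#' @param seed Seed for the score noise.
#' @return Tibble with columns `coc_bells`, `coc_letter`.
#' @export
generate_coc_scores <- function(fraction_diffuse, baseline = -0.1,
                                slope = 0.4, noise_sd = 0.03, seed = 1L) {
  stopifnot(all(fraction_diffuse >= 0 & fraction_diffuse <= 1))
  n <- length(fraction_diffuse)
  withr::with_seed(seed, {
    mk <- function() {
      pmax(0, baseline + slope * fraction_diffuse + rnorm(n, 0, noise_sd))
    }
    tibble(coc_bells = mk(), coc_letter = mk())
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates every subject's time series, volume-level latent-state ground
#' truth, and a behavior table whose CoC scores are driven by each subject's
#' realized diffuse-state occupancy. The returned time series emulate
#' post-denoising residual BOLD (the generator has no temporal spectral
#' model), so they enter windowing without further band-pass filtering.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `dfc_cohort`: `timeseries` (tibble), `behavior`
#'   (tibble: `subject`, `coc_bells`, `coc_letter`, `group`), `truth`
#'   (tibble: volume-level states), `spec`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(
#'   n_subjects = c(2, 2),
#'   n_volumes = 60, seed = 7
#' ))
#' dplyr::count(cohort$behavior, group)
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "dfc_cohort_spec"))
  groups <- rep(c("neglect", "non_neglect"), spec$n_subjects)
  n_total <- length(groups)
  subs <- purrr::map(seq_len(n_total), function(i) {
    simulate_subject(spec, groups[i], i)
  })
  truth <- bind_rows(purrr::map(subs, "truth"))
  frac_diffuse <- truth %>%
    group_by(.data$subject) %>%
    summarise(fraction = mean(.data$state == 2L), .groups = "drop")
  scores <- generate_coc_scores(
    frac_diffuse$fraction,
    baseline = spec$coc$baseline, slope = spec$coc$slope,
    noise_sd = spec$coc$noise_sd,
    seed = subject_seed(spec$seed, 0L, 9999L)
  )
  behavior <- dplyr::bind_cols(
    tibble(
      subject = frac_diffuse$subject,
      group = groups[match(
        frac_diffuse$subject,
        sprintf("sub-%02d", seq_len(n_total))
      )]
    ),
    scores
  )
  structure(
    list(
      timeseries = bind_rows(purrr::map(subs, "timeseries")),
      behavior = behavior[, c("subject", "coc_bells", "coc_letter", "group")],
      truth = truth,
      spec = spec
    ),
    class = "dfc_cohort"
  )
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat(
    "<dfc_cohort> ", length(unique(x$timeseries$subject)), " subjects, ",
    x$spec$n_runs, " run(s) x ", x$spec$n_volumes, " volumes, ",
    nrow(x$spec$parcellation), " ROIs\n",
    sep = ""
  )
  invisible(x)
}

#' Majority-vote ground-truth labels for sliding windows
#'
#' A window's true state is the state covering the majority of its volumes;
#' ties break toward the earlier (left-most) state in the window. Windows
#' that span a state switch at all are flagged `pure = FALSE`.
#'
#' @param truth Volume-level truth tibble (`subject`, `run`, `volume`,
#'   `state`) from [simulate_cohort()].
#' @param window_length,step Window geometry matching [sliding_window_fc()].
#' @return Tibble `subject`, `run`, `onset`, `state`, `pure`.
#' @export
truth_window_labels <- function(truth, window_length = 20L, step = 1L) {
  truth %>%
    arrange(.data$subject, .data$run, .data$volume) %>%
    group_by(.data$subject, .data$run) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(lab = purrr::map(.data$data, function(d) {
      s <- d$state
      n_w <- count_windows(length(s), window_length, step)
      onsets <- seq.int(1L, by = step, length.out = n_w)
      st <- integer(n_w)
      pure <- logical(n_w)
      for (w in seq_len(n_w)) {
        seg <- s[onsets[w]:(onsets[w] + window_length - 1L)]
        counts <- table(seg)
        top <- max(counts)
        winners <- as.integer(names(counts)[counts == top])
        # tie toward the state appearing earlier in the window
        st[w] <- seg[seg %in% winners][1]
        pure[w] <- length(counts) == 1L
      }
      tibble(onset = onsets, state = st, pure = pure)
    })) %>%
    select("subject", "run", "lab") %>%
    tidyr::unnest("lab")
}

#' Write a simulated cohort to disk as plain-text files
#'
#' Per-subject/run TSV time series, behavior TSV, parcellation TSV and a
#' JSON ground-truth file — the on-disk cohort layout that the readers in
#' this package consume.
#'
#' @param cohort A `dfc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  cohort$timeseries %>%
    group_by(.data$subject, .data$run) %>%
    dplyr::group_walk(function(d, key) {
      readr::write_tsv(
        d[setdiff(names(d), "volume")],
        file.path(ts_dir, sprintf("%s_run-%d.tsv", key$subject, key$run))
      )
    })
  readr::write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  write_parcellation(cohort$spec$parcellation, file.path(dir, "parcellation.tsv"))
  jsonlite::write_json(
    list(
      seed = cohort$spec$seed,
      states = cohort$truth
    ),
    file.path(dir, "ground_truth.json")
  )
  invisible(dir)
}
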