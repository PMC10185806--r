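#' Fit a brain-state model to windowed FC features
#'
#' Concatenates all subjects' windowed Fisher-z FC vectors in canonical
#' order (subject, then run, then window onset), clusters them with
#' [kmeans_manhattan()] (or scans `k_range` with [select_k()] when `k` is
#' not given) and returns centroids plus per-window state labels.
#'
#' @param wfc Windowed FC tibble from [sliding_window_fc()].
#' @param k Number of states; if `NULL`, selected by the MPFC peak over
#'   `k_range`.
#' @param k_range Candidate k values for MPFC selection (default 2:6).
#' @param n_init Restarts per k.
#' @param seed Integer seed.
#' @param roi_names Optional ROI names for centroid matrices.
#' @param dunn_max_points Passed to [select_k()].
#' @return A list of class `dfc_state_model`: `k`, `centroids` (k x P),
#'   `centroid_matrices` (list of N x N), `assignments` (tibble `subject`,
#'   `run`, `onset`, `state`), `quality` (MPFC table or `NULL`), `cost`,
#'   `distance`, `seed`, `n_init`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = c(2, 2), n_volumes = 60))
#' wfc <- sliding_window_fc(cohort$timeseries)
#' model <- cluster_states(wfc, k = 2, n_init = 5, seed = 1)
#' model$k
#' @export
cluster_states <- function(wfc, k = NULL, k_range = 2:6, n_init = 50L,
                           seed = 20230502L, roi_names = NULL,
                           dunn_max_points = 6000L) {
  if (is.null(roi_names)) roi_names <- attr(wfc$z, "roi_names")
  wfc <- arrange(wfc, .data$subject, .data$run, .data$onset)
  features <- unname(as.matrix(wfc$z))
  quality <- NULL
  if (is.null(k)) {
    sel <- select_k(features, k_range, n_init, seed, dunn_max_points)
    fit <- sel$model
    quality <- sel$quality
    k <- sel$k_opt
  } else {
    fit <- kmeans_manhattan(features, k, n_init = n_init, seed = seed)
  }
  structure(
    list(
      k = as.integer(k),
      centroids = fit$centers,
      centroid_matrices = lapply(
        seq_len(nrow(fit$centers)),
        function(i) unvectorize_upper(fit$centers[i, ], roi_names)
      ),
      assignments = mutate(
        wfc[c("subject", "run", "onset")],
        state = fit$labels
      ),
      quality = quality,
      cost = fit$cost,
      distance = "manhattan",
      seed = as.integer(seed),
      n_init = as.integer(n_init)
    ),
    class = "dfc_state_model"
  )
}

#' @export
print.dfc_state_model <- function(x, ...) {
  occ <- table(x$assignments$state) / nrow(x$assignments)
  cat(
    "<dfc_state_model> k = ", x$k, ", ",
    nrow(x$assignments), " windows, occupancy: ",
    paste(sprintf("state %s %.1f%%", names(occ), 100 * occ), collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Relabel the states of a fitted model
#'
#' @param model A `dfc_state_model`.
#' @param perm Integer permutation: new state `i` is old state `perm[i]`.
#' @return The relabeled model.
#' @export
relabel_states <- function(model, perm) {
  stopifnot(sort(perm) == seq_len(model$k))
  inv <- order(perm)
  model$centroids <- model$centroids[perm, , drop = FALSE]
  model$centroid_matrices <- model$centroid_matrices[perm]
  model$assignments$state <- inv[model$assignments$state]
  model
}

#' Per-subject mean FC matrix of each visited state
#'
#' For every subject and state, the element-wise mean of the subject's
#' windowed Fisher-z matrices assigned to that state — the subject-level
#' "centroid" on which modularity and system segregation are computed.
#' States a subject never visits are absent from the output (not
#' zero-filled).
#'
#' @param wfc Windowed FC tibble from [sliding_window_fc()].
#' @param model A `dfc_state_model` whose assignments cover `wfc`'s windows.
#' @param roi_names Optional ROI names.
#' @return Tibble `subject`, `state`, `n_windows`, `fc` (list of N x N
#'   matrices).
#' @export
subject_state_matrices <- function(wfc, model, roi_names = NULL) {
  if (is.null(roi_names)) roi_names <- attr(wfc$z, "roi_names")
  joined <- wfc %>%
    arrange(.data$subject, .data$run, .data$onset) %>%
    left_join(model$assignments, by = c("subject", "run", "onset"))
  if (anyNA(joined$state)) {
    abort("Model assignments do not cover all windows in `wfc`.")
  }
  joined %>%
    group_by(.data$subject, .data$state) %>%
    summarise(
      n_windows = dplyr::n(),
      fc = list(unvectorize_upper(colMeans(.data$z), .env$roi_names)),
      .groups = "drop"
    )
}

#' Match two sets of state centroids by correlation
#'
#' Greedy one-to-one assignment maximizing the Pearson correlation of
#' centroid upper triangles — used to align states across independent
#' clustering runs (sub-cohorts, or estimate vs ground truth).
#'
#' @param centroids_a,centroids_b Matrices (k x P) of centroid vectors, or
#'   lists of N x N matrices.
#' @return Tibble `state_a`, `state_b`, `correlation`, sorted by `state_a`.
#' @export
match_states <- function(centroids_a, centroids_b) {
  as_mat <- function(x) {
    if (is.list(x)) {
      do.call(rbind, lapply(x, vectorize_upper))
    } else {
      as.matrix(x)
    }
  }
  a <- as_mat(centroids_a)
  b <- as_mat(centroids_b)
  cc <- stats::cor(t(a), t(b))
  ka <- nrow(a)
  kb <- nrow(b)
  pairs <- list()
  used_a <- logical(ka)
  used_b <- logical(kb)
  for (i in seq_len(min(ka, kb))) {
    cc_free <- cc
    cc_free[used_a, ] <- -Inf
    cc_free[, used_b] <- -Inf
    best <- arrayInd(which.max(cc_free), dim(cc))
    pairs[[i]] <- tibble(
      state_a = best[1], state_b = best[2],
      correlation = cc[best[1], best[2]]
    )
    used_a[best[1]] <- TRUE
    used_b[best[2]] <- TRUE
  }
  arrange(bind_rows(pairs), .data$state_a)
}
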