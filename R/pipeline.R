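#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults follow the
#' standard sliding-window protocol for this design: 20-TR windows moved by
#' 1 TR, a 0.029-0.15 Hz band, MPFC scan over k = 2..6 with 50 k-means
#' restarts, signed-Louvain modularity with 100 restarts.
#'
#' @param window_length_tr,step_tr Window geometry in TRs.
#' @param band Band-pass edges in Hz (applied only when the input is not
#'   already filtered).
#' @param k_range Candidate state counts for the MPFC scan; a single value
#'   skips the scan.
#' @param n_init K-means restarts.
#' @param seed Master seed.
#' @param n_louvain Louvain restarts per matrix.
#' @param gamma Louvain resolution.
#' @param negative_weights `"signed"` or `"zero"` handling of negative FC.
#' @param dunn_max_points Subsampling threshold for the Dunn index.
#' @return A list of class `dfc_config`.
#' @export
run_config <- function(window_length_tr = 20L, step_tr = 1L,
                       band = c(0.029, 0.15), k_range = 2:6, n_init = 50L,
                       seed = 20230502L, n_louvain = 100L, gamma = 1,
                       negative_weights = c("signed", "zero"),
                       dunn_max_points = 6000L) {
  negative_weights <- match.arg(negative_weights)
  structure(
    list(
      window_length_tr = as.integer(window_length_tr),
      step_tr = as.integer(step_tr),
      band = band, k_range = as.integer(k_range),
      n_init = as.integer(n_init), seed = as.integer(seed),
      n_louvain = as.integer(n_louvain), gamma = gamma,
      negative_weights = negative_weights,
      dunn_max_points = as.integer(dunn_max_points)
    ),
    class = "dfc_config"
  )
}

#' Run the whole-cohort brain-state analysis
#'
#' Executes the full pipeline on a cohort: (optional) band-pass filter,
#' sliding-window FC, state clustering with MPFC model selection,
#' relabeling of states by descending system segregation of the cohort
#' centroids (so state 1 is the most segregated state), per-subject state
#' matrices, modularity/segregation metrics, fraction/dwell temporal
#' dynamics, and the group/severity statistics. Re-running with the same
#' inputs and config is deterministic.
#'
#' @param timeseries Cohort time-series tibble (`subject`, `run`, `volume`,
#'   ROI columns).
#' @param parcellation A [parcellation()].
#' @param behavior Behavior tibble; `NULL` skips the group statistics.
#' @param config A [run_config()].
#' @param tr_seconds Repetition time in seconds.
#' @param filtered Set `TRUE` when `timeseries` is already band-passed (or
#'   emulates filtered residuals, as [simulate_cohort()] output does).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV/JSON with config/seed provenance.
#' @return A list of class `dfc_run`: `wfc`, `model`, `quality`,
#'   `state_matrices`, `graph`, `temporal`, `stats`, `static`, `config`.
#' @export
run_whole_cohort <- function(timeseries, parcellation, behavior = NULL,
                             config = run_config(), tr_seconds = 1.714,
                             filtered = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "dfc_config"))
  if (!setequal(roi_columns(timeseries), parcellation$roi)) {
    abort("Time-series ROI columns do not match the parcellation.")
  }
  timeseries <- timeseries[c(
    "subject", "run", "volume",
    parcellation$roi
  )]
  if (!filtered) {
    timeseries <- bandpass_filter(
      timeseries, tr_seconds,
      config$band[1], config$band[2]
    )
  }
  wfc <- sliding_window_fc(
    timeseries, config$window_length_tr,
    config$step_tr
  )
  k_range <- config$k_range
  model <- if (length(k_range) == 1) {
    cluster_states(wfc,
      k = k_range, n_init = config$n_init,
      seed = config$seed, roi_names = parcellation$roi
    )
  } else {
    cluster_states(wfc,
      k = NULL, k_range = k_range, n_init = config$n_init,
      seed = config$seed, roi_names = parcellation$roi,
      dunn_max_points = config$dunn_max_points
    )
  }
  # state 1 = most segregated cohort centroid, mirroring the reporting
  # convention for the segregated/diffuse pair
  seg <- vapply(
    model$centroid_matrices,
    function(m) {
      as.numeric(suppressWarnings(system_segregation(m, parcellation)))
    },
    numeric(1)
  )
  model <- relabel_states(model, order(seg, decreasing = TRUE))

  smat <- subject_state_matrices(wfc, model, roi_names = parcellation$roi)
  graph <- graph_metrics(
    smat, parcellation,
    gamma = config$gamma,
    n_runs = config$n_louvain, seed = config$seed,
    negative_weights = config$negative_weights
  )
  temporal <- temporal_metrics(model,
    step_tr = config$step_tr,
    tr_seconds = tr_seconds
  )
  static <- graph_metrics(
    static_fc(wfc, roi_names = parcellation$roi), parcellation,
    gamma = config$gamma, n_runs = config$n_louvain,
    seed = config$seed, negative_weights = config$negative_weights
  )
  stats_out <- NULL
  if (!is.null(behavior)) {
    stats_out <- run_group_analysis(temporal, behavior, graph = graph)
  }
  run <- structure(
    list(
      wfc = wfc, model = model, quality = model$quality,
      state_matrices = smat, graph = graph, temporal = temporal,
      static = static, stats = stats_out, config = config
    ),
    class = "dfc_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.dfc_run <- function(x, ...) {
  cat("<dfc_run> k =", x$model$k, "states over", nrow(x$wfc), "windows\n")
  if (!is.null(x$quality)) {
    cat("MPFC selection:\n")
    print(x$quality)
  }
  invisible(x)
}

#' Run the analysis independently per sub-cohort
#'
#' Splits the cohort by the behavior table's `group` column, runs
#' [run_whole_cohort()] (including an independent MPFC scan) inside each
#' group, matches states across the two groups by centroid correlation,
#' and compares modularity/segregation of matched states across groups with
#' two-sample t-tests.
#'
#' @inheritParams run_whole_cohort
#' @param behavior Behavior tibble with a `group` column of two levels,
#'   each with at least 2 subjects.
#' @return List of class `dfc_subcohort_run`: `runs` (named list of
#'   `dfc_run`), `state_matching` (tibble), `cross_group_tests` (tibble).
#' @export
run_subcohorts <- function(timeseries, parcellation, behavior,
                           config = run_config(), tr_seconds = 1.714,
                           filtered = FALSE) {
  groups <- split(behavior$subject, behavior$group)
  if (length(groups) != 2) abort("`group` must have exactly two levels.")
  if (any(lengths(groups) < 2)) {
    abort("Each sub-cohort needs at least 2 subjects.")
  }
  runs <- purrr::imap(groups, function(subs, g) {
    run_whole_cohort(
      filter(timeseries, .data$subject %in% subs),
      parcellation,
      behavior = NULL, config = config,
      tr_seconds = tr_seconds, filtered = filtered
    )
  })
  g1 <- names(runs)[1]
  g2 <- names(runs)[2]
  matching <- match_states(
    runs[[g1]]$model$centroids,
    runs[[g2]]$model$centroids
  )
  cross <- bind_rows(purrr::map(seq_len(nrow(matching)), function(i) {
    sa <- matching$state_a[i]
    sb <- matching$state_b[i]
    bind_rows(purrr::map(c("modularity", "segregation"), function(col) {
      x <- filter(runs[[g1]]$graph, .data$state == sa)[[col]]
      y <- filter(runs[[g2]]$graph, .data$state == sb)[[col]]
      if (length(x) < 2 || length(y) < 2) {
        return(NULL)
      }
      mutate(ttest_two_sample(x, y),
        metric = col,
        state_a = sa, state_b = sb,
        group_a = g1, group_b = g2
      )
    }))
  }))
  structure(
    list(
      runs = runs, state_matching = matching,
      cross_group_tests = cross
    ),
    class = "dfc_subcohort_run"
  )
}

#' Write a run's result tables to a directory
#'
#' TSV for tabular results, JSON for the config and state centroids; every
#' file set is accompanied by a `provenance.json` carrying the config, the
#' seed, a content hash of the config, and the package version.
#'
#' @param run A `dfc_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(run$config)
  jsonlite::write_json(
    list(
      config = cfg,
      config_hash = rlang::hash(cfg),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("dfcstates"))
    ),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE
  )
  readr::write_tsv(run$model$assignments, file.path(dir, "state_labels.tsv"))
  readr::write_tsv(run$temporal, file.path(dir, "temporal_metrics.tsv"))
  readr::write_tsv(
    select(run$graph, -"fc"),
    file.path(dir, "graph_metrics.tsv")
  )
  readr::write_tsv(
    select(run$static, -"fc"),
    file.path(dir, "static_metrics.tsv")
  )
  if (!is.null(run$quality)) {
    readr::write_tsv(run$quality, file.path(dir, "cluster_quality.tsv"))
  }
  jsonlite::write_json(
    purrr::map(run$model$centroid_matrices, ~ round(unclass(.x), 8)),
    file.path(dir, "state_centroids.json")
  )
  if (!is.null(run$stats)) {
    jsonlite::write_json(
      purrr::map(
        unclass(run$stats)[!vapply(run$stats, is.null, logical(1))],
        ~ as.list(.x)
      ),
      file.path(dir, "group_stats.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
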