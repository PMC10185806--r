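#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted state model
#'
#' One row per state with occupancy and centroid summaries.
#'
#' @param x A `dfc_state_model`.
#' @param ... Unused.
#' @return Tibble `state`, `n_windows`, `occupancy`, `mean_abs_z`.
#' @export
tidy.dfc_state_model <- function(x, ...) {
  occ <- tabulate(x$assignments$state, x$k)
  tibble(
    state = seq_len(x$k),
    n_windows = occ,
    occupancy = occ / sum(occ),
    mean_abs_z = vapply(
      seq_len(x$k),
      function(i) mean(abs(x$centroids[i, ])),
      numeric(1)
    )
  )
}

#' @rdname tidy.dfc_state_model
#' @return `glance`: one-row tibble `k`, `n_windows`, `n_subjects`, `cost`,
#'   `distance`, `seed`.
#' @export
glance.dfc_state_model <- function(x, ...) {
  tibble(
    k = x$k,
    n_windows = nrow(x$assignments),
    n_subjects = length(unique(x$assignments$subject)),
    cost = x$cost,
    distance = x$distance,
    seed = x$seed
  )
}

#' Tidy an MPFC model-selection scan
#'
#' @param x A `dfc_k_selection`.
#' @param ... Unused.
#' @return The quality tibble (one row per candidate k).
#' @export
tidy.dfc_k_selection <- function(x, ...) x$quality

#' @rdname tidy.dfc_k_selection
#' @export
glance.dfc_k_selection <- function(x, ...) {
  tibble(
    k_opt = x$k_opt,
    mpfc_max = max(x$quality$mpfc),
    k_scanned = nrow(x$quality)
  )
}

#' Tidy a whole-cohort run
#'
#' @param x A `dfc_run`.
#' @param ... Unused.
#' @return Per-subject-per-state tibble joining temporal and graph metrics.
#' @export
tidy.dfc_run <- function(x, ...) {
  left_join(
    x$temporal,
    select(x$graph, -"fc"),
    by = c("subject", "state")
  )
}

#' @rdname tidy.dfc_run
#' @export
glance.dfc_run <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$model),
    tibble(
      window_length_tr = x$config$window_length_tr,
      step_tr = x$config$step_tr
    )
  )
}
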