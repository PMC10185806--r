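#' Fraction of windows spent in each state
#'
#' @param labels Integer window-label sequence (values in `1..k`).
#' @param k Number of states.
#' @return Numeric vector of length k summing to 1.
#' @examples
#' fraction_times(c(1, 1, 1, 2, 2), k = 2) # 0.6 0.4
#' @export
fraction_times <- function(labels, k) {
  stopifnot(length(labels) >= 1, all(labels >= 1), all(labels <= k))
  tabulate(labels, k) / length(labels)
}

#' Mean dwell time per state
#'
#' Dwell time is the mean length of maximal contiguous runs of a state in
#' the window-label sequence, in window units. Acquisition-run boundaries
#' terminate a dwell run (a state held across two runs counts as two
#' visits). Unvisited states get dwell 0 and 0 visits.
#'
#' @param labels Integer window labels in `1..k`.
#' @param k Number of states.
#' @param run Optional vector of acquisition-run identifiers aligned with
#'   `labels`; changes in `run` break dwell runs.
#' @return Tibble `state`, `dwell_windows`, `n_visits`.
#' @examples
#' dwell_times(c(1, 1, 2, 1, 1, 1, 2, 2), k = 2)
#' @export
dwell_times <- function(labels, k, run = NULL) {
  stopifnot(length(labels) >= 1, all(labels >= 1), all(labels <= k))
  if (is.null(run)) run <- rep(1L, length(labels))
  stopifnot(length(run) == length(labels))
  brk <- c(TRUE, labels[-1] != labels[-length(labels)] |
    run[-1] != run[-length(run)])
  visit_id <- cumsum(brk)
  lens <- tabulate(visit_id)
  visit_state <- labels[brk]
  dw <- vapply(seq_len(k), function(s) {
    ls <- lens[visit_state == s]
    if (length(ls)) mean(ls) else 0
  }, numeric(1))
  nv <- tabulate(visit_state, k)
  tibble(state = seq_len(k), dwell_windows = dw, n_visits = as.integer(nv))
}

#' Per-subject temporal dynamics of the brain states
#'
#' Fraction time (share of a subject's windows assigned to each state) and
#' mean dwell time (window units, with an optional conversion to seconds via
#' `step * TR`) for every subject in a state model.
#'
#' @param model A `dfc_state_model` (its `assignments` drive everything).
#' @param step_tr Window step in TRs (for the seconds conversion).
#' @param tr_seconds Repetition time in seconds; if `NULL`, no seconds
#'   column is produced.
#' @return Tibble `subject`, `state`, `fraction_time`, `fraction_pct`,
#'   `dwell_windows`, `n_visits` and (when `tr_seconds` is given)
#'   `dwell_seconds`.
#' @export
temporal_metrics <- function(model, step_tr = 1L, tr_seconds = NULL) {
  k <- model$k
  out <- model$assignments %>%
    arrange(.data$subject, .data$run, .data$onset) %>%
    group_by(.data$subject) %>%
    dplyr::group_modify(function(d, key) {
      ft <- fraction_times(d$state, k)
      dw <- dwell_times(d$state, k, run = d$run)
      mutate(dw,
        fraction_time = ft[.data$state],
        fraction_pct = 100 * .data$fraction_time
      )
    }) %>%
    ungroup() %>%
    select(
      "subject", "state", "fraction_time", "fraction_pct",
      "dwell_windows", "n_visits"
    )
  if (!is.null(tr_seconds)) {
    out <- mutate(out, dwell_seconds = .data$dwell_windows * step_tr * tr_seconds)
  }
  out
}
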