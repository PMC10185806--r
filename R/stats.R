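#' Classify spatial neglect from Center-of-Cancellation scores
#'
#' A subject is classified as neglect when the CoC score is strictly above
#' the normative cut-off in at least one cancellation test (0.081 for the
#' Bells test, 0.083 for the Letter test). A missing score classifies on the
#' available one; both missing is an error.
#'
#' @param coc_bells,coc_letter Numeric CoC scores (NA allowed, not both).
#' @param cutoffs Length-2 cut-offs for (Bells, Letter).
#' @return Logical vector.
#' @examples
#' classify_neglect(c(0.5, 0.05, 0.081), c(0.01, 0.05, 0.083))
#' @export
classify_neglect <- function(coc_bells, coc_letter,
                             cutoffs = c(0.081, 0.083)) {
  stopifnot(length(coc_bells) == length(coc_letter), length(cutoffs) == 2)
  if (any(is.na(coc_bells) & is.na(coc_letter))) {
    abort("At least one CoC score is required per subject.")
  }
  b <- !is.na(coc_bells) & coc_bells > cutoffs[1]
  l <- !is.na(coc_letter) & coc_letter > cutoffs[2]
  b | l
}

#' Two-sample pooled-variance t-test
#'
#' Student's t with pooled variance and `df = n_x + n_y - 2`, two-tailed.
#' The sign convention is `x - y` (group 1 minus group 2).
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `form`.
#' @export
ttest_two_sample <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  fit <- t.test(x, y, var.equal = TRUE)
  tibble(
    t = unname(fit$statistic), df = unname(fit$parameter),
    p = fit$p.value, mean_diff = mean(x) - mean(y),
    form = "pooled_two_sample"
  )
}

#' Pooled-variance t-test from summary statistics
#'
#' Identical to [ttest_two_sample()] on raw data with these summaries — the
#' form used to recompute published t values from printed means/SDs/ns.
#'
#' @param m1,s1,n1 Mean, SD and n of group 1.
#' @param m2,s2,n2 Mean, SD and n of group 2.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `form`.
#' @examples
#' ttest_from_summary(0.5085, 0.2071, 11, 0.6726, 0.1020, 9)
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) abort("Pooled variance is zero.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  tibble(
    t = t, df = df, p = 2 * pt(-abs(t), df),
    mean_diff = m1 - m2, form = "summary_stats"
  )
}

#' Paired t-test
#'
#' One-sample t on pairwise differences, `df = n - 1`. Incomplete pairs
#' (NA in either member) are dropped, with the dropped count reported. All
#' differences equal to zero yield `t = 0, p = 1`; a non-zero constant
#' difference yields an infinite t reported with `p = 0` and a
#' `zero_variance` flag.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `n_dropped`,
#'   `zero_variance`, `form`.
#' @export
ttest_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  d <- x[keep] - y[keep]
  if (length(d) < 2) abort("Need at least 2 complete pairs.")
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(
        t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
        n_dropped = n_dropped, zero_variance = TRUE, form = "paired"
      ))
    }
    return(tibble(
      t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
      mean_diff = mean(d), n_dropped = n_dropped,
      zero_variance = TRUE, form = "paired"
    ))
  }
  fit <- t.test(d)
  tibble(
    t = unname(fit$statistic), df = unname(fit$parameter),
    p = fit$p.value, mean_diff = mean(d), n_dropped = n_dropped,
    zero_variance = FALSE, form = "paired"
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' two-sided p-value from the t approximation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); either being
#'   constant is an error (rho undefined).
#' @return One-row tibble: `rho`, `p`, `n`.
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4)) # rho = 0.8
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation is undefined for constant input.")
  }
  fit <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(fit$estimate), p = fit$p.value, n = length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforced; the family is
#' exactly the set of p-values passed in.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @examples
#' fdr_bh(c(0.01, 0.04)) # 0.02 0.04
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Group and severity statistics for the brain states
#'
#' Reproduces the statistical battery of the state analysis:
#' * per state, two-sample pooled t-tests (neglect minus non-neglect) on
#'   fraction times and on dwell times, each metric's states FDR-corrected
#'   as one family;
#' * Spearman correlations of neglect severity (mean of the two CoC scores)
#'   with fraction times and dwell times per state, FDR per metric family;
#' * paired t-tests contrasting modularity and system segregation between
#'   consecutive states across subjects.
#'
#' @param temporal Tibble from [temporal_metrics()].
#' @param graph Tibble from [graph_metrics()] on subject state matrices
#'   (needs `subject`, `state`, `modularity`, `segregation`); optional.
#' @param behavior Behavior tibble (`subject`, `coc_bells`, `coc_letter`,
#'   `group`).
#' @param neglect_label Value of `behavior$group` defining group 1
#'   (default `"neglect"`).
#' @return List of class `dfc_group_stats`: `group_tests` (tibble: `metric`,
#'   `state`, `t`, `df`, `p`, `q`, `mean_diff`), `severity` (tibble:
#'   `metric`, `state`, `rho`, `p`, `q`, `n`), `state_contrasts` (tibble or
#'   `NULL`).
#' @export
run_group_analysis <- function(temporal, behavior, graph = NULL,
                               neglect_label = "neglect") {
  joined <- left_join(temporal, behavior, by = "subject")
  if (anyNA(joined$group)) {
    abort("Behavior table does not cover all subjects in `temporal`.")
  }
  joined <- mutate(joined,
    severity = (.data$coc_bells + .data$coc_letter) / 2,
    is_neglect = .data$group == neglect_label
  )
  states <- sort(unique(joined$state))
  metrics <- c(fraction_time = "fraction_time", dwell_windows = "dwell_windows")

  one_family <- function(metric) {
    rows <- purrr::map(states, function(s) {
      d <- filter(joined, .data$state == s)
      x <- d[[metric]][d$is_neglect]
      y <- d[[metric]][!d$is_neglect]
      if (length(x) < 2 || length(y) < 2) {
        warn(sprintf(
          "Group with < 2 subjects; skipping %s test for state %d.",
          metric, s
        ))
        return(NULL)
      }
      mutate(ttest_two_sample(x, y), metric = metric, state = s)
    })
    out <- bind_rows(rows)
    if (nrow(out)) out$q <- fdr_bh(out$p)
    out
  }
  empty_tests <- tibble(
    metric = character(), state = integer(), t = numeric(), df = numeric(),
    p = numeric(), q = numeric(), mean_diff = numeric()
  )
  group_tests <- bind_rows(
    empty_tests,
    bind_rows(purrr::map(names(metrics), one_family))
  ) %>%
    select("metric", "state", "t", "df", "p", "q", "mean_diff")

  sev_family <- function(metric) {
    rows <- purrr::map(states, function(s) {
      d <- filter(joined, .data$state == s)
      mutate(spearman_cor(d$severity, d[[metric]]), metric = metric, state = s)
    })
    out <- bind_rows(rows)
    out$q <- fdr_bh(out$p)
    out
  }
  severity <- bind_rows(purrr::map(names(metrics), sev_family)) %>%
    select("metric", "state", "rho", "p", "q", "n")

  state_contrasts <- NULL
  if (!is.null(graph)) {
    wide <- function(col) {
      tidyr::pivot_wider(
        graph[c("subject", "state", col)],
        names_from = "state", values_from = all_of(col), names_prefix = "s"
      )
    }
    pairs <- utils::combn(states, 2, simplify = FALSE)
    rows <- purrr::map(pairs, function(pr) {
      bind_rows(purrr::map(c("modularity", "segregation"), function(col) {
        w <- wide(col)
        mutate(
          ttest_paired(w[[paste0("s", pr[1])]], w[[paste0("s", pr[2])]]),
          metric = col, state_a = pr[1], state_b = pr[2]
        )
      }))
    })
    state_contrasts <- bind_rows(rows) %>%
      select(
        "metric", "state_a", "state_b", "t", "df", "p", "mean_diff",
        "n_dropped", "zero_variance"
      )
  }

  structure(
    list(
      group_tests = group_tests,
      severity = severity,
      state_contrasts = state_contrasts
    ),
    class = "dfc_group_stats"
  )
}

#' @export
print.dfc_group_stats <- function(x, ...) {
  cat("<dfc_group_stats>\nGroup t-tests (neglect - non-neglect):\n")
  print(x$group_tests)
  cat("\nSeverity (mean CoC) Spearman correlations:\n")
  print(x$severity)
  if (!is.null(x$state_contrasts)) {
    cat("\nPaired state contrasts:\n")
    print(x$state_contrasts)
  }
  invisible(x)
}
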