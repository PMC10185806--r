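#' Number of sliding windows
#'
#' Windows of `window_length` volumes advance by `step` volumes, so a run of
#' `n_volumes` yields `floor((n_volumes - window_length) / step) + 1` windows
#' (260 volumes, 20-TR window, 1-TR step give 241).
#'
#' @param n_volumes Number of volumes in the run.
#' @param window_length Window length in volumes (>= 2).
#' @param step Window step in volumes (>= 1).
#' @return Integer window count.
#' @export
count_windows <- function(n_volumes, window_length = 20L, step = 1L) {
  stopifnot(window_length >= 2, step >= 1)
  if (n_volumes < window_length) {
    abort("`n_volumes` must be at least `window_length`.")
  }
  as.integer((n_volumes - window_length) %/% step + 1L)
}

#' Fisher z transform of correlation values
#'
#' `atanh(r)`, applied after clipping `|r|` at `1 - 1e-7` so the result stays
#' finite for perfectly (anti-)correlated pairs.
#'
#' @param r Numeric vector/matrix of correlations.
#' @return `atanh` of the clipped input, same shape.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Row-major upper-triangle order: (1,2), (1,3), ..., (1,N), (2,3), ...
#' [unvectorize_upper()] inverts it exactly (diagonal restored as 0).
#'
#' @param m Symmetric N x N matrix.
#' @return Numeric vector of length `N * (N - 1) / 2`.
#' @export
vectorize_upper <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  # column-major lower triangle == row-major upper triangle for symmetric m
  m[lower.tri(m)]
}

#' @rdname vectorize_upper
#' @param v Vector as produced by [vectorize_upper()].
#' @param roi_names Optional dimnames for the restored matrix.
#' @return `unvectorize_upper`: the N x N symmetric matrix with zero diagonal.
#' @export
unvectorize_upper <- function(v, roi_names = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-8) {
    abort("Length is not a triangular number N(N-1)/2.")
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(roi_names)) dimnames(m) <- list(roi_names, roi_names)
  m
}

# Rolling Pearson correlations of all column pairs via cumulative sums:
# O(T N^2) per run. Returns W x P matrix of r values (P = N(N-1)/2,
# row-major upper-triangle order) plus the window onsets.
rolling_pearson <- function(x, window_length, step) {
  t_n <- nrow(x)
  n <- ncol(x)
  n_w <- count_windows(t_n, window_length, step)
  onsets <- seq.int(1L, by = step, length.out = n_w)
  lower <- which(lower.tri(matrix(0, n, n)))
  ij <- arrayInd(lower, c(n, n)) # row-major-upper pair (col, row)
  # cumulative sums of x and of all pairwise products
  cs <- apply(x, 2, cumsum)
  prod_mat <- x[, ij[, 2], drop = FALSE] * x[, ij[, 1], drop = FALSE]
  csp <- apply(prod_mat, 2, cumsum)
  sq <- apply(x * x, 2, cumsum)
  win_sum <- function(cm) {
    hi <- cm[onsets + window_length - 1L, , drop = FALSE]
    lo <- rbind(0, cm)[onsets, , drop = FALSE]
    hi - lo
  }
  s <- win_sum(cs)
  s2 <- win_sum(sq)
  sp <- win_sum(csp)
  w <- window_length
  vx <- s2 - s^2 / w # w * variance
  vx[vx < 0] <- 0
  cov_ij <- sp - s[, ij[, 2], drop = FALSE] * s[, ij[, 1], drop = FALSE] / w
  denom <- sqrt(vx[, ij[, 2], drop = FALSE] * vx[, ij[, 1], drop = FALSE])
  bad <- denom <= .Machine$double.eps * w
  r <- cov_ij / denom
  if (any(bad)) {
    warn("Zero-variance ROI within a window; affected correlations set to 0.")
    r[bad] <- 0
  }
  list(r = r, onsets = onsets)
}

#' Sliding-window functional connectivity
#'
#' For each window of `window_length` volumes (advancing by `step`), the
#' Pearson correlation between every ROI pair is computed and Fisher
#' z-transformed. Windows never cross run boundaries; a subject's window
#' stream is the run-wise concatenation in acquisition order. A ROI with zero
#' variance inside a window yields r = 0 for its pairs, with a warning.
#'
#' @param ts Cohort time-series tibble (`subject`, `run`, `volume`, ROI
#'   columns), band-pass filtered.
#' @param window_length Window length in volumes (default 20).
#' @param step Step in volumes (default 1).
#' @return A tibble with columns `subject`, `run`, `onset` (first volume of
#'   the window) and a matrix column `z` whose rows are the Fisher-z upper
#'   triangles (length `N(N-1)/2`, order of [vectorize_upper()]).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(
#'   n_subjects = c(1, 1),
#'   n_volumes = 40, seed = 1
#' ))
#' wfc <- sliding_window_fc(cohort$timeseries)
#' nrow(wfc) # 2 subjects x 21 windows
#' @export
sliding_window_fc <- function(ts, window_length = 20L, step = 1L) {
  rois <- roi_columns(ts)
  blocks <- ts %>%
    arrange(.data$subject, .data$run, .data$volume) %>%
    group_by(.data$subject, .data$run) %>%
    tidyr::nest() %>%
    ungroup() %>%
    arrange(.data$subject, .data$run)
  out <- purrr::pmap(
    list(blocks$subject, blocks$run, blocks$data),
    function(subject, run, data) {
      x <- as.matrix(data[rois])
      rp <- rolling_pearson(x, window_length, step)
      tibble(
        subject = subject, run = run, onset = rp$onsets,
        z = fisher_z(rp$r)
      )
    }
  )
  res <- bind_rows(out)
  attr(res$z, "roi_names") <- rois
  res
}

#' Static (time-averaged) functional connectivity
#'
#' Element-wise mean of all of a subject's windowed Fisher-z matrices, pooled
#' across runs — the static counterpart of the dynamic connectivity stream.
#'
#' @param wfc Windowed FC tibble from [sliding_window_fc()].
#' @param roi_names Optional ROI names for matrix dimnames; defaults to the
#'   names recorded by [sliding_window_fc()].
#' @return A tibble with one row per subject: `subject`, `n_windows`, and a
#'   list column `fc` of N x N symmetric zero-diagonal matrices.
#' @export
static_fc <- function(wfc, roi_names = NULL) {
  stopifnot(nrow(wfc) >= 1)
  if (is.null(roi_names)) roi_names <- attr(wfc$z, "roi_names")
  wfc %>%
    group_by(.data$subject) %>%
    summarise(
      n_windows = dplyr::n(),
      fc = list(unvectorize_upper(colMeans(.data$z), roi_names)),
      .groups = "drop"
    )
}
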