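#' Temporal band-pass filter for ROI time series
#'
#' Applies a 2nd-order Butterworth band-pass forward and backward
#' ([signal::filtfilt()]), so the net filter is zero-phase and the effective
#' roll-off is 4th order. The default band, 0.029-0.15 Hz, is the range
#' recommended for sliding-window dynamic connectivity: the lower edge
#' suppresses fluctuations slower than the window length, the upper edge
#' removes high-frequency noise. Each ROI column is filtered independently;
#' output length equals input length. No padding is added beyond the filter
#' routine's own edge handling, so roughly the first and last `1/low_hz`
#' seconds of the record are attenuated.
#'
#' @param ts Cohort time-series tibble (`subject`, `run`, `volume`, ROI
#'   columns), as from [read_roi_timeseries()] or [simulate_cohort()].
#' @param tr_seconds Repetition time in seconds.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)` (the Nyquist frequency).
#' @param order Butterworth order per pass (default 2).
#' @return A tibble of the same shape with filtered ROI columns.
#' @examples
#' p <- parcellation(c("r1", "r2"), c("A", "A"))
#' ts <- tibble::tibble(
#'   subject = "s1", run = 1L, volume = 1:120,
#'   r1 = sin(2 * pi * 0.08 * (0:119) * 1.714), r2 = rnorm(120)
#' )
#' filt <- bandpass_filter(ts, tr_seconds = 1.714)
#' @export
bandpass_filter <- function(ts, tr_seconds, low_hz = 0.029, high_hz = 0.15,
                            order = 2L) {
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    abort("Need 0 < low_hz < high_hz.")
  }
  if (high_hz >= nyquist) {
    abort(sprintf(
      "high_hz (%.4f) must be below the Nyquist frequency (%.4f Hz).",
      high_hz, nyquist
    ))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  rois <- roi_columns(ts)
  # columns are demeaned first: DC is outside the band anyway, and removing
  # it before filtering avoids step transients at the record edges
  ts %>%
    group_by(.data$subject, .data$run) %>%
    mutate(across(all_of(rois), ~ signal::filtfilt(bf, .x - mean(.x)))) %>%
    ungroup()
}
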