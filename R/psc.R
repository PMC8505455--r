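#' Extract trial percent signal change from voxel timecourses
#'
#' For each stimulus event, averages the `window_len_s` samples starting
#' `window_offset_s` seconds after the event onset (the window offset
#' accounts for hemodynamic delay; sampling is assumed to be one image per
#' second) and expresses the average as percent change relative to a
#' baseline level.
#'
#' @param timecourse numeric vector or time x voxels matrix of raw signal.
#' @param onsets integer vector of 1-based sample indices of event onsets.
#' @param baseline_level baseline signal level; must be nonzero.
#' @param window_offset_s seconds between onset and window start (default 5).
#' @param window_len_s window length in seconds/samples (default 4).
#' @return numeric matrix (events x voxels) of percent signal change.
#' @examples
#' tc <- rep(100, 20); tc[6:9] <- 110
#' compute_psc(tc, onsets = 1, baseline_level = 100)  # 10%
#' @export
compute_psc <- function(timecourse, onsets, baseline_level,
                        window_offset_s = 5, window_len_s = 4) {
  if (!is.matrix(timecourse)) timecourse <- matrix(timecourse, ncol = 1)
  if (length(baseline_level) != 1 || baseline_level == 0) {
    stop("baseline_level must be a single nonzero value")
  }
  n <- nrow(timecourse)
  out <- matrix(NA_real_, length(onsets), ncol(timecourse))
  for (e in seq_along(onsets)) {
    rows <- onsets[e] + window_offset_s + seq_len(window_len_s) - 1
    if (min(rows) < 1 || max(rows) > n) {
      stop(sprintf("event %d: response window [%d, %d] falls outside the series (length %d)",
                   e, min(rows), max(rows), n))
    }
    out[e, ] <- 100 * (colMeans(timecourse[rows, , drop = FALSE]) - baseline_level) /
      baseline_level
  }
  out
}
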