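#' Pool interspike intervals within spontaneous windows
#'
#' Collects interspike intervals (ISIs) between consecutive spikes that both
#' fall inside the same window. Intervals spanning a window boundary are
#' excluded, so ISIs never bridge an odor presentation. Windows are half-open
#' \code{[start, end)} and must be disjoint and sorted.
#'
#' @param times Numeric spike times (seconds), or a \code{\link{spike_train}}.
#' @param windows data.frame with \code{start_s}, \code{end_s} columns, as
#'   produced by \code{\link{interstimulus_tail_windows}}.
#' @return Numeric vector of ISI durations in seconds (possibly empty).
#' @export
pool_spontaneous_isis <- function(times, windows) {
  if (inherits(times, "spike_train")) times <- times$times
  if (nrow(windows) == 0L || length(times) < 2L) return(numeric(0))
  isis <- numeric(0)
  for (i in seq_len(nrow(windows))) {
    inside <- times[times >= windows$start_s[i] & times < windows$end_s[i]]
    if (length(inside) >= 2L) isis <- c(isis, diff(inside))
  }
  isis
}

#' Spontaneous firing rate from pooled ISIs
#'
#' The session-wide spontaneous rate is the reciprocal of the mean interspike
#' interval over the pooled spontaneous windows.
#'
#' @param isis Numeric ISI durations in seconds.
#' @return Rate in Hz; \code{NA_real_} when no ISIs are available.
#' @export
spontaneous_rate <- function(isis) {
  if (length(isis) < 1L) return(NA_real_)
  1 / mean(isis)
}

#' Coefficient of variation of the ISI distribution
#'
#' CV = ISI SD / ISI mean, using the sample (n - 1) standard deviation. CV is
#' 1 for a Poisson process and 0 for a perfectly regular train; values above 1
#' indicate burstier-than-Poisson output.
#'
#' @param isis Numeric ISI durations in seconds.
#' @return Dimensionless CV; \code{NA_real_} with fewer than 2 ISIs.
#' @export
isi_cv <- function(isis) {
  if (length(isis) < 2L) return(NA_real_)
  stats::sd(isis) / mean(isis)
}

#' Per-cell spontaneous activity metrics for a session
#'
#' Computes, for every cell in a session, the spontaneous firing rate and ISI
#' CV over the final \code{spont_tail} seconds of each interstimulus interval.
#'
#' @param session An \code{os_session}.
#' @param windows An \code{\link{analysis_windows}}.
#' @return data.frame with columns \code{cell_id}, \code{region},
#'   \code{rate_hz}, \code{isi_cv}, \code{n_isis}. Metrics are \code{NA} when
#'   fewer than 2 qualifying ISIs exist.
#' @export
spontaneous_metrics <- function(session, windows = analysis_windows()) {
  tails <- interstimulus_tail_windows(session$events, windows)
  res <- lapply(session$cells$cell_id, function(id) {
    isis <- pool_spontaneous_isis(session$spikes[[id]], tails)
    data.frame(cell_id = id,
               rate_hz = if (length(isis) >= 2L) spontaneous_rate(isis) else NA_real_,
               isi_cv = isi_cv(isis),
               n_isis = length(isis))
  })
  out <- do.call(rbind, res)
  merge(session$cells[, c("cell_id", "region")], out,
        by = "cell_id", sort = FALSE)
}
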