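#' Epoch a spike train into per-trial baseline and odor-period counts
#'
#' For every odor presentation, counts spikes in the baseline window
#' \code{[onset - baseline_dur, onset)} and the odor window
#' \code{[onset, onset + odor_dur)} (half-open, so a spike at onset belongs to
#' the odor period). Trials whose baseline window would begin before the
#' session start are dropped with a warning.
#'
#' @param times Numeric spike times (seconds) or a \code{\link{spike_train}}.
#' @param events An \code{\link{event_table}}.
#' @param windows An \code{\link{analysis_windows}}.
#' @return data.frame with one row per retained trial: \code{odor_id},
#'   \code{is_vehicle}, \code{onset_s}, \code{baseline_count},
#'   \code{odor_count}.
#' @export
epoch_trials <- function(times, events, windows = analysis_windows()) {
  if (inherits(times, "spike_train")) times <- times$times
  keep <- events$onset_s - windows$baseline_dur >= 0
  if (any(!keep)) {
    warning(sprintf("epoch_trials: dropped %d trial(s) with baseline before session start",
                    sum(!keep)), call. = FALSE)
  }
  ev <- events[keep, , drop = FALSE]
  times <- sort(times)
  # number of spikes strictly before x, so counts are over half-open [a, b)
  n_before <- function(x) findInterval(x, times, left.open = TRUE)
  base_ct <- n_before(ev$onset_s) - n_before(ev$onset_s - windows$baseline_dur)
  odor_ct <- n_before(ev$onset_s + windows$odor_dur) - n_before(ev$onset_s)
  data.frame(odor_id = ev$odor_id, is_vehicle = ev$is_vehicle,
             onset_s = ev$onset_s, baseline_count = base_ct,
             odor_count = odor_ct)
}

#' Baseline-normalized odor-response z-score
#'
#' Per-trial firing rates are counts divided by the window duration; the
#' response is expressed in baseline SD units:
#' z = (mean odor rate - mean baseline rate) / SD of per-trial baseline rates,
#' with the sample (n - 1) SD. When the baseline SD is zero the z-score is 0
#' if the means are equal and a signed infinite sentinel otherwise.
#'
#' @param baseline_counts,odor_counts Integer per-trial spike counts.
#' @param windows An \code{\link{analysis_windows}} (window durations).
#' @return z in baseline-SD units; \code{NA_real_} with fewer than 2 trials;
#'   \code{Inf}/\code{-Inf} sentinels for the degenerate zero-SD case.
#' @export
response_zscore <- function(baseline_counts, odor_counts,
                            windows = analysis_windows()) {
  stopifnot(length(baseline_counts) == length(odor_counts))
  n <- length(baseline_counts)
  if (n < 2L) return(NA_real_)
  base_rate <- baseline_counts / windows$baseline_dur
  odor_rate <- odor_counts / windows$odor_dur
  delta <- mean(odor_rate) - mean(base_rate)
  s <- stats::sd(base_rate)
  if (s == 0) {
    if (delta == 0) return(0)
    return(sign(delta) * Inf)
  }
  delta / s
}

#' Paired rank-biserial correlation
#'
#' Nonparametric effect size for paired data via the simple-difference
#' formula on signed ranks: zero differences are discarded, absolute
#' differences are average-ranked, and
#' r = (sum of ranks of positive differences - sum of ranks of negative
#' differences) / total rank sum. r = 1 when every nonzero difference is
#' positive, r = -1 when every one is negative.
#'
#' @param x Paired differences, or the first sample if \code{y} is given.
#' @param y Optional second sample paired with \code{x} (differences are
#'   \code{x - y}).
#' @return Correlation in \code{[-1, 1]}; 0 (with attribute
#'   \code{degenerate = TRUE}) when all differences are zero.
#' @export
rank_biserial_paired <- function(x, y = NULL) {
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    d <- as.numeric(x) - as.numeric(y)
  } else {
    d <- as.numeric(x)
  }
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

#' All response statistics for one odor-cell pair
#'
#' Combines the per-pair statistics computed on trial-aligned counts: the
#' baseline-normalized z-score, the paired rank-biserial effect size, the
#' two-sided Wilcoxon signed-rank p-value on the paired counts, mean rates,
#' and the classification flags \code{significant} (p < \code{alpha_pair})
#' and \code{exceeds_sd} (z >= \code{sd_threshold}).
#'
#' @param baseline_counts,odor_counts Integer per-trial spike counts.
#' @param windows An \code{\link{analysis_windows}}.
#' @return A one-row data.frame: \code{n_trials}, \code{mean_baseline_hz},
#'   \code{mean_odor_hz}, \code{z}, \code{r_rb}, \code{p}, \code{significant},
#'   \code{exceeds_sd}.
#' @export
test_pair_significance <- function(baseline_counts, odor_counts,
                                   windows = analysis_windows()) {
  stopifnot(length(baseline_counts) == length(odor_counts),
            length(baseline_counts) >= 1L)
  wt <- wilcoxon_signed_rank(odor_counts, baseline_counts)
  z <- response_zscore(baseline_counts, odor_counts, windows)
  exceeds <- !is.na(z) && z >= windows$sd_threshold  # Inf sentinel qualifies
  data.frame(n_trials = length(baseline_counts),
             mean_baseline_hz = mean(baseline_counts) / windows$baseline_dur,
             mean_odor_hz = mean(odor_counts) / windows$odor_dur,
             z = z,
             r_rb = as.numeric(rank_biserial_paired(odor_counts, baseline_counts)),
             p = wt$p,
             significant = wt$p < windows$alpha_pair,
             exceeds_sd = exceeds)
}

#' Per odor-cell pair response table for one cell
#'
#' Epochs the train around every presentation and computes the full pair
#' statistics for each odorant (the vehicle channel included; it is flagged so
#' downstream summaries can exclude it from responsiveness proportions).
#'
#' @param cell_id Unit identifier carried into the output.
#' @param times Spike times or a \code{\link{spike_train}}.
#' @param events An \code{\link{event_table}}.
#' @param windows An \code{\link{analysis_windows}}.
#' @return data.frame with one row per odorant: \code{cell_id},
#'   \code{odor_id}, \code{is_vehicle}, and the columns of
#'   \code{\link{test_pair_significance}}.
#' @export
cell_odor_responses <- function(cell_id, times, events,
                                windows = analysis_windows()) {
  trials <- epoch_trials(times, events, windows)
  odors <- unique(trials$odor_id)
  rows <- lapply(odors, function(od) {
    tr <- trials[trials$odor_id == od, , drop = FALSE]
    cbind(data.frame(cell_id = cell_id, odor_id = od,
                     is_vehicle = tr$is_vehicle[1L]),
          test_pair_significance(tr$baseline_count, tr$odor_count, windows))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Odor selectivity index
#'
#' (maxrate - minrate) / (maxrate + minrate) over a cell's mean odor-period
#' firing rates across the odorant panel, vehicle omitted. 0 indicates equal
#' rates for all odorants, 1 indicates firing confined to a single odorant.
#'
#' @param rates Numeric mean odor-period rates (Hz), one per odorant,
#'   vehicle already excluded.
#' @return Selectivity in \code{[0, 1]} for nonnegative rates;
#'   \code{NA_real_} with fewer than 2 odorants or when all rates are zero.
#' @export
selectivity_index <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2L) return(NA_real_)
  mx <- max(rates); mn <- min(rates)
  if (mx + mn == 0) return(NA_real_)
  (mx - mn) / (mx + mn)
}

#' Per-cell odor tuning profiles
#'
#' Reduces a per-pair response table to one row per cell: mean odor-period
#' rates across the panel (vehicle omitted), their extrema, and the
#' selectivity index.
#'
#' @param pairs data.frame as returned by \code{\link{cell_odor_responses}}
#'   (possibly row-bound over cells).
#' @return data.frame with \code{cell_id}, \code{n_odorants}, \code{maxrate_hz},
#'   \code{minrate_hz}, \code{selectivity}.
#' @export
odor_tuning <- function(pairs) {
  po <- pairs[!pairs$is_vehicle, , drop = FALSE]
  ids <- unique(pairs$cell_id)
  rows <- lapply(ids, function(id) {
    r <- po$mean_odor_hz[po$cell_id == id]
    data.frame(cell_id = id, n_odorants = length(r),
               maxrate_hz = if (length(r)) max(r) else NA_real_,
               minrate_hz = if (length(r)) min(r) else NA_real_,
               selectivity = selectivity_index(r))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify responsiveness across a cohort
#'
#' Aggregates per-pair response flags into regional counts and proportions:
#' significant odor-cell pairs, cells responsive to at least one odorant,
#' pairs with z-scores at or above the strong-response threshold, a per-odorant
#' breakdown, and the number of effective odorants among responsive cells.
#' Vehicle pairs are excluded from all responsiveness proportions (their test
#' results remain available in the input table).
#'
#' @param pairs Per-pair response table (rows from
#'   \code{\link{cell_odor_responses}} over all cells).
#' @param cells A \code{\link{cell_table}} covering every \code{cell_id} in
#'   \code{pairs}.
#' @return A list of class \code{cohort_classification}: \code{region_summary}
#'   (per region: n_cells, n_pairs, n_sig_pairs, prop_sig_pairs,
#'   n_responsive_cells, prop_responsive_cells, n_exceed_sd, prop_exceed_sd,
#'   median_n_odors_responsive), \code{per_odor} (per region and odorant:
#'   n_pairs, n_sig, n_responsive_cells), and \code{responsive_cells}
#'   (cell_id, region, n_sig_odors).
#' @export
classify_cohort <- function(pairs, cells) {
  orphan <- setdiff(unique(pairs$cell_id), cells$cell_id)
  if (length(orphan)) {
    stop("classify_cohort: pairs reference unknown cell_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  pr <- merge(pairs[, setdiff(names(pairs), "region")],
              cells[, c("cell_id", "region")], by = "cell_id")
  po <- pr[!pr$is_vehicle, , drop = FALSE]

  per_cell <- stats::aggregate(significant ~ cell_id + region, data = po, FUN = sum)
  names(per_cell)[3L] <- "n_sig_odors"
  resp_cells <- per_cell[per_cell$n_sig_odors >= 1L, , drop = FALSE]
  rownames(resp_cells) <- NULL

  regions <- unique(cells$region)
  region_summary <- do.call(rbind, lapply(regions, function(rg) {
    cr <- cells$cell_id[cells$region == rg]
    pp <- po[po$region == rg, , drop = FALSE]
    rc <- resp_cells[resp_cells$region == rg, , drop = FALSE]
    n_pairs <- nrow(pp)
    data.frame(region = rg,
               n_cells = length(cr),
               n_pairs = n_pairs,
               n_sig_pairs = sum(pp$significant),
               prop_sig_pairs = if (n_pairs) mean(pp$significant) else NA_real_,
               n_responsive_cells = nrow(rc),
               prop_responsive_cells = if (length(cr)) nrow(rc) / length(cr) else NA_real_,
               n_exceed_sd = sum(pp$exceeds_sd),
               prop_exceed_sd = if (n_pairs) mean(pp$exceeds_sd) else NA_real_,
               median_n_odors_responsive = if (nrow(rc)) stats::median(rc$n_sig_odors) else NA_real_)
  }))
  rownames(region_summary) <- NULL

  per_odor <- stats::aggregate(cbind(n_pairs = significant * 0 + 1,
                                     n_sig = significant) ~ region + odor_id,
                               data = po, FUN = sum)
  structure(list(region_summary = region_summary,
                 per_odor = per_odor,
                 responsive_cells = resp_cells),
            class = "cohort_classification")
}

#' Peristimulus time histogram for one odor-cell pair
#'
#' Bins spikes relative to each presentation onset and averages the binned
#' rates across trials, with the across-trial standard error per bin.
#'
#' @param times Spike times or a \code{\link{spike_train}}.
#' @param onsets Numeric odor onsets (seconds) for the trials to average.
#' @param bin_width_s Bin width in seconds.
#' @param span Two-element numeric: window relative to onset
#'   (e.g. \code{c(-4, 8)}).
#' @return A list of class \code{psth}: \code{bin_width_s}, \code{edges},
#'   \code{centers}, \code{rate_hz}, \code{sem_hz} (NA with a single trial),
#'   \code{n_trials}.
#' @export
compute_psth <- function(times, onsets, bin_width_s = 0.1, span = c(-4, 8)) {
  if (inherits(times, "spike_train")) times <- times$times
  stopifnot(length(onsets) >= 1L, diff(span) > 0)
  nb <- ceiling((span[2L] - span[1L]) / bin_width_s - 1e-9)
  edges <- span[1L] + bin_width_s * (0:nb)
  counts <- matrix(0, nrow = length(onsets), ncol = nb)
  for (i in seq_along(onsets)) {
    rel <- times - onsets[i]
    rel <- rel[rel >= edges[1L] & rel < edges[nb + 1L]]
    if (length(rel)) {
      idx <- pmin(nb, floor((rel - edges[1L]) / bin_width_s) + 1L)
      tab <- tabulate(idx, nbins = nb)
      counts[i, ] <- tab
    }
  }
  rates <- counts / bin_width_s
  m <- colMeans(rates)
  sem <- if (nrow(rates) > 1L) {
    apply(rates, 2L, stats::sd) / sqrt(nrow(rates))
  } else {
    rep(NA_real_, nb)
  }
  structure(list(bin_width_s = bin_width_s, edges = edges,
                 centers = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                 rate_hz = m, sem_hz = sem, n_trials = length(onsets)),
            class = "psth")
}

#' Grand-average PSTH across qualifying odor-cell pairs
#'
#' Averages the per-pair PSTH traces (each already trial-averaged) and
#' reports the across-pair SEM, as used to summarise strong excitatory
#' responses (pairs whose odor-period z-score exceeds the SD threshold).
#'
#' @param psths List of \code{psth} objects on identical bin grids.
#' @return A \code{psth} whose \code{n_trials} field holds the number of
#'   pairs averaged; \code{NULL} for an empty list.
#' @export
grand_average_psth <- function(psths) {
  psths <- Filter(Negate(is.null), psths)
  if (length(psths) == 0L) return(NULL)
  e1 <- psths[[1L]]$edges
  ok <- vapply(psths, function(p) length(p$edges) == length(e1) &&
                 max(abs(p$edges - e1)) < 1e-9, TRUE)
  if (!all(ok)) stop("grand_average_psth: PSTHs on different bin grids",
                     call. = FALSE)
  mat <- do.call(rbind, lapply(psths, function(p) p$rate_hz))
  sem <- if (nrow(mat) > 1L) {
    apply(mat, 2L, stats::sd) / sqrt(nrow(mat))
  } else {
    rep(0, ncol(mat))
  }
  structure(list(bin_width_s = psths[[1L]]$bin_width_s, edges = e1,
                 centers = psths[[1L]]$centers,
                 rate_hz = colMeans(mat), sem_hz = sem,
                 n_trials = length(psths)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %.3f s over [%.1f, %.1f] s, %d trace(s), peak %.2f Hz\n",
              length(x$rate_hz), x$bin_width_s, x$edges[1L],
              x$edges[length(x$edges)], x$n_trials, max(x$rate_hz)))
  invisible(x)
}
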