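#' Run the full analysis over a cohort of sessions
#'
#' Applies every stage to each session — spontaneous metrics over the
#' interstimulus tails, per odor-cell pair response statistics, per-cell
#' tuning, respiratory cycle detection and phase statistics (for sessions with
#' a respiration trace) — then aggregates regional summaries, grand-average
#' PSTHs of strong excitatory pairs, and interregional / sex comparisons.
#' Deterministic given its inputs.
#'
#' @param sessions A list of \code{os_session}, a single session, a
#'   \code{synthetic_cohort}, or a directory path of written sessions.
#' @param windows An \code{\link{analysis_windows}}.
#' @param compare Character vector of two regions entered into inferential
#'   comparisons (default DTT vs AON; other regions are summarised
#'   descriptively only).
#' @param cycle_origin Zero-crossing direction passed to
#'   \code{\link{detect_cycles}} (phase-origin convention).
#' @return List of class \code{cohort_summary}: per-cell and per-pair tables
#'   (\code{cells}, \code{spont}, \code{pairs}, \code{tuning}, \code{phase}),
#'   the \code{classification}, a per-region \code{region_summary},
#'   interregional and sex \code{comparisons}, and per-region
#'   \code{grand_psth}.
#' @export
run_cohort <- function(sessions, windows = analysis_windows(),
                       compare = c("DTT", "AON"), cycle_origin = "rising") {
  if (is.character(sessions) && length(sessions) == 1L) {
    sessions <- read_cohort(sessions)
  }
  if (inherits(sessions, "synthetic_cohort")) sessions <- sessions$sessions
  if (inherits(sessions, "os_session")) sessions <- list(sessions)
  if (!length(sessions) || sum(vapply(sessions, function(s) nrow(s$cells), 0L)) == 0L) {
    stop("run_cohort: no cells to analyse", call. = FALSE)
  }

  cells_l <- list(); spont_l <- list(); pairs_l <- list(); phase_l <- list()
  psths <- list()
  for (si in seq_along(sessions)) {
    sess <- sessions[[si]]
    cells_l[[si]] <- cbind(as.data.frame(sess$cells), session = si)
    spont_l[[si]] <- spontaneous_metrics(sess, windows)

    cycles <- NULL
    if (!is.null(sess$respiration)) {
      cycles <- detect_cycles(sess$respiration, direction = cycle_origin)
    }
    for (id in sess$cells$cell_id) {
      pr <- cell_odor_responses(id, sess$spikes[[id]], sess$events, windows)
      pairs_l[[length(pairs_l) + 1L]] <- pr
      if (!is.null(cycles) && nrow(cycles)) {
        ph <- cell_phase_stats(sess$spikes[[id]], cycles, sess$events, windows)
        phase_l[[length(phase_l) + 1L]] <- cbind(cell_id = id, ph)
      }
      # PSTHs retained for strong excitatory pairs only
      strong <- pr$odor_id[pr$exceeds_sd & !pr$is_vehicle]
      for (od in strong) {
        onsets <- sess$events$onset_s[sess$events$odor_id == od]
        onsets <- onsets[onsets - windows$baseline_dur >= 0]
        psths[[length(psths) + 1L]] <- list(
          cell_id = id, odor_id = od,
          psth = compute_psth(sess$spikes[[id]], onsets,
                              windows$psth_bin_s, windows$psth_span))
      }
    }
  }
  cells <- do.call(rbind, cells_l)
  spont <- do.call(rbind, spont_l)
  pairs <- merge(do.call(rbind, pairs_l),
                 cells[, c("cell_id", "region", "sex")], by = "cell_id")
  phase <- if (length(phase_l)) do.call(rbind, phase_l) else NULL
  if (!is.null(phase)) {
    phase <- merge(phase, cells[, c("cell_id", "region")], by = "cell_id")
  }

  cls <- classify_cohort(pairs, cells)
  tuning <- merge(odor_tuning(pairs), cells[, c("cell_id", "region")],
                  by = "cell_id")
  spont <- merge(spont[, setdiff(names(spont), "region")],
                 cells[, c("cell_id", "region", "sex")], by = "cell_id")

  med <- function(v) if (sum(!is.na(v))) stats::median(v, na.rm = TRUE) else NA_real_
  region_summary <- do.call(rbind, lapply(unique(cells$region), function(rg) {
    sp <- spont[spont$region == rg, ]
    tu <- tuning[tuning$region == rg, ]
    resp_ids <- cls$responsive_cells$cell_id[cls$responsive_cells$region == rg]
    ph <- if (!is.null(phase)) phase[phase$region == rg, ] else NULL
    mod <- if (!is.null(ph)) ph[!is.na(ph$significant) & ph$significant &
                                  !is.na(ph$unimodal) & ph$unimodal, ] else NULL
    base <- cls$region_summary[cls$region_summary$region == rg, ]
    cbind(base,
          data.frame(
            median_rate_hz = med(sp$rate_hz),
            median_isi_cv = med(sp$isi_cv),
            median_selectivity = med(tu$selectivity),
            median_selectivity_responsive = med(tu$selectivity[tu$cell_id %in% resp_ids]),
            n_phase_cells = if (is.null(ph)) 0L else nrow(ph),
            n_modulated = if (is.null(mod)) 0L else nrow(mod),
            prop_modulated = if (is.null(ph) || !nrow(ph)) NA_real_ else
              nrow(mod) / nrow(ph),
            population_phase_deg = if (is.null(mod) || !nrow(mod)) NA_real_ else
              population_mean_phase(mod$theta_deg)))
  }))
  rownames(region_summary) <- NULL

  comparisons <- list(
    rate_hz = compare_metric(spont, "rate_hz", "region", compare),
    isi_cv = compare_metric(spont, "isi_cv", "region", compare),
    selectivity = compare_metric(tuning, "selectivity", "region", compare),
    sex_rate_hz = compare_metric(spont, "rate_hz", "sex", c("F", "M")),
    sex_isi_cv = compare_metric(spont, "isi_cv", "sex", c("F", "M")),
    per_odor_z = compare_regions_per_odor(pairs, compare)
  )

  grand_psth <- lapply(stats::setNames(nm = compare), function(rg) {
    ids <- cells$cell_id[cells$region == rg]
    sel <- Filter(function(e) e$cell_id %in% ids, psths)
    grand_average_psth(lapply(sel, `[[`, "psth"))
  })

  structure(list(cells = cells, spont = spont, pairs = pairs, tuning = tuning,
                 phase = phase, classification = cls,
                 region_summary = region_summary, comparisons = comparisons,
                 grand_psth = grand_psth, windows = windows),
            class = "cohort_summary")
}

# Mann-Whitney comparison of one per-cell metric between two groups
compare_metric <- function(tbl, metric, group_col, groups) {
  a <- tbl[[metric]][tbl[[group_col]] == groups[1L]]
  b <- tbl[[metric]][tbl[[group_col]] == groups[2L]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    return(data.frame(metric = metric, U = NA_real_, n1 = length(a),
                      n2 = length(b), n = length(a) + length(b),
                      p = NA_real_, skipped = TRUE))
  }
  mw <- mann_whitney_u(a, b)
  data.frame(metric = metric, U = mw$statistic, n1 = mw$n1, n2 = mw$n2,
             n = mw$n1 + mw$n2, p = mw$p, skipped = FALSE)
}

#' Interregional Mann-Whitney comparisons of per-cell metrics
#'
#' Compares one or more per-cell metric columns between two regions with
#' two-sided Mann-Whitney tests, reporting U, group sizes and p per metric.
#' Empty groups are flagged and skipped rather than erroring.
#'
#' @param tbl data.frame with a \code{region} column and the metric columns.
#' @param metrics Character vector of metric column names.
#' @param regions Two regions to compare.
#' @return data.frame, one row per metric: \code{metric}, \code{U}, \code{n1},
#'   \code{n2}, \code{n}, \code{p}, \code{skipped}.
#' @export
compare_regions <- function(tbl, metrics, regions = c("DTT", "AON")) {
  out <- do.call(rbind, lapply(metrics, function(m)
    compare_metric(tbl, m, "region", regions)))
  rownames(out) <- NULL
  out
}

# per-odorant Mann-Whitney comparisons of z-scores between regions
compare_regions_per_odor <- function(pairs, regions = c("DTT", "AON")) {
  po <- pairs[!pairs$is_vehicle & !is.na(pairs$z), , drop = FALSE]
  odors <- sort(unique(po$odor_id))
  out <- do.call(rbind, lapply(odors, function(od) {
    sub <- po[po$odor_id == od, ]
    r <- compare_metric(sub, "z", "region", regions)
    cbind(data.frame(odor_id = od), r[, setdiff(names(r), "metric")])
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  %d cells, %d odor-cell pairs (%d non-vehicle)\n",
              nrow(x$cells), nrow(x$pairs), sum(!x$pairs$is_vehicle)))
  rs <- x$region_summary
  for (i in seq_len(nrow(rs))) {
    cat(sprintf(
      "  %s: %d cells | median rate %.2f Hz, CV %.2f | sig pairs %d/%d (%.1f%%) | responsive cells %d/%d (%.1f%%)\n",
      rs$region[i], rs$n_cells[i], rs$median_rate_hz[i], rs$median_isi_cv[i],
      rs$n_sig_pairs[i], rs$n_pairs[i], 100 * rs$prop_sig_pairs[i],
      rs$n_responsive_cells[i], rs$n_cells[i],
      100 * rs$prop_responsive_cells[i]))
    if (!is.na(rs$population_phase_deg[i])) {
      cat(sprintf("       respiration-modulated %d/%d (%.1f%%), population phase %.1f deg\n",
                  rs$n_modulated[i], rs$n_phase_cells[i],
                  100 * rs$prop_modulated[i], rs$population_phase_deg[i]))
    }
  }
  invisible(x)
}
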