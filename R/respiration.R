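deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# angle of (C, S) in degrees, wrapped to [0, 360)
atan2_deg <- function(S, C) (rad2deg(atan2(S, C)) + 360) %% 360

# resultant length of a set of phases (degrees), optionally harmonic-doubled
resultant_length <- function(phases_deg, harmonic = 1L) {
  if (length(phases_deg) == 0L) return(NA_real_)
  a <- deg2rad(phases_deg * harmonic)
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

#' Segment a respiration trace into breathing cycles
#'
#' Band-limits the raw sensor signal (zero-phase Butterworth filter over a
#' configurable passband) and places cycle boundaries at signed zero
#' crossings, linearly interpolated between samples. Cycles with durations
#' outside physiologic bounds are discarded. The crossing direction defines
#' the phase origin: which respiratory landmark a given direction corresponds
#' to depends on sensor polarity, so both are available; the package's
#' synthetic traces rise through zero at cycle start, making \code{"rising"}
#' the convention-consistent default.
#'
#' @param trace A \code{\link{respiration_trace}}.
#' @param passband Two-element numeric, filter passband in Hz (default 1-15).
#' @param direction \code{"rising"} (default) or \code{"falling"} zero
#'   crossings as cycle boundaries.
#' @param dur_bounds Two-element numeric, admissible cycle durations in
#'   seconds (default 0.1-2).
#' @param edge_pad Seconds at either end of the trace within which cycles are
#'   discarded (zero-phase filter warm-up; default 0.5).
#' @return data.frame of class \code{resp_cycles} with columns
#'   \code{cycle_start_s}, \code{cycle_end_s}; zero rows (with a warning) when
#'   no cycles are detectable.
#' @export
detect_cycles <- function(trace, passband = c(1, 15),
                          direction = c("rising", "falling"),
                          dur_bounds = c(0.1, 2), edge_pad = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(trace, "respiration_trace"))
  fs <- trace$sample_rate_hz
  x <- trace$values
  if (length(x) < 2 * fs) stop("detect_cycles: trace shorter than 2 s",
                               call. = FALSE)
  ny <- fs / 2
  lo <- max(passband[1L] / ny, 1e-6)
  hi <- min(passband[2L] / ny, 0.99)
  if (lo < hi) {
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  if (direction == "falling") x <- -x
  i <- which(x[-length(x)] < 0 & x[-1L] >= 0)
  empty <- resp_cycles(numeric(0), numeric(0))
  if (length(i) < 2L) {
    warning("detect_cycles: no cycles detected", call. = FALSE)
    return(empty)
  }
  frac <- -x[i] / (x[i + 1L] - x[i])   # linear interpolation of the crossing
  t_cross <- trace$t0 + (i - 1L + frac) / fs
  start <- t_cross[-length(t_cross)]
  end <- t_cross[-1L]
  dur <- end - start
  t_end <- trace$t0 + length(trace$values) / fs
  keep <- dur >= dur_bounds[1L] & dur <= dur_bounds[2L] &
    start >= trace$t0 + edge_pad & end <= t_end - edge_pad
  if (!any(keep)) {
    warning("detect_cycles: no cycles within duration bounds", call. = FALSE)
    return(empty)
  }
  resp_cycles(start[keep], end[keep])
}

#' Construct a respiration cycle table
#'
#' @param cycle_start_s,cycle_end_s Numeric cycle boundaries in seconds;
#'   cycles must be non-overlapping and sorted (gaps are allowed).
#' @return data.frame of class \code{resp_cycles}.
#' @export
resp_cycles <- function(cycle_start_s, cycle_end_s) {
  cy <- data.frame(cycle_start_s = as.numeric(cycle_start_s),
                   cycle_end_s = as.numeric(cycle_end_s))
  if (nrow(cy)) {
    stopifnot(all(cy$cycle_end_s > cy$cycle_start_s))
    if (nrow(cy) > 1L) {
      stopifnot(!is.unsorted(cy$cycle_start_s),
                all(cy$cycle_start_s[-1L] >= cy$cycle_end_s[-nrow(cy)] - 1e-12))
    }
  }
  class(cy) <- c("resp_cycles", "data.frame")
  cy
}

#' Assign proportional respiratory phases to spikes
#'
#' Each spike inside a detected cycle receives the phase
#' 360 x (t - cycle start) / (cycle duration) in degrees, so variable-duration
#' cycles are stretched onto a common 0-360 degree axis. Spikes outside every
#' cycle (or outside the analysis window, if given) are dropped and counted.
#'
#' @param times Spike times or a \code{\link{spike_train}}.
#' @param cycles A \code{\link{resp_cycles}} table.
#' @param window Optional \code{c(start_s, end_s)} half-open analysis window;
#'   spikes outside it are ignored (not counted as dropped).
#' @return List of class \code{phase_sample}: \code{phases_deg} in
#'   \code{[0, 360)}, \code{n_spikes}, \code{n_dropped}.
#' @export
assign_spike_phases <- function(times, cycles, window = NULL) {
  if (inherits(times, "spike_train")) times <- times$times
  if (!is.null(window)) {
    times <- times[times >= window[1L] & times < window[2L]]
  }
  if (nrow(cycles) == 0L || length(times) == 0L) {
    return(structure(list(phases_deg = numeric(0), n_spikes = 0L,
                          n_dropped = length(times)),
                     class = "phase_sample"))
  }
  idx <- findInterval(times, cycles$cycle_start_s)
  ok <- idx >= 1L & times < cycles$cycle_end_s[pmax(idx, 1L)]
  ti <- times[ok]; ci <- idx[ok]
  ph <- 360 * (ti - cycles$cycle_start_s[ci]) /
    (cycles$cycle_end_s[ci] - cycles$cycle_start_s[ci])
  ph <- ph %% 360
  structure(list(phases_deg = ph, n_spikes = length(ph),
                 n_dropped = sum(!ok)),
            class = "phase_sample")
}

#' Binned phase histogram
#'
#' @param phases Numeric phases in degrees, or a \code{phase_sample}.
#' @param bin_deg Bin width in degrees; must divide 360 (default 6, giving 60
#'   bins).
#' @return List of class \code{phase_histogram}: \code{bin_deg},
#'   \code{centers_deg}, \code{counts}.
#' @export
phase_histogram <- function(phases, bin_deg = 6) {
  if (inherits(phases, "phase_sample")) phases <- phases$phases_deg
  nb <- 360 / bin_deg
  stopifnot(abs(nb - round(nb)) < 1e-9)
  nb <- as.integer(round(nb))
  idx <- pmin(nb, floor((phases %% 360) / bin_deg) + 1L)
  structure(list(bin_deg = bin_deg,
                 centers_deg = (seq_len(nb) - 0.5) * bin_deg,
                 counts = tabulate(idx, nbins = nb)),
            class = "phase_histogram")
}

#' Preferred phase and modulation depth from binned spike phases
#'
#' Spike phases are binned (6 degree bins by default), each bin contributes a
#' vector at its centre with magnitude equal to its count, and the normalized
#' vector sum gives the preferred phase theta (its angle) and the modulation
#' depth rho (its length divided by the spike count, in \code{[0, 1]}).
#'
#' @param phases Numeric phases in degrees, a \code{phase_sample}, or a
#'   \code{phase_histogram}.
#' @param bin_deg Bin width in degrees (ignored when a histogram is supplied).
#' @return List of class \code{phase_vector}: \code{theta_deg} in
#'   \code{[0, 360)}, \code{rho}, \code{n}.
#' @export
phase_vector <- function(phases, bin_deg = 6) {
  h <- if (inherits(phases, "phase_histogram")) phases else
    phase_histogram(phases, bin_deg)
  n <- sum(h$counts)
  if (n == 0L) {
    return(structure(list(theta_deg = NA_real_, rho = NA_real_, n = 0L),
                     class = "phase_vector"))
  }
  a <- deg2rad(h$centers_deg)
  C <- sum(h$counts * cos(a)); S <- sum(h$counts * sin(a))
  structure(list(theta_deg = atan2_deg(S, C),
                 rho = sqrt(C^2 + S^2) / n,
                 n = as.integer(n)),
            class = "phase_vector")
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether spike phases deviate from a uniform distribution around the
#' respiratory cycle. The statistic is Z = n rho^2 and the p-value uses the
#' standard small-sample-corrected closed form
#' p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n)) with R = n rho, which
#' improves on exp(-Z) for moderate n.
#'
#' @param pv A \code{phase_vector} (or any list with \code{rho} and \code{n}).
#' @param alpha Significance level for the \code{significant} flag (default
#'   0.01).
#' @return List of class \code{rayleigh_result}: \code{Z}, \code{p}, \code{n},
#'   \code{significant}. With n < 4 the test is not attempted and all fields
#'   are \code{NA}.
#' @export
rayleigh_test <- function(pv, alpha = 0.01) {
  n <- pv$n
  if (is.na(n) || n < 4L) {
    return(structure(list(Z = NA_real_, p = NA_real_, n = n,
                          significant = NA), class = "rayleigh_result"))
  }
  R <- n * pv$rho
  Z <- n * pv$rho^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  p <- min(1, max(0, p))
  structure(list(Z = Z, p = p, n = n, significant = p < alpha),
            class = "rayleigh_result")
}

#' Unimodality check via harmonic resultants
#'
#' Compares the resultant length at the fundamental (R1, phases as observed)
#' with the resultant length at the doubled angle (R2, phases x 2 mod 360).
#' A bimodal, antipodally balanced distribution concentrates power in the
#' second harmonic (R2 >> R1), whereas a unimodal one does not; the
#' distribution is flagged unimodal when R1 >= R2.
#'
#' @param phases Numeric phases in degrees, a \code{phase_sample}, or a
#'   \code{phase_histogram} (bin centres weighted by counts).
#' @return Logical flag; \code{NA} for an empty sample.
#' @export
check_unimodality <- function(phases) {
  if (inherits(phases, "phase_sample")) phases <- phases$phases_deg
  if (inherits(phases, "phase_histogram")) {
    phases <- rep(phases$centers_deg, phases$counts)
  }
  if (length(phases) == 0L) return(NA)
  resultant_length(phases, 1L) >= resultant_length(phases, 2L)
}

#' Respiratory phase statistics for one cell
#'
#' Pools spike phases over the phase-analysis window after every odor onset
#' (default 8 s, all presentations including vehicle), forms the binned
#' resultant vector, runs the Rayleigh test and the unimodality check.
#'
#' @param times Spike times or a \code{\link{spike_train}}.
#' @param cycles A \code{\link{resp_cycles}} table.
#' @param events An \code{\link{event_table}}.
#' @param windows An \code{\link{analysis_windows}} (uses \code{phase_dur} and
#'   \code{alpha_phase}).
#' @param bin_deg Histogram bin width in degrees.
#' @return One-row data.frame: \code{theta_deg}, \code{rho}, \code{Z},
#'   \code{p}, \code{significant}, \code{unimodal}, \code{n_spikes},
#'   \code{n_dropped}.
#' @export
cell_phase_stats <- function(times, cycles, events,
                             windows = analysis_windows(), bin_deg = 6) {
  if (inherits(times, "spike_train")) times <- times$times
  phases <- numeric(0); dropped <- 0L
  for (i in seq_len(nrow(events))) {
    ps <- assign_spike_phases(times, cycles,
                              window = c(events$onset_s[i],
                                         events$onset_s[i] + windows$phase_dur))
    phases <- c(phases, ps$phases_deg)
    dropped <- dropped + ps$n_dropped
  }
  pv <- phase_vector(phases, bin_deg)
  rt <- rayleigh_test(pv, alpha = windows$alpha_phase)
  data.frame(theta_deg = pv$theta_deg, rho = pv$rho, Z = rt$Z, p = rt$p,
             significant = rt$significant,
             unimodal = check_unimodality(phases),
             n_spikes = pv$n, n_dropped = dropped)
}

#' Population mean preferred phase
#'
#' The angle of the sum of unit vectors at each qualifying cell's preferred
#' phase (equal weighting), used to summarise phase preferences of all
#' significantly modulated, unimodal cells in a region.
#'
#' @param theta_deg Numeric preferred phases in degrees.
#' @return Mean phase in degrees in \code{[0, 360)}; \code{NA_real_} for an
#'   empty input or a fully balanced configuration (zero resultant).
#' @export
population_mean_phase <- function(theta_deg) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (length(theta_deg) == 0L) return(NA_real_)
  a <- deg2rad(theta_deg)
  C <- sum(cos(a)); S <- sum(sin(a))
  if (sqrt(C^2 + S^2) < 1e-12) return(NA_real_)
  atan2_deg(S, C)
}
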