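#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator with defaults chosen
#' to emulate the acquisition protocol and the statistical structure the
#' analyses assume: 2 s odor pulses with 28 s interstimulus intervals, a
#' median of 8 trials over a panel of 11 odorants plus a mineral-oil vehicle
#' channel, log-normal spontaneous rates with median near 1.4 Hz,
#' anesthetized-mouse respiration near 3 Hz with variable cycle durations,
#' von Mises respiratory gain with preferred phases near 25 degrees, and a
#' minority of cells carrying odor-selective excitatory transients that begin
#' a fraction of a second after odor onset and outlast odor offset.
#'
#' @param n_cells Named integer vector of cells per region, e.g.
#'   \code{c(DTT = 4, AON = 4)}.
#' @param cells_per_subject Units recorded per synthetic subject (default 4).
#' @param n_odorants Odorants in the panel, vehicle excluded (default 11).
#' @param n_trials Presentations per channel (default 8).
#' @param odor_dur_s Odor pulse duration, seconds (default 2).
#' @param isi_s Interstimulus interval, seconds (default 28).
#' @param resp_rate_hz Mean respiration rate, Hz (default 3).
#' @param resp_cycle_cv Coefficient of variation of cycle durations (default
#'   0.15).
#' @param resp_sample_rate_hz Respiration trace sampling rate (default 100).
#' @param resp_noise_sd SD of additive trace noise (default 0.05).
#' @param baseline_median_hz,baseline_sdlog Log-normal spontaneous-rate
#'   parameters (median 1.4 Hz, sigma_log 1).
#' @param kappa_meanlog,kappa_sdlog Log-normal draw for the von Mises
#'   concentration of respiratory gain.
#' @param mu_mean_deg,mu_sd_deg Normal draw (wrapped) for preferred phase.
#' @param frac_responsive Named numeric: per-region probability that a cell is
#'   odor-responsive.
#' @param prob_extra_odor Per-odorant probability that a responsive cell
#'   responds to each additional odorant beyond its first (binomial tuning
#'   breadth).
#' @param response_gain Multiplicative rate gain during the transient
#'   (>= 1, excitatory only).
#' @param response_latency_s Response latency after odor onset, seconds.
#' @param response_duration_s Transient duration, seconds (outlasts the 2 s
#'   pulse).
#' @param seed Integer master seed recorded in the output manifest.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_cells = c(DTT = 4, AON = 4),
                       cells_per_subject = 4L,
                       n_odorants = 11L, n_trials = 8L,
                       odor_dur_s = 2, isi_s = 28,
                       resp_rate_hz = 3, resp_cycle_cv = 0.15,
                       resp_sample_rate_hz = 100, resp_noise_sd = 0.05,
                       baseline_median_hz = 1.4, baseline_sdlog = 1,
                       kappa_meanlog = log(0.8), kappa_sdlog = 0.5,
                       mu_mean_deg = 25, mu_sd_deg = 15,
                       frac_responsive = c(DTT = 0.30, AON = 0.11, VTT = 0.13,
                                           OTHER = 0),
                       prob_extra_odor = 0.25,
                       response_gain = 4,
                       response_latency_s = 0.4,
                       response_duration_s = 6,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$n_cells >= 0), cfg$cells_per_subject >= 1,
            cfg$n_odorants >= 1, cfg$n_trials >= 1,
            cfg$odor_dur_s > 0, cfg$isi_s > 0,
            cfg$resp_rate_hz > 0, cfg$resp_cycle_cv >= 0,
            cfg$baseline_median_hz > 0,
            all(cfg$frac_responsive >= 0), all(cfg$frac_responsive <= 1),
            cfg$response_gain >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a respiration trace with known cycle boundaries
#'
#' Cycle durations are drawn from a gamma distribution with the configured
#' mean (1 / respiration rate) and coefficient of variation (CV = 0 gives a
#' perfectly periodic trace). The trace renders one sinusoid period per cycle
#' (rising through zero at each cycle start) plus additive Gaussian noise, and
#' the ground-truth cycle table is returned alongside.
#'
#' @param duration_s Trace duration in seconds.
#' @param config A \code{\link{sim_config}} (respiration fields used). Uses
#'   the current RNG stream.
#' @return List with elements \code{trace} (\code{respiration_trace}) and
#'   \code{cycles} (\code{resp_cycles}, truncated to cycles starting before
#'   \code{duration_s}).
#' @export
simulate_respiration <- function(duration_s, config = sim_config()) {
  m <- 1 / config$resp_rate_hz
  cv <- config$resp_cycle_cv
  n_guess <- ceiling(duration_s / m * 1.5) + 10L
  draw <- function(k) {
    if (cv == 0) rep(m, k) else
      stats::rgamma(k, shape = 1 / cv^2, scale = m * cv^2)
  }
  durs <- draw(n_guess)
  while (sum(durs) < duration_s + 2 * m) durs <- c(durs, draw(n_guess))
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  keep <- starts < duration_s
  starts <- starts[keep]; ends <- ends[keep]

  fs <- config$resp_sample_rate_hz
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ci <- findInterval(t, starts)
  frac <- (t - starts[ci]) / (ends[ci] - starts[ci])
  vals <- sin(2 * pi * frac)
  if (config$resp_noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), sd = config$resp_noise_sd)
  }
  list(trace = respiration_trace(vals, fs, t0 = 0),
       cycles = resp_cycles(starts, ends))
}

# von Mises density-normalized gain: averages to 1 over phase
vm_gain <- function(phase_deg, kappa, mu_deg) {
  if (kappa == 0) return(rep(1, length(phase_deg)))
  exp(kappa * cos(deg2rad(phase_deg - mu_deg))) / besselI(kappa, 0)
}

#' Ground truth for one synthetic cell
#'
#' Draws the latent parameters of one unit from the cohort-level
#' distributions in a \code{\link{sim_config}}: a log-normal baseline rate, a
#' log-normal von Mises concentration with a wrapped-normal preferred phase,
#' and (with the region's responsive fraction) a responsive odor subset with
#' a common excitatory gain, latency and duration. Uses the current RNG
#' stream.
#'
#' @param cell_id,region Identifiers carried into the truth record.
#' @param odor_ids Character vector of non-vehicle odorant identifiers.
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{cell_truth}.
#' @export
draw_cell_truth <- function(cell_id, region, odor_ids, config = sim_config()) {
  frac <- config$frac_responsive
  p_resp <- if (region %in% names(frac)) frac[[region]] else 0
  responsive <- stats::runif(1) < p_resp
  resp_odors <- character(0)
  if (responsive) {
    n_extra <- stats::rbinom(1, length(odor_ids) - 1L, config$prob_extra_odor)
    resp_odors <- sample(odor_ids, 1L + n_extra)
  }
  structure(list(
    cell_id = cell_id, region = region,
    baseline_hz = stats::rlnorm(1, meanlog = log(config$baseline_median_hz),
                                sdlog = config$baseline_sdlog),
    kappa = stats::rlnorm(1, meanlog = config$kappa_meanlog,
                          sdlog = config$kappa_sdlog),
    mu_deg = (stats::rnorm(1, config$mu_mean_deg, config$mu_sd_deg)) %% 360,
    responsive_odors = resp_odors,
    response_gain = config$response_gain,
    response_latency_s = config$response_latency_s,
    response_duration_s = config$response_duration_s),
    class = "cell_truth")
}

#' Simulate one cell's spike train by Poisson thinning
#'
#' Generates an inhomogeneous Poisson spike train with intensity
#' lambda(t) = baseline rate x von Mises respiratory gain
#' exp(kappa cos(phi(t) - mu)) / I0(kappa) x odor gain, where phi(t) is the
#' proportional phase within the containing respiration cycle (gain 1 outside
#' any cycle) and the odor gain applies from onset + latency for the response
#' duration, for the cell's responsive odors only. Candidates are drawn
#' homogeneously at the intensity upper bound and thinned, which samples the
#' target process exactly. Uses the current RNG stream.
#'
#' @param truth A \code{cell_truth}.
#' @param events An \code{\link{event_table}}.
#' @param cycles A \code{\link{resp_cycles}} ground-truth table.
#' @param duration_s Session duration in seconds.
#' @return A \code{\link{spike_train}}.
#' @export
simulate_cell_spikes <- function(truth, events, cycles, duration_s) {
  peak_vm <- if (truth$kappa == 0) 1 else
    exp(truth$kappa) / besselI(truth$kappa, 0)
  peak_gain <- if (length(truth$responsive_odors)) truth$response_gain else 1
  lam_max <- truth$baseline_hz * peak_vm * peak_gain
  n_cand <- stats::rpois(1, lam_max * duration_s)
  if (n_cand == 0L) return(spike_train(truth$cell_id, numeric(0)))
  t_cand <- sort(stats::runif(n_cand, 0, duration_s))

  # respiratory gain
  lam <- rep(truth$baseline_hz, n_cand)
  if (truth$kappa > 0 && nrow(cycles)) {
    idx <- findInterval(t_cand, cycles$cycle_start_s)
    inside <- idx >= 1L & t_cand < cycles$cycle_end_s[pmax(idx, 1L)]
    ph <- 360 * (t_cand[inside] - cycles$cycle_start_s[idx[inside]]) /
      (cycles$cycle_end_s[idx[inside]] - cycles$cycle_start_s[idx[inside]])
    lam[inside] <- lam[inside] * vm_gain(ph, truth$kappa, truth$mu_deg)
  }

  # odor-evoked transient gain
  if (length(truth$responsive_odors)) {
    resp_ev <- events[events$odor_id %in% truth$responsive_odors, , drop = FALSE]
    for (i in seq_len(nrow(resp_ev))) {
      a <- resp_ev$onset_s[i] + truth$response_latency_s
      b <- a + truth$response_duration_s
      on <- t_cand >= a & t_cand < b
      lam[on] <- lam[on] * truth$response_gain
    }
  }

  keep <- stats::runif(n_cand) < lam / lam_max
  times <- unique(t_cand[keep])
  times <- times[times < duration_s]
  spike_train(truth$cell_id, times)
}

# block-randomized presentation schedule: each block is one permutation of all
# channels, so every channel accrues n_trials presentations in pseudorandom
# order (uses current RNG stream)
build_schedule <- function(odor_ids, vehicle_id, config) {
  channels <- c(odor_ids, vehicle_id)
  order_all <- unlist(lapply(seq_len(config$n_trials),
                             function(b) sample(channels)))
  n <- length(order_all)
  period <- config$odor_dur_s + config$isi_s
  onsets <- config$isi_s + (seq_len(n) - 1L) * period
  event_table(order_all, order_all == vehicle_id, onsets,
              onsets + config$odor_dur_s)
}

#' Simulate a full cohort of sessions with retained ground truth
#'
#' Builds one session per synthetic subject (each subject contributes
#' \code{cells_per_subject} units from a single region), with a
#' block-randomized presentation schedule over the odorant panel plus vehicle,
#' a respiration trace with known cycle boundaries, and inhomogeneous Poisson
#' spike trains per cell. The master seed determines per-subject and per-cell
#' substreams, so a fixed seed reproduces the cohort exactly.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{synthetic_cohort}: \code{sessions} (list of
#'   \code{os_session}), \code{truth} (data.frame, one row per cell with all
#'   latent parameters), \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  regions <- rep(names(config$n_cells), config$n_cells)
  n_total <- length(regions)
  if (n_total == 0L) stop("simulate_cohort: no cells requested", call. = FALSE)
  odor_ids <- sprintf("odor%02d", seq_len(config$n_odorants))
  vehicle_id <- "vehicle"

  # assign cells to subjects (one region per subject)
  subj_of <- integer(n_total)
  next_subj <- 0L
  for (rg in unique(regions)) {
    idx <- which(regions == rg)
    grp <- ceiling(seq_along(idx) / config$cells_per_subject)
    subj_of[idx] <- next_subj + grp
    next_subj <- next_subj + max(grp)
  }
  n_subj <- max(subj_of)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subj)

  sessions <- vector("list", n_subj)
  truth_rows <- vector("list", n_total)
  for (s in seq_len(n_subj)) {
    set.seed(subj_seeds[s])
    cells_idx <- which(subj_of == s)
    region <- regions[cells_idx[1L]]
    subject_id <- sprintf("subj%02d", s)
    sex <- if (s %% 2L) "F" else "M"

    evs <- build_schedule(odor_ids, vehicle_id, config)
    duration_s <- max(evs$offset_s) + config$isi_s
    resp <- simulate_respiration(duration_s, config)

    ids <- sprintf("cell%03d", cells_idx)
    spikes <- list()
    for (j in seq_along(cells_idx)) {
      tr <- draw_cell_truth(ids[j], region, odor_ids, config)
      spikes[[ids[j]]] <- simulate_cell_spikes(tr, evs, resp$cycles, duration_s)
      truth_rows[[cells_idx[j]]] <- data.frame(
        cell_id = tr$cell_id, subject_id = subject_id, region = region,
        sex = sex, baseline_hz = tr$baseline_hz, kappa = tr$kappa,
        mu_deg = tr$mu_deg,
        n_responsive = length(tr$responsive_odors),
        responsive_odors = paste(tr$responsive_odors, collapse = ";"),
        response_gain = tr$response_gain,
        response_latency_s = tr$response_latency_s,
        response_duration_s = tr$response_duration_s)
    }
    cells <- cell_table(ids, region, subject_id, sex)
    sessions[[s]] <- session(cells, spikes, evs, duration_s, resp$trace)
  }
  structure(list(sessions = sessions,
                 truth = do.call(rbind, truth_rows),
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' One session subdirectory per subject (\code{\link{write_session}} dialect),
#' plus \code{ground_truth.csv} and a \code{config.txt} key-value echo
#' recording every generator setting including the seed.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$sessions)) {
    write_session(cohort$sessions[[s]],
                  file.path(dir, sprintf("session%02d", s)))
  }
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  flat <- vapply(cfg, function(v) paste(
    if (!is.null(names(v))) sprintf("%s:%s", names(v), v) else as.character(v),
    collapse = ","), "")
  write_kv(flat, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read back a cohort of session directories
#'
#' @param dir Directory containing session subdirectories (any subdirectory
#'   with a \code{manifest.txt} is loaded).
#' @return List of \code{os_session}.
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "manifest.txt"))]
  if (!length(subs)) stop("read_cohort: no session directories in ", dir,
                          call. = FALSE)
  lapply(subs, read_session)
}
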