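# Small deterministic fixtures built in code.

# hand-built two-cell session: 12 events (2 odors + vehicle, 4 trials each)
make_fixture_session <- function(with_respiration = TRUE) {
  odors <- rep(c("octanal", "limonene", "vehicle"), times = 4)
  onsets <- 28 + (seq_along(odors) - 1) * 30
  ev <- event_table(odors, odors == "vehicle", onsets, onsets + 2)
  duration <- max(ev$offset_s) + 28
  cells <- cell_table(c("cA", "cB"), c("DTT", "AON"), c("s1", "s1"),
                      c("F", "F"))
  set.seed(99)
  spikes <- list(cA = sort(runif(300, 0, duration - 0.001)),
                 cB = numeric(0))
  resp <- NULL
  if (with_respiration) {
    fs <- 100
    t <- seq(0, duration - 1 / fs, by = 1 / fs)
    resp <- respiration_trace(sin(2 * pi * 3 * t), fs)
  }
  session(cells, spikes, ev, duration, resp)
}

# fixed ground truth for low-level simulator calls
make_truth <- function(id = "c", baseline = 2, kappa = 0, mu = 0,
                       odors = character(0), gain = 1, latency = 0.4,
                       duration = 6) {
  structure(list(cell_id = id, region = "DTT", baseline_hz = baseline,
                 kappa = kappa, mu_deg = mu, responsive_odors = odors,
                 response_gain = gain, response_latency_s = latency,
                 response_duration_s = duration), class = "cell_truth")
}

# tiny synthetic cohort for structural tests (fast: short panel, few trials)
make_tiny_cohort <- function(seed = 7, ...) {
  simulate_cohort(sim_config(n_cells = c(DTT = 2, AON = 2), n_odorants = 3,
                             n_trials = 4, seed = seed, ...))
}
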