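test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- make_tiny_cohort(seed = 5)
  c2 <- make_tiny_cohort(seed = 5)
  expect_identical(c1$truth, c2$truth)
  for (s in seq_along(c1$sessions)) {
    expect_identical(c1$sessions[[s]]$spikes, c2$sessions[[s]]$spikes)
    expect_identical(c1$sessions[[s]]$respiration$values,
                     c2$sessions[[s]]$respiration$values)
  }
  c3 <- make_tiny_cohort(seed = 6)
  expect_false(identical(c1$sessions[[1]]$spikes, c3$sessions[[1]]$spikes))
})

test_that("cycle durations honour the configured mean and CV", {
  set.seed(51)
  cfg <- sim_config(resp_rate_hz = 3, resp_cycle_cv = 0)
  sim <- simulate_respiration(30, cfg)
  dur <- sim$cycles$cycle_end_s - sim$cycles$cycle_start_s
  expect_true(all(abs(dur - 1 / 3) < 1e-12))  # CV = 0: perfectly periodic

  sim2 <- simulate_respiration(60, sim_config(resp_rate_hz = 3,
                                              resp_cycle_cv = 0.15))
  n <- nrow(sim2$cycles)
  expect_lt(abs(n - 180), 3 * sqrt(180))
  d2 <- sim2$cycles$cycle_end_s - sim2$cycles$cycle_start_s
  expect_lt(abs(sd(d2) / mean(d2) - 0.15), 0.05)
})

test_that("the trace rises through zero at each ground-truth cycle start", {
  set.seed(52)
  cfg <- sim_config(resp_noise_sd = 0)
  sim <- simulate_respiration(20, cfg)
  fs <- sim$trace$sample_rate_hz
  starts <- sim$cycles$cycle_start_s[-1]
  i <- round(starts * fs) + 1
  before <- sim$trace$values[i - 1]
  after <- sim$trace$values[i + 1]
  expect_true(all(before < 0 & after > 0))
})

test_that("an unmodulated non-responsive cell is homogeneous Poisson at baseline", {
  set.seed(53)
  truth <- structure(list(cell_id = "c", region = "DTT", baseline_hz = 2,
                          kappa = 0, mu_deg = 0,
                          responsive_odors = character(0),
                          response_gain = 1, response_latency_s = 0,
                          response_duration_s = 0), class = "cell_truth")
  dur <- 600
  cfg <- sim_config()
  sim <- simulate_respiration(dur, cfg)
  st <- simulate_cell_spikes(truth, event_table(character(0), logical(0),
                                                numeric(0), numeric(0)),
                             sim$cycles, dur)
  n <- length(st$times)
  expect_lt(abs(n - 2 * dur), 3 * sqrt(2 * dur))
  # exponential ISIs: CV near 1
  expect_lt(abs(isi_cv(diff(st$times)) - 1), 0.1)
})

test_that("von Mises respiratory gain preserves the mean rate and peaks at mu", {
  set.seed(54)
  truth <- structure(list(cell_id = "c", region = "DTT", baseline_hz = 3,
                          kappa = 1, mu_deg = 30,
                          responsive_odors = character(0),
                          response_gain = 1, response_latency_s = 0,
                          response_duration_s = 0), class = "cell_truth")
  dur <- 600
  sim <- simulate_respiration(dur, sim_config())
  st <- simulate_cell_spikes(truth, event_table(character(0), logical(0),
                                                numeric(0), numeric(0)),
                             sim$cycles, dur)
  n <- length(st$times)
  # gain normalized by I0(kappa): off-odor rate equals baseline
  expect_lt(abs(n - 3 * dur), 3 * sqrt(3 * dur))
  # emitted spike phases concentrate at mu
  ps <- assign_spike_phases(st$times, sim$cycles)
  pv <- phase_vector(ps)
  expect_lt(circ_diff_deg(pv$theta_deg, 30), 10)
  expect_gt(pv$rho, 0.2)
})

test_that("thinning passes a time-rescaling KS check on modulated cells", {
  set.seed(55)
  cfg <- sim_config()
  rejections <- 0L
  n_cells <- 20L
  for (k in seq_len(n_cells)) {
    sim <- simulate_respiration(150, cfg)
    truth <- structure(list(cell_id = "c", region = "DTT", baseline_hz = 3,
                            kappa = 1, mu_deg = runif(1, 0, 360),
                            responsive_odors = character(0),
                            response_gain = 1, response_latency_s = 0,
                            response_duration_s = 0), class = "cell_truth")
    st <- simulate_cell_spikes(truth, event_table(character(0), logical(0),
                                                  numeric(0), numeric(0)),
                               sim$cycles, 150)
    # independent numeric reconstruction of the cumulative intensity
    tg <- seq(0, 150, by = 1e-3)
    idx <- findInterval(tg, sim$cycles$cycle_start_s)
    inside <- idx >= 1 & tg < sim$cycles$cycle_end_s[pmax(idx, 1)]
    lam <- rep(truth$baseline_hz, length(tg))
    phi <- 360 * (tg[inside] - sim$cycles$cycle_start_s[idx[inside]]) /
      (sim$cycles$cycle_end_s[idx[inside]] - sim$cycles$cycle_start_s[idx[inside]])
    lam[inside] <- truth$baseline_hz *
      exp(truth$kappa * cos((phi - truth$mu_deg) * pi / 180)) /
      besselI(truth$kappa, 0)
    Lam <- cumsum(lam) * 1e-3
    z <- diff(approx(tg, Lam, xout = st$times)$y)
    if (stats::ks.test(z, "pexp")$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, ceiling(0.05 * n_cells))
})

test_that("a null cohort produces z-scores centred on zero", {
  co <- simulate_cohort(sim_config(n_cells = c(DTT = 4), n_odorants = 5,
                                   n_trials = 6,
                                   frac_responsive = c(DTT = 0), seed = 8))
  s <- run_cohort(co, compare = c("DTT", "DTT"))
  z <- s$pairs$z[is.finite(s$pairs$z)]
  expect_lt(abs(mean(z)), 0.4)
})

test_that("cohort ground truth and sessions round-trip through disk", {
  co <- make_tiny_cohort(seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "config.txt")))
  sessions <- read_cohort(dir)
  expect_length(sessions, length(co$sessions))
  expect_identical(sessions[[1]]$spikes, co$sessions[[1]]$spikes)
  truth <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(truth), sum(vapply(co$sessions,
                                       function(s) nrow(s$cells), 0L)))
})

test_that("responsive cells carry programmed excitatory transients", {
  co <- simulate_cohort(sim_config(n_cells = c(DTT = 3), n_odorants = 4,
                                   frac_responsive = c(DTT = 1),
                                   baseline_sdlog = 0.2, seed = 10))
  expect_true(all(co$truth$n_responsive >= 1))
  expect_true(all(co$truth$response_gain >= 1))
  # odor-period rate for a responsive odor exceeds baseline on most trials
  s <- co$sessions[[1]]
  id <- co$truth$cell_id[1]
  resp_od <- strsplit(co$truth$responsive_odors[1], ";")[[1]][1]
  tr <- epoch_trials(s$spikes[[id]], s$events)
  tr <- tr[tr$odor_id == resp_od, ]
  expect_gt(mean(tr$odor_count > tr$baseline_count), 0.7)
})
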