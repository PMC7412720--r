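test_that("epoching counts spikes in half-open baseline and odor windows", {
  ev <- event_table("a", FALSE, 10, 12)
  tr <- epoch_trials(c(9.5, 10.5, 11.5), ev)
  expect_equal(tr$baseline_count, 1)
  expect_equal(tr$odor_count, 2)
  # a spike exactly at onset belongs to the odor period
  tr2 <- epoch_trials(10, ev)
  expect_equal(tr2$baseline_count, 0)
  expect_equal(tr2$odor_count, 1)
  # empty train gives zero counts
  tr3 <- epoch_trials(numeric(0), ev)
  expect_equal(tr3$baseline_count + tr3$odor_count, 0)
})

test_that("trials whose baseline precedes the session start are dropped with a warning", {
  ev <- event_table(c("a", "a"), c(FALSE, FALSE), c(2, 40), c(4, 42))
  expect_warning(tr <- epoch_trials(c(1, 41), ev), "dropped 1 trial")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$onset_s, 40)
})

test_that("epoched counts match a brute-force per-trial recount", {
  co <- make_tiny_cohort()
  s <- co$sessions[[1]]
  w <- analysis_windows()
  for (id in s$cells$cell_id) {
    tr <- epoch_trials(s$spikes[[id]], s$events, w)
    for (i in seq_len(nrow(tr))) {
      t0 <- tr$onset_s[i]
      expect_equal(tr$baseline_count[i],
                   length(which(s$spikes[[id]] >= t0 - 4 & s$spikes[[id]] < t0)))
      expect_equal(tr$odor_count[i],
                   length(which(s$spikes[[id]] >= t0 & s$spikes[[id]] < t0 + 4)))
    }
  }
})

test_that("response z-score follows the baseline-SD normalization", {
  w <- analysis_windows()
  # identical counts trial-by-trial: z = 0
  expect_equal(response_zscore(c(3, 5, 4), c(3, 5, 4), w), 0)
  # constant baseline with a different odor mean: infinite-z sentinel
  expect_identical(response_zscore(c(4, 4, 4, 4), c(8, 8, 8, 8), w), Inf)
  expect_identical(response_zscore(c(8, 8, 8, 8), c(4, 4, 4, 4), w), -Inf)
  # constructed set: baseline rates {0.5, 1, 1.5} Hz (mean 1, SD 0.5),
  # odor mean 2.5 Hz -> z = 3
  expect_equal(response_zscore(c(2, 4, 6), c(10, 10, 10), w), 3)
  expect_true(is.na(response_zscore(4, 8, w)))
})

test_that("z is shift-invariant in counts and antisymmetric for matched SDs", {
  w <- analysis_windows()
  b <- c(2, 4, 6, 3); o <- c(6, 3, 2, 4)  # permutation: equal SDs
  expect_equal(response_zscore(b, o, w), -response_zscore(o, b, w))
  # adding the same count to every window shifts both means equally and
  # leaves the baseline SD unchanged, so z is unchanged
  z0 <- response_zscore(b, c(5, 6, 9, 4), w)
  expect_equal(response_zscore(b + 2, c(5, 6, 9, 4) + 2, w), z0)
  # but scaling counts rescales numerator and denominator alike
  expect_equal(response_zscore(b * 3, c(5, 6, 9, 4) * 3, w), z0)
})

test_that("paired rank-biserial matches its enumeration oracle and boundary cases", {
  expect_equal(rank_biserial_paired(1:8), 1)
  expect_equal(rank_biserial_paired(-(1:5)), -1)
  expect_equal(rank_biserial_paired(c(2, -2)), 0)
  # {+3, +1, -2}: ranks 3, 1, 2 -> (4 - 2) / 6
  expect_equal(rank_biserial_paired(c(3, 1, -2)), 1 / 3)
  r0 <- rank_biserial_paired(rep(0, 4))
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))
  set.seed(31)
  for (i in 1:10) {
    x <- rpois(8, 6); y <- rpois(8, 5)
    expect_equal(as.numeric(rank_biserial_paired(x, y)),
                 oracle_rank_biserial(x, y))
  }
})

test_that("r_rb = 1 exactly when all nonzero differences are positive", {
  set.seed(32)
  for (i in 1:10) {
    d <- rnorm(10)
    r <- as.numeric(rank_biserial_paired(d))
    expect_identical(r == 1, all(d[d != 0] > 0))
  }
})

test_that("pair significance combines test, effect size and flags", {
  w <- analysis_windows()
  same <- test_pair_significance(c(3, 4, 5, 4), c(3, 4, 5, 4), w)
  expect_equal(same$p, 1)
  expect_false(same$significant)
  expect_equal(same$z, 0)

  b8 <- c(4, 5, 3, 4, 5, 3, 4, 5)
  up <- test_pair_significance(b8, b8 + (8:15), w)  # tie-free differences
  expect_equal(up$p, 2 / 256)
  expect_true(up$significant)
  expect_equal(up$r_rb, 1)
  expect_equal(up$mean_baseline_hz, mean(b8) / 4)
})

test_that("selectivity index follows the printed formula and its invariances", {
  expect_equal(selectivity_index(c(2, 2, 2)), 0)
  expect_equal(selectivity_index(c(0, 3)), 1)
  expect_equal(selectivity_index(c(2, 1, 0.5)), 0.6)
  expect_true(is.na(selectivity_index(2)))
  expect_true(is.na(selectivity_index(c(0, 0, 0))))
  set.seed(33)
  r <- runif(6, 0, 5)
  expect_equal(selectivity_index(r * 7.3), selectivity_index(r))
  expect_true(selectivity_index(r) >= 0 && selectivity_index(r) <= 1)
})

test_that("cohort classification counts flags exactly and excludes vehicle", {
  cells <- cell_table(c("c1", "c2", "c3"), c("DTT", "DTT", "AON"),
                      c("s1", "s1", "s2"))
  pairs <- data.frame(
    cell_id = rep(c("c1", "c2", "c3"), each = 3),
    odor_id = rep(c("o1", "o2", "vehicle"), 3),
    is_vehicle = rep(c(FALSE, FALSE, TRUE), 3),
    significant = c(TRUE, TRUE, TRUE,   FALSE, FALSE, FALSE,  TRUE, FALSE, FALSE),
    exceeds_sd = c(TRUE, FALSE, FALSE,  FALSE, FALSE, FALSE,  FALSE, FALSE, FALSE))
  cls <- classify_cohort(pairs, cells)
  dtt <- cls$region_summary[cls$region_summary$region == "DTT", ]
  expect_equal(dtt$n_pairs, 4)           # vehicle pairs excluded
  expect_equal(dtt$n_sig_pairs, 2)       # c1's significant vehicle not counted
  expect_equal(dtt$n_responsive_cells, 1)
  expect_equal(dtt$prop_responsive_cells, 0.5)
  expect_equal(dtt$n_exceed_sd, 1)
  aon <- cls$region_summary[cls$region_summary$region == "AON", ]
  expect_equal(aon$n_sig_pairs, 1)
  expect_equal(aon$prop_sig_pairs, 0.5)
  expect_error(classify_cohort(transform(pairs, cell_id = "ghost"), cells),
               "unknown cell_id")
})

test_that("classification of an all-null table gives zero proportions", {
  cells <- cell_table(c("c1", "c2"), c("DTT", "DTT"), c("s1", "s1"))
  pairs <- data.frame(cell_id = c("c1", "c2"), odor_id = "o1",
                      is_vehicle = FALSE, significant = FALSE,
                      exceeds_sd = FALSE)
  cls <- classify_cohort(pairs, cells)
  expect_equal(cls$region_summary$prop_sig_pairs, 0)
  expect_equal(cls$region_summary$n_responsive_cells, 0)
})

test_that("PSTH of a regular train is flat at the train's rate", {
  t <- seq(0.05, 200, by = 0.1)  # 10 Hz regular
  psth <- compute_psth(t, onsets = c(50, 100, 150), bin_width_s = 0.5,
                       span = c(-4, 8))
  expect_true(all(abs(psth$rate_hz - 10) < 1e-9))
  expect_true(all(psth$sem_hz < 1e-9))
  # single trial: SEM undefined
  p1 <- compute_psth(t, onsets = 50)
  expect_true(all(is.na(p1$sem_hz)))
  expect_equal(p1$n_trials, 1)
})

test_that("PSTH peak lands within one bin of a programmed transient", {
  set.seed(34)
  onsets <- seq(30, 30 * 40, by = 30)
  latency <- 0.6
  spikes <- sort(unlist(lapply(onsets, function(o)
    o + latency + runif(40, 0, 0.25))))
  psth <- compute_psth(spikes, onsets, bin_width_s = 0.25, span = c(-2, 4))
  peak <- psth$centers[which.max(psth$rate_hz)]
  expect_lt(abs(peak - (latency + 0.125)), 0.25 + 1e-9)
})

test_that("grand-average PSTH reduces correctly", {
  t <- seq(0.05, 100, by = 0.1)
  p <- compute_psth(t, onsets = c(30, 60), bin_width_s = 0.5)
  g1 <- grand_average_psth(list(p))
  expect_equal(g1$rate_hz, p$rate_hz)
  g2 <- grand_average_psth(list(p, p))
  expect_true(all(g2$sem_hz < 1e-12))
  expect_equal(g2$rate_hz, p$rate_hz)
  expect_null(grand_average_psth(list()))
  p_bad <- compute_psth(t, onsets = 30, bin_width_s = 0.5, span = c(-2, 4))
  expect_error(grand_average_psth(list(p, p_bad)), "bin grids")
})
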