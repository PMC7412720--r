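---
title: "Methods: odor-evoked and respiration-coupled spike-train analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-evoked and respiration-coupled spike-train analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorspike)
```

# The setting and the data model

The package analyses single-unit extracellular recordings made while a
panel of monomolecular odorants (plus a mineral-oil vehicle channel) is
presented in timed pulses — the typical anesthetized-rodent design: 2 s odor
pulses separated by 28 s interstimulus intervals, around 8 trials per
odorant over a panel of 5–13 odorants, with chest-wall respiration recorded
alongside. A *session* bundles sorted spike times per unit, the odor event
table, optional respiration trace, and unit metadata (region, subject,
sex). Spike sorting is upstream of this package: the input is spike
*times*, not waveforms.

Time is in seconds from session start and every epoch is half-open
`[start, end)`, so a spike coinciding exactly with odor onset belongs to
the odor period and no spike can be counted twice. Sessions serialise to a
plain-text directory (CSV files plus a key–value manifest) with numerics
printed at full binary precision, so a written-and-reread session is
identical to the original.

# Spontaneous activity

Spontaneous metrics use only the final `spont_tail` (default 10) seconds of
each interstimulus interval — the tail is the part of the gap in which
residual odor has cleared. Gaps shorter than the tail contribute their full
length (the default 28 s schedule makes this rare); segments before the
first and after the last presentation are not interstimulus intervals and
are excluded. ISIs are pooled across all tails into a single distribution,
and intervals spanning a window boundary are discarded, so no ISI ever
bridges an odor presentation. The rate is `1 / mean(ISI)` and the
variability is `CV = sd(ISI) / mean(ISI)` with the sample (n−1) SD — with
hundreds of ISIs the population/sample distinction is negligible, but the
choice is fixed and tested. Cells with fewer than two qualifying ISIs carry
`NA` metrics rather than a crash or a zero.

# Odor-response statistics

For each presentation, spikes are counted in the 4 s baseline window
immediately before onset and the 4 s odor window from onset. Trials whose
baseline would begin before the session start are dropped with a warning.
Per odor–cell pair:

* **z-score**: per-trial rates are counts divided by the window duration;
  `z = (mean odor rate − mean baseline rate) / sd(baseline rates)` with the
  sample SD across trials. Trial-wise baseline SD is the minimal structure
  consistent with a per-pair statistic; a pooled-bin SD would need a bin
  width the design does not define. If the baseline SD is zero, z is 0 when
  the means agree and a signed infinite sentinel otherwise (rank-based
  significance is unaffected; the sentinel simply marks the strong-response
  flag as satisfied for positive differences).
* **Rank-biserial effect size**: zero differences are discarded, absolute
  differences are average-ranked, and
  `r = (Σ ranks⁺ − Σ ranks⁻) / Σ ranks`. `r = 1` exactly when every nonzero
  difference is positive.
* **Significance**: a two-sided Wilcoxon signed-rank test on the paired
  counts at `alpha_pair = 0.01` per pair, with *no* multiple-testing
  correction across pairs — the published classification rule this package
  reproduces is per-pair, and correcting would change what is being
  reproduced.
* **Strong responses**: pairs with `z ≥ sd_threshold` (default 3) feed the
  grand-average PSTH. PSTHs default to 100 ms bins over −4 s to +8 s around
  onset; bin width is a display resolution, not an inference parameter, and
  is configurable.

The **selectivity index** `(maxrate − minrate) / (maxrate + minrate)` is
computed over a cell's mean odor-period rates with the vehicle omitted. For
nonnegative rates it lies in [0, 1]; it is `NA` when fewer than two
odorants have rates or all rates are zero. (Published cohort medians above
1 for this quantity imply some unstated rate transformation upstream of the
formula; the formula here is implemented exactly as printed, and nothing in
the package asserts values above 1.)

The vehicle channel is tested like any odorant — a negative control should
be examined, not skipped — but is excluded from selectivity and from all
responsiveness proportions.

## Exact small-sample testing and the tie policy

With ~8 paired integer counts, the discreteness of the signed-rank
distribution dominates: the smallest attainable two-sided p is `2/2⁸ =
0.0078`, achieved only by a perfectly consistent direction. Tied absolute
differences are the *norm* for count data, and the common software fallback
(tie-corrected normal approximation) yields p ≈ 0.014 for a perfect 8/8
response — silently making a per-pair criterion of p < 0.01 unattainable at
this trial count. `wilcoxon_signed_rank()` therefore keeps an exact method
for small samples in both regimes: the classical signed-rank distribution
when the absolute differences are tie-free (n ≤ 25), and the full
permutation distribution of the average signed ranks when ties are present
(n ≤ 15; the 2ⁿ sign assignments are aggregated by convolution over doubled
ranks, so average ranks stay integral). Zero differences are discarded
before ranking, the standard convention. Beyond those sizes the
tie-corrected normal approximation with continuity correction takes over;
at n = 25 the two agree within a few percent. `mann_whitney_u()` (used for
interregional and sex comparisons, where data are continuous metrics and
ties are incidental) is exact for tie-free samples up to n = 25 per group
and tie-corrected otherwise. Both tests are two-sided throughout: the
excitatory-only character of the responses is an empirical finding, not an
analysis assumption.

# Respiratory phase analysis

Breathing cycles are segmented by band-limiting the raw sensor signal
(zero-phase 2nd-order Butterworth, default passband 1–15 Hz — wide enough
for 2–4 Hz anesthetized breathing and its waveform harmonics, while
removing drift and spike bleed-through) and taking signed zero crossings,
linearly interpolated between samples, as cycle boundaries. Cycles with
durations outside 0.1–2 s (0.5–10 Hz) are discarded as non-physiologic, as
are cycles within 0.5 s of the trace edges, where the filter's warm-up
distorts crossings.

**Phase-origin convention.** Which respiratory landmark a zero crossing
marks depends on sensor polarity and placement, and descriptions of the
origin in this literature are genuinely ambiguous (inspiration onset vs the
inhalation–exhalation transition differ by half a cycle). The package makes
the convention explicit rather than guessing: `direction = "rising"`
(default) or `"falling"` selects the crossing, and the synthetic trace
defines the reference — it rises through zero at each ground-truth cycle
start, so the default recovers the generator's cycle table and programmed
phases exactly.

Each spike within a detected cycle receives the proportional phase
`360 · (t − start) / duration`, which stretches variable-duration cycles
onto a common circular axis; spikes outside every detected cycle are
dropped and counted. Phase statistics pool spikes from the 8 s window
beginning at every odor onset (all channels, vehicle included), the window
in which both evoked and ongoing activity are of interest; pooling across
trials is the default reading of a per-cell phase statistic. Phases are
binned at 6° (60 bins), each bin contributes a vector at its centre with
magnitude equal to its count, and the normalized vector sum gives θ
(preferred phase) and ρ (modulation depth). Binning quantizes θ by at most
±3° and attenuates ρ by the factor sinc(3°) ≈ 0.9995 — both negligible
against biological variability, and the binned estimate is tested to agree
with the unbinned resultant within those bounds.

The Rayleigh statistic is `Z = nρ²` with the small-sample-corrected
closed-form p-value `exp(√(1 + 4n + 4(n² − R²)) − (1 + 2n))`, `R = nρ`,
clamped to [0, 1]; the test requires n ≥ 4 and is flagged `NA` below that.
Calibration on uniform phases (5,000 simulated cells of 100 spikes) puts
the empirical rejection rate at α = 0.01 close to nominal (≈0.009–0.012).
Cells passing the Rayleigh test are additionally checked for unimodality by
comparing the resultant length at the fundamental (R₁) against the doubled
angle (R₂): an antipodally balanced bimodal distribution concentrates power
in the second harmonic, so `unimodal = (R₁ ≥ R₂)`. This check is
deterministic and assertable, which is why it was chosen over fitting
mixture models. Population phase preferences are angles of unit-vector sums
over the significant unimodal cells.

# The synthetic-session generator

The generator exists so that every stage has ground truth to recover. It
emulates the assumed statistical structure of the recordings:

* **Spontaneous rates** are log-normal across cells (median 1.4 Hz,
  σ_log = 1), matching the typical 1–2 Hz cohort medians of
  anesthetized olfactory-cortex recordings and the heavy right tail of
  cortical rate distributions.
* **Respiration** is a sequence of gamma-distributed cycle durations (mean
  rate 3 Hz, CV 0.15 by default — anesthetized-mouse breathing; both
  configurable), rendered as one sinusoid period per cycle plus additive
  noise, with the ground-truth cycle table retained.
* **Respiratory coupling** multiplies the baseline rate by a normalized von
  Mises gain `exp(κ cos(φ − μ)) / I₀(κ)`, which averages to 1 over a cycle,
  so coupling reshapes timing without changing mean rate. κ is log-normal
  across cells (median 0.8) and μ is drawn around 25° (SD 15°), placing
  preferred phases just after the cycle origin as observed in this
  preparation.
* **Odor responses** are excitatory multiplicative transients (default gain
  4× from 0.4 s after onset for 6 s — beginning within the first couple of
  respiratory cycles and outlasting the 2 s pulse). Per region, a
  configurable fraction of cells is responsive; a responsive cell's odor
  subset has binomial breadth (1 + Binomial(panel−1, 0.25), median ≈ 3–4 of
  11). Inhibitory responses are deliberately absent by default, matching
  the excitatory-only response profile this design reproduces.
* **Spiking** is an inhomogeneous Poisson process sampled exactly by
  thinning against the intensity's upper bound; a time-rescaling
  Kolmogorov–Smirnov check on modulated cells verifies the sampler.
* **Schedule** is block-randomized: each block is one permutation of all
  channels (odorants + vehicle), repeated `n_trials` times, giving the
  pseudorandom interleaving of the acquisition protocol. A master seed
  derives per-subject substreams, so cohorts are exactly reproducible.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify about real data: bursting and other
non-Poisson ISI structure (simulated CVs sit at 1), rate drift and
anesthesia-depth nonstationarity, correlated variability across
simultaneously recorded cells, sniff-frequency dynamics and inhalation
asymmetry in the respiration waveform, inhibitory or biphasic odor
responses, and spike-sorting contamination. Results on real recordings
inherit all of those caveats.

# Validation problem sizes

The packaged checks run at the scale the analyses are meant for: Rayleigh
calibration on 5,000 uniform cells × 100 spikes; phase recovery on 200
cells of ~1,000 spikes (κ = 1, μ = 30°, recovered within ±5°) with ρ
strictly increasing over κ ∈ {0, 0.5, 1, 2}; exact-test agreement with
brute-force enumeration at n ≤ 10; classifier type-I error over 5,005
simulated null pairs (observed ≈ 0.003–0.008 against the 0.01 criterion —
conservative because the discrete exact test cannot attain 0.01 itself);
spontaneous-metric recovery on 10,000-ISI exponential trains; and
end-to-end recovery of programmed responsive fractions (0.30/0.11, n = 37
per region, within exact binomial 95% intervals) and a programmed 25°
population phase (within ±5°) from a full two-region cohort.

```{r example, eval = FALSE}
cfg <- sim_config(n_cells = c(DTT = 37, AON = 37),
                  frac_responsive = c(DTT = 0.30, AON = 0.11),
                  mu_mean_deg = 25, seed = 1)
summary <- run_cohort(simulate_cohort(cfg))
summary$region_summary
```

# Known limitations

* The exact tied-rank permutation test is enumerated only to n = 15; larger
  tied samples fall back to the corrected normal approximation, whose
  two-sided p can differ by a few percent near criterion boundaries.
* Cycle segmentation assumes a roughly sinusoidal band-limited sensor
  signal; strongly asymmetric or clipped respiration waveforms may shift
  the effective phase origin relative to the physiological landmark, which
  is why the crossing direction is exposed as a parameter rather than
  fixed.
* Phase statistics pool across all trials and channels within the 8 s
  post-onset windows; odor-conditional phase analyses are possible via
  `assign_spike_phases()` on event subsets but are not a packaged summary.
* The infinite-z sentinel for zero baseline variance is reported as `Inf`
  rather than a capped value; downstream medians use it only through the
  strong-response flag.
* Selectivity is undefined (NA) for silent cells (all odor-period rates
  zero), which slightly biases cohort selectivity medians toward active
  cells.
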