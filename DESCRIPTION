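Package: odorspike
Title: Odor-Evoked and Respiration-Coupled Single-Unit Spike Train Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of single-unit extracellular recordings collected during
    timed odorant presentation: spontaneous firing-rate and interspike-interval
    variability metrics, trial-epoched odor-response statistics
    (baseline-normalized z-scores, paired rank-biserial effect sizes, exact
    Wilcoxon signed-rank significance, selectivity indices, peristimulus time
    histograms), and respiration phase-locking analysis (proportional phase
    assignment across variable-duration breathing cycles, binned resultant
    vectors, Rayleigh tests, unimodality checks, population phase summaries).
    Includes an inhomogeneous-Poisson synthetic-session generator with
    log-normal spontaneous rates, von Mises respiratory gain, and programmable
    odor-selective excitatory transients, so the full pipeline can be
    calibrated and validated against retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
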