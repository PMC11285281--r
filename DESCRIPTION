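Package: lprx
Title: Long-Pressure-Reactivity Index Derivation and Critical-Threshold Scanning
Version: 0.1.0
Authors@R: person("NCCU", "Analytics", email = "nccu.analytics@example.org", role = c("aut", "cre"))
Description: Derives the long-pressure-reactivity index (LPRx) -- a moving
    Pearson correlation between minute-by-minute intracranial pressure (ICP)
    and mean arterial pressure (MAP) samples -- from sporadically sampled
    neuromonitoring time series, and locates critical LPRx and ICP thresholds
    for dichotomized long-term outcome by a sequential chi-square scan.
    Includes artifact and drainage-interval cleaning, gap-limited imputation,
    segment-level burden summaries (grand means and percent time above
    threshold), monitor-type subgrouping, Mann-Whitney cohort comparisons,
    and a synthetic-cohort generator with known per-patient cerebrovascular
    reactivity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
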