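Package: phaseslope
Title: Anticipation Slopes and Population Synchronization for Fly Activity Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Drosophila locomotor activity recorded with Trikinetics
    DAM2 monitors under multi-phase light and temperature entrainment protocols.
    Reads and writes the DAM2 tab-separated format, represents environmental
    schedules (LD, LL, DD and 12h:12h temperature cycles) with Zeitgeber-time
    mapping, bins per-minute counts into 30-minute bins, normalizes each fly to
    its own maximum, and computes population median activity profiles. On top of
    these it implements an anticipation-slope statistic for the activity increase
    preceding an environmental transition: the slope of the population median
    between activity-minimum and activity-maximum landmarks (Slo_the), the median
    of the per-fly slopes over the same landmarks (Slo_exp), their ratio as a
    population-synchronization index, and a half-threshold classifier of
    anticipating versus non-anticipating flies, including the mirrored downhill
    variant for free-running days. A labeled inhomogeneous-Poisson generator of
    synthetic activity data, figure functions (double-plotted actograms, daily
    profiles, slope box plots) and a one-call pipeline make every stage runnable
    and testable without external recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
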