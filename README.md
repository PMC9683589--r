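# phaseslope

Quantifying clock-driven **anticipation** and **population synchronization**
in *Drosophila* locomotor activity recorded with Trikinetics DAM2 monitors,
under entrainment protocols that combine light–dark cycles (LD), constant
light or darkness (LL/DD) and 12 h:12 h 25 °C:16 °C temperature cycles in
constant light or darkness (LLTC/DDTC), including phase shifts between
regimes.

A circadian clock announces itself as a gradual activity ramp *before* a
predictable environmental transition; an acute burst *at* the transition (the
startle response) needs no clock. `phaseslope` turns per-minute beam-crossing
counts into 30-min binned, per-fly max-normalized activity, builds the
population median profile of an analysis day, and measures the ramp between
two landmarks on that profile — the latest minimum (ZT_min) and the first
maximum before the transition (ZT_max, startle bin excluded):

```
Slope    = (Act_max − Act_ZTmin) / (t_ZTmax − t_ZTmin)     [% of max / min]
Slo_the  = slope of the population median profile
Slo_exp  = median of the individual per-fly slopes (same landmarks)
```

The ratio **Slo_exp / Slo_the** is a population-synchronization index: ≈ 1
when most individuals behave like the median, well below 1 when they do not.
A fly is classified **anticipating** when its own slope exceeds ½ · Slo_the.
A mirrored *downhill* analysis covers the post-peak activity decline on
free-running days, and group comparisons (Kruskal–Wallis; seeded bootstrap of
mean differences) are built in. A labeled inhomogeneous-Poisson generator of
synthetic populations — synchronized, misphased, and clock-disrupted
(unconsolidated tonic activity) phenotypes — makes the whole pipeline
runnable and testable without any recordings.

Who this is for: chronobiologists analyzing DAM-style activity data who want
the anticipation-slope statistic, its synchronization ratio and classifier as
a tested, scriptable pipeline rather than a spreadsheet procedure.

## Worked example

```r
library(phaseslope)

protocol <- standard_protocol("LLTC", days_ld = 2, days_constant = 3,
                              days_tc = 6, shift_h = 5)

# a synchronized control population, 60 flies
sim  <- simulate_population(sim_preset("control_LLTC", n_flies = 60, seed = 42),
                            protocol)
prep <- daily_profile(sim$matrix, protocol, "TC6")   # 6th temperature-cycle day
analyze_slopes(prep$norm, prep$profile, transition_zt = 720)
#> <slope_analysis> (uphill) n = 60 flies
#>   landmarks: ZT_min 8.0 h (act 3.2), ZT_max 11.0 h (act 63.6)
#>   Slo_the = 0.34, Slo_exp = 0.34, ratio = 1.00
#>   anticipating: 100.0%

# half the flies clock-disrupted
mut   <- simulate_population(sim_preset("cycDN_like", n_flies = 60, seed = 42),
                             protocol)
prep2 <- daily_profile(mut$matrix, protocol, "TC6")
analyze_slopes(prep2$norm, prep2$profile, transition_zt = 720)
#> <slope_analysis> (uphill) n = 60 flies
#>   landmarks: ZT_min 6.5 h (act 7.4), ZT_max 11.5 h (act 58.5)
#>   Slo_the = 0.17, Slo_exp = 0.09, ratio = 0.55
#>   anticipating: 50.0%
```

Reading this: the control population rises from 3.2% to 63.6% of each fly's
maximum between ZT 8 h and ZT 11 h (slope 0.34 %/min); the median fly has the
same slope as the median profile (ratio 1.00) and every fly clears the
half-threshold. In the disrupted population the median profile still shows a
ramp (Slo_the 0.17) but the median individual slope is half of it (ratio
0.55), and only half the flies anticipate the cold transition — the signature
of a desynchronized population.

Everything above is also available as one call driven by a YAML config
(`run_pipeline("config.yaml")`), which writes the normalized activity and
profile CSVs, a slope-analysis JSON, figures (daily profile with landmark
markers, double-plotted actogram, slope box plots) and a provenance log.
DAM2 monitor files are read with `read_dam2()` and written with
`write_dam2()`; write → read is lossless.

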