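# xlf — X-ray lung function from cinematic chest radiography

Assessing lung function in mouse models of allergic airway disease usually
means plethysmography, which either restrains the animal or lacks
sensitivity. An alternative is to film the chest of an unrestrained,
lightly anesthetized mouse with low-dose planar cinematic radiography: air
content modulates x-ray transmission, so the mean transmission over the
lung rises and falls with every breath. `xlf` implements the complete
analysis chain for that measurement, for preclinical researchers comparing
healthy, inflamed and treated cohorts or quantifying airway responsiveness
to methacholine.

## What it computes

From a radiograph movie (multi-page TIFF) plus lung/background ROIs, the
package extracts the **x-ray transmission function**

    XTF(t) = (L(t) − B(t)) / mean(B),

the lung-minus-background transmission normalized by the time-averaged
background (unitless, tube-fluctuation free), detrends it (200-sample
moving average, order-2 polynomial subtraction), and detects **breathing
events** as maximal excursions above a scan line at
`mean(XTF) + 0.33·sd(XTF)`. Each event is parameterized with the shifted
cubic

    P(x) = b2·(x−b1)³ − b3·(x−b1)² − b4·(x−b1) + b5,

with `x` in samples from the event start: `b1` = time-to-peak, `b3` =
peak curvature (air-flow dynamic), `b5` = peak height (maximal relative
air content), `b2`/`b4` = asymmetry, plus the relative inspiration time
`t_in[%] = 100·b1·dt/duration`. Scans are summarized by the per-cycle
averages plus respiratory rate and slope extrema, and compared across
groups with unpaired Welch t-tests (margins p < 0.1 and p < 0.05);
methacholine responsiveness is analyzed as per-animal relative change to
baseline over 0/3/10/50 mg/ml. A synthetic-data generator with exact
ground truth (cubic-model pulses, tube drift, detector noise, cohort
effect-size presets) makes every stage testable without animal data, and a
VOI module quantifies soft-tissue `vol.ratio` and mean δ-value in
phase-contrast lung CT volumes.

## Worked example

```r
library(xlf)

sim <- simulate_trace(trace_sim_config(noise_sd = 0.02, seed = 1))
res <- analyze_trace(sim$trace)
round(res$summary[, c("b1", "b3", "b5", "t_in_pct", "n_events", "bpm")], 4)
#>       b1     b3     b5 t_in_pct n_events     bpm
#> 1 9.3581 0.0033 0.9997  47.3338       24 42.3529
```

24 breathing events were detected in the 34 s scan (42.4 breaths/min); the
peak sits 9.36 samples (312 ms) into the average event, at 47.3% of its
duration, with peak height 1.00 — matching the generator's settings
(amplitude 1, inspiration fraction 0.45).

Comparing simulated healthy (CN) and inflamed (SAA) cohorts of 6 animals:

```r
su  <- cohort_summaries(simulate_cohort(cohort_sim_config(
         groups = cohort_presets()[c("CN", "SAA")], seed = 1)))
cmp <- compare_groups(su)   # b1, b3, b5, t_in_pct
cmp[, c("parameter", "mean1", "mean2", "t_stat", "p_value", "sig_005")]
#>   parameter    mean1    mean2 t_stat  p_value sig_005
#> 1        b1  8.31164  9.12811  -5.16 4.36e-04    TRUE
#> 2        b3  0.00709  0.00247  17.13 2.01e-07    TRUE
#> 3        b5  1.01882  0.59092   9.78 2.07e-05    TRUE
#> 4  t_in_pct 46.74251 43.21765   7.30 3.92e-04    TRUE
```

The inflamed group shows the disease signature: later absolute peak
(higher `b1`) yet relatively shorter inspiration (lower `t_in`), with
reduced air-flow dynamic (`b3`) and peak air content (`b5`), all at
p < 0.05.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/xlf.R extract --stack movie.tif --roi roi.json --rate 30 --out trace.csv
Rscript inst/cli/xlf.R analyze --trace trace.csv --out summary.json
```

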