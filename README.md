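# oligoflux

Quantitative analysis of amyloid-aggregation inhibitor screens, built for
experiments like antibody scanning against α-synuclein: a panel of designed
single-domain antibodies (DesAbs) is incubated with aggregating protein and
ranked by how strongly each suppresses the generation of oligomeric
species, then characterized by binding assays and single-molecule imaging.

The package covers the full analysis chain, tidyverse-style (data frames
in, tibbles out):

* **Kinetics** — normalize thioflavin-T (ThT) traces; fit the linear
  elongation phase of highly seeded reactions (slope = 2·k₊·P(0)·m(0));
  fit low-seeded, secondary-nucleation-dominated reactions with the
  generalized logistic (Richards) curve
  M(t) = (1 + a·e^(−κt))^(−1/c), c fixed at 0.3, where κ is the
  effective fibril-amplification rate.
* **Oligomer flux** — the package's core: from a fitted M(t) and the
  elongation rate r₊, the net rate of oligomer generation
  φ(t) = dP/dt with P = (dM/dt)/(r₊(1−M)) evaluates in closed form as a
  non-negative bell, summarized by its peak height (φ_Peak), area
  (φ_Area = κ/r₊ − P(0), the total oligomers formed) and peak time
  (φ_Time), each reported relative to the control-condition mean. An
  effective inhibitor pushes the relative peak and area below 1 and the
  relative peak time above 1.
* **Binding** — saturation-binding fits Y = B_max·x/(K_d + x) for
  thermophoresis titrations (16-point 1:1.75 serial dilutions), response
  flooring, and reference/baseline subtraction for biolayer-interferometry
  traces.
* **Imaging** — spot counting in single-molecule pull-down TIRF stacks
  (frame averaging, robust local-maxima detection) and morphometrics of
  super-resolved aggregates from localization tables (single-linkage
  clustering; length, convex-hull area, circularity, and a
  sampling-debiased moment eccentricity).
* **Reporting** — one-way ANOVA with per-condition comparisons against the
  control and significance-star labelling.
* **Synthetic data** — seeded generators for every input (ThT traces,
  titrations, TIRF stacks, localization tables), so the whole pipeline is
  testable without instrument data.

Fitted objects are plain S3 with broom-style `tidy()`/`glance()` methods
and `ggplot2::autoplot()` diagnostics. See the methods vignette
(`vignettes/oligoflux-methods.Rmd`) for the models, assumptions and design
choices.

## Worked example

Simulate a control and an inhibitor condition (the inhibitor lowers the
amplification rate κ from 0.020 to 0.012 per minute), fit every replicate,
and compare the oligomer flux:

```r
library(oligoflux)
library(dplyr)

t <- seq(0, 2000, by = 1)
traces <- bind_rows(
  sim_tht_traces(t, kappa = 0.020, noise_sd = 0.02, seed = 1,  condition = "control"),
  sim_tht_traces(t, kappa = 0.012, noise_sd = 0.02, seed = 10, condition = "aS46"))

fit_logistic(filter(traces, condition == "control"))
#> Generalized logistic fit: a = 50.69, kappa = 0.02007 /min (c fixed at 0.3)
#>   t_half = 268.6 min, R^2 = 0.9960, n = 6003

metrics <- flux_metrics_table(traces, r_plus = 0.002)
metrics %>% select(condition, replicate, kappa, t_half, phi_peak_rel, phi_time_rel)
#> # A tibble: 6 × 6
#>   condition replicate  kappa t_half phi_peak_rel phi_time_rel
#>   <chr>         <int>  <dbl>  <dbl>        <dbl>        <dbl>
#> 1 aS46              1 0.0121   448.        0.363        1.67
#> 2 aS46              2 0.0119   449.        0.354        1.67
#> 3 aS46              3 0.0119   448.        0.354        1.66
#> 4 control           1 0.0202   268.        1.02         1.000
#> 5 control           2 0.0200   268.        0.995        0.999
#> 6 control           3 0.0200   269.        0.989        1.00

anova_vs_control(metrics %>% transmute(condition, value = phi_peak_rel))
#> # A tibble: 2 × 6
#>   condition     n  mean      sd    p_value stars
#> 1 aS46          3 0.357 0.00514  0.0000283 ****
#> 2 control       3 1     0.0141  NA         <NA>
```

Reading the table: the inhibitor slows fibril amplification (κ recovered at
0.012 vs the control's 0.020 per minute), roughly doubles the reaction
half-time, cuts the peak oligomer flux to ~36% of the control, and delays
the flux peak ~1.7-fold — the signature of a secondary-nucleation
inhibitor. The ANOVA flags the peak-flux reduction at four stars.

A saturation-binding fit on a simulated 16-point 1:1.75 titration:

```r
fit_saturation(sim_binding_curve(kd = 0.3, bmax = 10, top_conc = 50,
                                 noise_sd = 0.1, seed = 3))
#> Saturation binding fit: K_d = 0.3007, B_max = 9.98 (R^2 = 1.000, n = 16)
```

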