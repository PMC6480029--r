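# fieldscan

Statistical process control for spatially correlated dynamic fields
observed through sensor networks with substantial missing data.

Grain-temperature layers in a granary, regional disease counts, machined
surfaces: in all of these a "field" `x_t ~ N(mu_0, Sigma)` is watched over
time, and an out-of-control event appears as a *cluster* of neighbouring
locations whose mean shifts upward from an unknown change point onward.
In practice a large share of the sensor readings never arrives (sensor
aging, radio failures, read errors), which delays or breaks conventional
multivariate control charts.  `fieldscan` is for process-monitoring
practitioners and methodologists who need cluster-level detection that
keeps working at 20–50% missing data.

## Method

The package combines two pieces:

1. **Multitask Gaussian-process imputation.**  `L` related processes on a
   shared `n`-sensor lattice are modelled per time slice as
   `y_l = kappa alpha_l`, `alpha_l ~ N(m, C)`, with the squared-exponential
   kernel `kappa(s_i, s_j) = exp(-||s_i - s_j||^2 / delta^2)` carrying
   spatial correlation and a normal-inverse-Wishart hyper-prior
   `m | C ~ N(0, C/pi)`, `C ~ IW(tau, kappa^{-1})` tying the processes
   together.  An EM algorithm estimates `(alpha_l, m, C, sigma^2)` per
   slice; missing cells of the monitored process are filled from
   `y_hat = kappa alpha_hat`.

2. **A likelihood-ratio MCUSUM spatial scan chart.**  For every circular
   cluster `O_{c,r}` (all centers, all achievable radii up to `r_u`) and
   every candidate shift direction, the chart accumulates
   `S_t = max(0, S_{t-1} + mu_{c,r}' Sigma^{-1} (x_hat_t - mu_{c,r}/2))`
   and alarms when the maximum statistic exceeds a control limit `h`,
   calibrated by Monte-Carlo simulation of the full pipeline (masking and
   imputation included) to a target in-control average run length (ARL0).
   The scan argmax identifies the outbreak cluster.

A benchmark mode (`model = "meanfill"`) replaces missing entries with the
in-control mean instead — the same chart without multitask learning — and
is consistently slower to detect, increasingly so at high missing ratios.

## A worked example

Simulate the bundled study design (5x5 grid, field covariance
`exp(-dist^2/250)`, three related processes sharing the latent field plus
`N(0, 0.1^2)` noise, 20% missing per slice, a 9-cell outbreak of
magnitude 0.5 starting at t = 51), impute, calibrate and monitor:

```r
library(fieldscan)

cfg   <- simConfig(shiftMagnitude = 0.5, missingRatio = 0.2,
                   clusterPattern = "medium")
panel <- simulatePanel(cfg, seed = 7)
panel
#> ObservationPanel: 3 process(es) x 300 time steps x 25 locations (20.0% missing)

imp <- imputePanel(panel)            # per-slice multitask EM completion
head(imp$diagnostics, 3)
#>   time iterations converged noiseVariance
#> 1    1         20      TRUE   0.004239125
#> 2    2         18      TRUE   0.009545447
#> 3    3         24      TRUE   0.016293433

cal <- calibrateH(cfg, targetArl0 = 200, reps = 100, cap = 800, seed = 1)
cal
#> CalibrationResult: h = 5.75406 for target ARL0 = 200
#>   achieved ARL0 = 190.5 (SE 17.8) from 102 replications (cap 800, 1 censored)

report <- runScan(imp$values, chartForConfig(cfg), cal@threshold)
report
#> AlarmReport: alarm at t = 51 (statistic 56.19 > h = 5.754); cluster center 13, radius 1.41, direction 1
```

The chart alarms at the first out-of-control step (t = 51, a detection
delay of 1) and identifies the planted cluster: center 13 is the grid
center `(3, 3)` and radius `sqrt(2)` is exactly the 9-cell "medium"
geometry.  The chart's known covariance is that of the monitored sensor
values (field covariance plus noise variance on the diagonal); the
per-slice EM diagnostics show the estimated noise variance hovering
around the generating value 0.01.

For stronger shifts the in-control scan statistic leaves zero so rarely
that large ARL0 targets become unattainable for any nonnegative limit;
`calibrateH()` then warns and returns the conservative limit `h = 0`
(see the methods vignette in `vignettes/`).

A command-line wrapper with `simulate`, `impute`, `monitor`, `calibrate`,
`evaluate` and `fixture` subcommands ships in `inst/scripts/fieldscan`
(see `?cli`).

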