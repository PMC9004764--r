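# chemodyn

Quantifying long-term chemotherapy response dynamics in cell populations
from longitudinal cell-count data.

## The problem

When cancer cells in culture are hit with a pulsed chemotherapeutic such as
doxorubicin, the population does not simply decay: sensitive cells keep
proliferating for a while before dying off, surviving cells sit in growth
arrest for days to weeks, and the survivors eventually regrow
logistically toward the well's carrying capacity. Summarising such an
experiment with a single 48- or 72-hour endpoint misses almost all of this
structure. chemodyn is for experimentalists and modellers who monitor
wells by automated imaging for weeks and want to turn those count curves
into interpretable parameters — resistant fraction, death rate, death
delay, arrest duration, regrowth rate — and into schedule-level metrics
that say which dosing regimen performed best.

## The model

Each well is described by a two-compartment ordinary differential equation
model: a sensitive pool *S* and a resistant pool *R*, coupled through the
total count *N*,

    dR/dt = g_r · R · (1 − N/N_max) · H(t − t_r)
    dS/dt = −k(t) · S
    N     = R + S,     R(0) = f_r·N0,  S(0) = (1 − f_r)·N0

with *t* = 0 at the start of the final drug exposure. The sensitive-cell
net rate `k(t)` rises from growth (−g_0) to a maximal death rate k_d
either exponentially with time constant t_d (variant 1), linearly over a
ramp of length t_d (variant 2), or is constant (variant 3, the classical
bi-exponential model). Variants are fitted per well by bounded multi-start
nonlinear least squares, compared by AIC = 2p + n·ln(RSS), and the
selected fit feeds schedule metrics: the fraction of non-recovering
replicates and the *critical time* (first time the population doubles its
initial count, projected from the model up to one year when not observed).

A full identifiability workbench is included: synthetic datasets with
known ground truth across an 18-variant model grid, Pearson-correlation
scoring of parameter recovery, AIC ground-truth selection rates, and
leave-one-out predictive validation. Proliferation delays are measured
from nuclei centroids by density clustering (DBSCAN) with backward cluster
tracking.

## Worked example

```r
library(chemodyn)

# a known ground truth: 5% resistant cells, 150 h arrest, exponential
# death delay
truth <- model_params(f_r = 0.05, g_r = 0.025, t_r = 150, k_d = 0.06,
                      t_d = 30, g_0 = 0.02, N_max = 4e4, N0 = 2000)
grid <- seq(0, 720, by = 4)
traj <- simulate_trajectory(truth, model_variant("exponential"), grid)
set.seed(1)
well <- count_series("demo", grid, pmax(0, traj$N + rnorm(length(grid), 0, 50)))

classify_recovery(well)
#> [1] TRUE

fit <- calibrate(well, model_variant("exponential"), t_r_input = 150)
fit
#> calibration (exponential k, t_r input, N_max calibrated): rss = 3.879e+05, n = 181, p = 6, AIC = 2341.21
#>   recovered = TRUE, converged = TRUE (20 starts)
round(unlist(fit$params), 4)
#>        f_r        g_r        t_r        k_d        t_d        g_0      N_max         N0
#>     0.0509     0.0250   150.0000     0.0567    26.5527     0.0237 39997.7628  1968.6773
```

The fitted resistant fraction (0.0509), regrowth rate (0.0250/h), death
rate (0.057/h) and death-delay constant (26.6 h) recover the generating
values to within a few percent at this noise level; RSS/n ≈ 2143 ≈ the
injected noise variance (50² = 2500), i.e. the fit sits at the noise
floor.

```r
ct <- critical_time_for_well(well, fit)
ct$critical_time_h
#> [1] 304
```

The well doubles its initial count at 304 h — about 150 h of arrest plus
six regrowth doublings — and that crossing time is the quantity compared
across dosing schedules.

An end-to-end run over a plate (preprocessing, delay detection,
calibration, selection, metrics) is one call:

```r
cfg <- pipeline_config(counts_csv = "counts.csv", out_dir = "results",
                       metadata_csv = "metadata.csv", seed = 1)
run_pipeline(cfg)
```

or, from a shell, `Rscript inst/scripts/chemodyn.R run-all --counts
counts.csv --out results`.

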