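# mycoflow

Quantitative analysis of bistable stringent-response activation in
*Mycobacterium smegmatis* from single-cell reporter fluorescence.

Under nutrient depletion, mycobacterial populations split into a
low-expression (L) and a high-expression (H) subpopulation of stress-gene
activity — the phenotypic heterogeneity behind persister formation. In
flow-cytometry time courses of GFP reporters driven by the *mprA*, *sigE*
and *rel* promoters, the population distribution of fluorescence `x` at
time `t` is a linear combination of two *time-invariant* component
distributions with time-varying weights:

```
P(x, t) = C1(t) P1(x) + C2(t) P2(x)
```

with a Gaussian `P1` (the L subpopulation; centre `x01`, width `w01`,
written in peak-width form so that sd = `w01/2`) and a lognormal `P2` (the
H subpopulation; log-mean `x02`, log-sd `w02`). mycoflow provides, for
users analysing such single-cell induction data:

- **Joint mixture fitting** (`fit_joint_timecourse()`): one shared
  Gaussian + lognormal pair across all acquisitions, per-time weights,
  fitted by expectation–maximization on raw events; single-family MLE
  (`fit_component_mle()`) and a lognormal-vs-gamma comparison for the H
  subpopulation (`compare_families()`).
- **Stochastic binning** (`stochastic_binning()`): each event `x_j` is
  assigned to L with probability `g1(x_j) = P1(x_j) / (P1(x_j) + P2(x_j))`
  against a uniform draw, resolving the overlap of the two components;
  subpopulation fractions `ω_i`, means `μ_i`, variances `σ_i²`
  (`N_i − 1` denominator), CVs, and the L→H transition-rate series
  (`analyze_timecourse()`).
- **Growth retardation** (`fit_growth_retardation()`): the reciprocal law
  `μ = φ / (1 + θ x)` linking protein (or reporter) level to specific
  growth rate, its Monod-kinetics derivation (`phi_theta_from_monod()`),
  and spline-based growth-rate estimation from OD600 curves
  (`specific_growth_rate()`).
- **Circuit model** (`pathway_params()`, `simulate_pathway()`): a
  deterministic ODE model of the MprAB–SigE–Rel cascade in which every
  protein decays at `γ_eff = γ + φ/(1 + θ x_tot)` — intrinsic degradation
  plus growth-retarded dilution. The retarded dilution closes a second,
  noncooperative positive feedback loop that produces bistability and
  hysteresis over the MprB autophosphorylation rate
  (`find_steady_states()`, `hysteresis_scan()`, `bistable_window()`).
- **Synthetic data** (`generate_flow_timecourse()` and friends): 20,000
  events per acquisition drawn from the invariant two-component mixture
  under a scheduled H fraction, logistic growth curves, and `(x, μ)`
  pairs, for validation and power analysis.
- **I/O**: CSV event tables and growth curves, YAML configs, a compact
  FCS 2.0/3.0/3.1 reader (`ingest_fcs()`), and a subcommand driver
  (`run_cli()`, wrapped by `inst/scripts/mycoflow-cli.R`).

## Worked example

Simulate an *mprA*-reporter time course at acquisition scale, refit the
mixture, and partition the population:

```r
library(mycoflow)
sc <- synthetic_scenario(promoter = "mprA", times_h = c(15, 18, 21, 24, 27),
                         n_events = 20000, seed = 42)
events <- generate_flow_timecourse(sc)
fit <- fit_joint_timecourse(events)
fit
#> Joint two-component fit: 8 iterations, loglik -591393.607
#> Two-component mixture (invariant Gaussian + lognormal)
#>   L / Gaussian : x01 = 97.4393, w01 = 103.609
#>   H / lognormal: x02 = 5.95521, w02 = 0.176067
#>   5 time point(s): 15h, 18h, 21h, 24h, 27h
```

The generating truth was `x01 = 97.3366`, `w01 = 103.0731`,
`x02 = 5.95526`, `w02 = 0.17618` — the shared components are recovered to
a fraction of a percent from 100,000 events. Binning then yields the
subpopulation statistics per time point:

```r
report <- analyze_timecourse(events, fit$model, seed = 43)
report$stats[, c("time", "subpopulation", "N", "omega", "mean", "cv")]
#>  time subpopulation     N  omega  mean    cv
#>   15h             L 18354 0.9177  97.1 0.530
#>   15h             H  1646 0.0823 384.2 0.195
#>   18h             L 14634 0.7317  96.5 0.524
#>   18h             H  5366 0.2683 390.6 0.181
#>   21h             L  7502 0.3751  98.0 0.541
#>   ...
#>   27h             H 19374 0.9687 392.6 0.175
```

`omega` for H rises from 0.08 to 0.97 — the gradual L→H transition — while
the component means stay put (invariant distributions). The per-capita
L→H transition rate over each interval is in `report$rates` (1/h).

The growth-retardation round trip, using the published fit values:

```r
d <- generate_mu_x_pairs(0.94, 0.317, x_grid = seq(0, 3, length.out = 20))
fit_growth_retardation(d$x, d$mu, start = c(phi = 1, theta = 0.1))
#> Growth-retardation law mu = phi / (1 + theta x): phi = 0.94 1/h, theta = 0.317
```

And the circuit model at the reference parameters (`k_auto = 0.7`, inside
the bistable window):

```r
p <- pathway_params()
find_steady_states(p, n_starts = 6, seed = 1)
#> 3 steady state(s) (2 stable)
#>     MprA    MprB   MprAP   MprBP    SigE     Rel     GFP stable
#>  0.13419 0.10380 0.03071 0.06109 0.05319 0.08840 0.08840   TRUE
#>  0.22587 0.19986 0.08216 0.10816 0.21712 0.46581 0.46581  FALSE
#>  0.66049 0.65251 0.15455 0.16253 0.84159 2.23592 2.23592   TRUE
bistable_window(p, seq(0.05, 1.5, length.out = 25))
#> Bistable window in k_auto: [0.5938, 0.8354] (width 0.2417), tracked species GFP
```

Two stable states separated by a saddle, and distinct up/down-sweep
branches over the autophosphorylation rate — bistability with hysteresis
from a noncooperative circuit, courtesy of the growth-retardation
feedback. Setting `theta = 0` (no retardation) empties the window.

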