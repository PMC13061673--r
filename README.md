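# adaptkuramoto

Simulation and analysis of Kuramoto phase oscillators with **non-reciprocal
adaptive couplings** — a minimal deterministic mechanism for the metastable
switching dynamics seen in oscillatory neural systems, where a few units
intermittently change the cluster they synchronize with.

The model couples $N$ phase oscillators,

$$\dot\theta_i = \omega_i + \frac{1}{N}\sum_j k_{ij}\sin(\theta_j-\theta_i)
  + \xi_i(t),$$

to an adaptive, directed coupling matrix

$$\dot k_{ij} = -\varepsilon\,[\,k_{ij} + \sin(\theta_i-\theta_j+\beta)\,],
\qquad
(\varepsilon,\beta) = \begin{cases}
(\varepsilon_1, -\pi/2) & i < j \quad\text{(Hebbian, fast)}\\
(\varepsilon_2, +\pi/2) & i > j \quad\text{(anti-Hebbian, slow)}
\end{cases}$$

For $\varepsilon_1 \gg \varepsilon_2$ the population self-organizes into two
anti-phase synchronized clusters ($R \approx 0$, $R_2 \approx 1$) that are
only metastable: the configuration is a saddle whose number of unstable
directions grows with $N$ (eigenvalues $\pm(1-2k/N)$ of the phase block),
and individual oscillators occasionally cross to the opposite cluster.

The package provides, for whoever wants to simulate or dissect this
mechanism (network-physiology modellers, nonlinear-dynamics researchers):

* a compiled Euler–Maruyama integrator for the dense, sparse-network and
  coupling-dependent-frequency variants (`simulate_kuramoto()`),
* order parameters, collective-state classification, cluster assignment,
  switching-event detection and dwell-time extraction (`order_parameters()`,
  `classify_state()`, `detect_switch_events()`, `dwell_intervals()`),
* the snapshot-based **estimated-time-of-escape predictor**: from a single
  state $\tau_{\rm win}$ steps before a switch, predict *which* oscillators
  will jump, scored Perfect / Good / Partial / Missed
  (`estimate_escape_times()`, `predict_switcher_set()`,
  `run_prediction_experiment()`),
* exact two-cluster equilibria, Jacobian blocks and the analytic saddle
  spectrum (`equilibrium_two_cluster()`, `jacobian_blocks()`,
  `analytic_spectrum()`, `spectrum_report()`),
* the parameter studies: adaptation-rate phase diagram with quadratic
  boundary fit, noise sweep, connectivity–dwell-time curve, and
  $\Gamma_0/\alpha$ regime scan (`sweep_epsilon_grid()`,
  `connectivity_sweep()`, `gamma_alpha_scan()`, ...).

Results come back as tibbles (with `tidy()`/`glance()` methods and
`autoplot()` figures), so everything composes with the usual tidyverse
verbs.

## Worked example

A single metastable run at the reference operating point
($N = 10$, $\varepsilon_1 = 0.01$, $\varepsilon_2 = 10^{-4}$,
$\sigma = 0$, $\omega_i = 0$):

```r
library(adaptkuramoto)

p    <- kuramoto_params(n = 10, eps1 = 0.01, eps2 = 1e-4)
init <- sample_initial_condition(10, seed = 3)
cfg  <- sim_config(n_steps = 1.8e6, seed = 3,
                   store_phases = TRUE, store_velocities = TRUE)
traj <- simulate_kuramoto(p, cfg, init)
glance(traj)
#> # A tibble: 1 × 6
#>       n n_steps mean_R mean_R2 label                seed
#>   <int>   <int>  <dbl>   <dbl> <chr>               <int>
#> 1    10 1800000  0.302   0.998 anti_phase_clusters     3
```

After the transient the system sits in two anti-phase clusters
($\langle R_2\rangle = 0.998$, far above the 0.8 threshold) with a low
first-order parameter — and it keeps switching:

```r
detect_switch_events(traj)[, 1:3]
#> # A tibble: 7 × 3
#>   event  t_step n_switchers
#>   <int>   <int>       <int>
#> 1     1  660222           1
#> 2     2  660307           1
#> 3     3  824822           1
#> ...
```

Each event is a single oscillator covering the full distance $\pi$ to the
opposite cluster. Can we tell *which* oscillator, from one snapshot 200
steps ahead of time?

```r
forecast_events(traj)[, c("event", "t_step", "leader", "category")]
#> # A tibble: 7 × 4
#>   event  t_step leader category
#> 1     1  660222      9 Missed
#> 2     2  660307      9 Perfect
#> 3     3  824822      8 Perfect
#> 4     4 1159860     10 Perfect
#> 5     5 1328407      9 Perfect
#> 6     6 1404453      7 Perfect
#> 7     7 1571358     10 Perfect
```

Six of seven events are predicted exactly (the miss is a near-simultaneous
pair of escapes 85 steps apart, which the 50-step grouping keeps as two
events). Across many realizations the combined Perfect + Good success rate
is 98–100% for $N = 6$ and $N = 10$.

Why switching is inevitable — the two-cluster state is a saddle:

```r
spectrum_report(n = 10)
#> <spectrum_report> N = 10
#>   unstable: 4 (predicted 4 )  zero: 2  stable: 4
#>   max |numeric - analytic| = 6.66e-16
```

`autoplot(traj)` plots the $R$/$R_2$ time series;
`autoplot(sweep_epsilon_grid(...))` draws the categorical
$(\varepsilon_1,\varepsilon_2)$ phase diagram. A JSON-config entry point
(`run_from_config()`, with a thin wrapper in `inst/scripts/akcli.R`) runs
any experiment from the shell and writes CSV/JSON artifacts plus a
manifest.

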