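---
title: "Metastable anti-phase clusters under non-reciprocal adaptive coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable anti-phase clusters under non-reciprocal adaptive coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptkuramoto)
```

## The model

`adaptkuramoto` simulates a population of $N$ Kuramoto phase oscillators
whose coupling matrix is itself a dynamical variable. Phases follow

$$\dot\theta_i = \omega_i + \frac{1}{N}\sum_{j=1}^N k_{ij}
  \sin(\theta_j - \theta_i) + \xi_i(t),$$

with additive Gaussian white noise of intensity $\sigma$
($\langle\xi_i(t)\xi_j(t')\rangle = \sigma^2\delta_{ij}\delta(t-t')$), while
every directed coupling relaxes towards a target set by the instantaneous
phase difference,

$$\dot k_{ij} = -\varepsilon\,[\,k_{ij} + \sin(\theta_i - \theta_j +
  \beta)\,],$$

with $(\varepsilon_1, \beta_1 = -\pi/2)$ above the diagonal and
$(\varepsilon_2, \beta_2 = +\pi/2)$ below it, and $k_{ii} = 0$. The
$-\pi/2$ shift is a Hebbian rule (co-phased pairs strengthen towards $+1$),
the $+\pi/2$ shift an anti-Hebbian one. The coupling between a pair of
oscillators is therefore *non-reciprocal* in two ways at once: the two
directions follow opposite plasticity rules and evolve on different time
scales ($\varepsilon_1 \gg \varepsilon_2$ throughout).

That combination produces the phenomenon the package is built to study:
the population organizes into two internally synchronized clusters a phase
difference $\pi$ apart, but the configuration is only *metastable*. It is a
saddle — every two-cluster equilibrium has unstable directions whose number
grows with $N$ — and the slowly drifting lower-triangle couplings steer the
system off it, so every so often one or a few oscillators cross over to the
opposite cluster, visible as a spike in the order parameters.

Two further variants are implemented behind the same interface:

* `"sparse"`: dynamics restricted to a connected undirected graph
  $A_{ij}$; the phase sum is degree-normalized
  ($1/\sum_j A_{ij}$) and only existing links adapt. Note that on the
  complete graph this normalization is $1/(N-1)$, not $1/N$, so the sparse
  variant does not reduce to the dense one verbatim — only after that
  prefactor.
* `"freq_adaptive"`: the interaction becomes
  $k_{ij}\,[\Gamma_0 - \sin(\theta_i - \theta_j + \alpha)]$ and each
  oscillator carries an effective frequency
  $\tilde\omega_i = \omega_i + (\Gamma_0/N)\sum_j k_{ij}$ that drifts with
  its couplings. $\Gamma_0 = \alpha = 0$ recovers the noiseless dense model.

## Integration

The Euler–Maruyama scheme advances both equations with a fixed step
$\Delta t = 0.01$; phases are wrapped to $[0, 2\pi)$ every step and the
noise increment is $\sigma\sqrt{\Delta t}\,\mathcal N(0,1)$ per oscillator
(couplings are deterministic). The inner loop is compiled (Rcpp); an
R-level `em_step()` implements the identical update and the test suite
holds the two paths together, with and without noise, against a shared RNG
stream. Because each Euler update of a coupling is a convex combination of
its current value and a target in $[-1, 1]$ (as long as
$\varepsilon\,\Delta t < 1$), couplings started inside $[-1, 1]$ remain
inside it at every step; this bound is asserted on recorded frames.

Random inputs follow the study conditions: initial phases uniform on
$[0, 2\pi)$, initial couplings uniform on $[-1, 1]$ with zero diagonal
(`sample_initial_condition()`; a `"near_plus_one"` mode reproduces the
delayed-onset scenario in which a fully synchronized transient precedes
metastability), and connected Erdős–Rényi graphs sampled by rejection at a
target mean degree (`generate_connected_graph()`), which keeps the degree
distribution of the conditioned ensemble clean. Every sweep derives
per-realization seeds from one master seed up front, so results are
reproducible and independent of execution order.

A homogeneous nonzero $\omega$ only co-rotates the frame: the package's
runs with $\omega_i = 3$ match the $\omega = 0$ trajectory plus linear
drift to $10^{-13}$ over $2\times10^4$ steps, and the deviation grows only
through round-off.

## Order parameters, classification, dwell times

`order_parameters()` returns $R e^{i\psi} = \langle e^{i\theta}\rangle$ and
$R_2 e^{i\psi_2} = \langle e^{2i\theta}\rangle$; $R \approx 0$ with
$R_2 \approx 1$ signals two anti-phase clusters. Long-time averages discard
the first 30% of a run, and `classify_state()` applies the threshold rules
at $R_{\rm th} = 0.8$ exactly as stated (both above: in-phase; $\langle R
\rangle \le R_{\rm th} < \langle R_2\rangle$: anti-phase clusters;
otherwise incoherent). Dwell intervals of the two-cluster state are maximal
runs with $R < R_{\rm th}$ and $R_2 > R_{\rm th}$. One practical caveat:
a near-$9{:}1$ cluster split has $R$ equal to the threshold up to noise, and
such trajectories chatter across it step by step. `dwell_intervals()`
therefore takes a `min_duration` argument; the connectivity sweep uses 50
steps — the same scale on which individual crossings are grouped into one
switching event — to drop that chatter from lifetime statistics.

Cluster membership uses half the angle of the second moment, $\psi_2/2$, as
the instantaneous reference direction (`assign_clusters()`): oscillator $i$
belongs to the cluster whose centre is nearer on the circle. The rule is
drift-proof (it follows a rotating configuration) and reduces to "clusters
at 0 and $\pi$" when they sit there.

## Switch detection and the arrival tolerance

`detect_switch_events()` tracks, for every oscillator, a continuous
displacement from the centre of its current cluster in the co-moving
$\psi_2/2$ frame. A switch is logged when that displacement accumulates a
full $\pi$ — the oscillator has reached the anti-podal point and lands in
the opposite cluster — and crossings within 50 steps of each other merge
into one collective event.

One numerical subtlety matters here. In this anchored frame the anti-podal
boundary *coincides with the attracting destination* of the switch: the
final approach is exponential, the last $10^{-12}$ rad are covered at
round-off-scale speeds, and a trigger at exactly $\pi$ would stamp the
event thousands of steps into that creep. The tracker therefore fires at
$\pi - \delta$ with `boundary_tol` $\delta = 0.1$ rad, chosen small against
the $\pi$ cluster separation but far above the creep scale, and the escape
predictor places its boundary on the same line. Consistency is the point:
with both on one line, the predicted time-to-boundary of a genuinely
escaping oscillator is $(1 - e^{-\lambda\tau_{\rm win}\Delta t})/(\lambda
\Delta t)$ — bounded and informative — independent of $\delta$, whereas an
inconsistent (exact-$\pi$) boundary pins it at $1/(\lambda\Delta t)$, which
for the slowest stable rates sits exactly at the exclusion cutoff.

## Snapshot escape prediction

Knowing that an event happens at step $t$, the predictor looks only at the
single snapshot $\tau_{\rm win} = 200$ steps earlier. For each oscillator
it computes the estimated time of escape
$\eta_i = d_i / (|\dot\theta_i|\,\Delta t)$ in steps, where $d_i$ is the
remaining distance to the boundary and $\dot\theta_i$ the deterministic
phase velocity at the snapshot. Oscillators with $\eta_i > \eta_{\max} =
500$ are excluded (strictly: $\eta = \eta_{\max}$ is kept). The leader is
the minimizer, the predicted set
$P = \{j : \eta_j \le \eta_{i^*} + \Delta\eta\}$ with $\Delta\eta = 150$
steps, and comparison with the actual switcher set $A$ yields Perfect
($P = A$), Good ($A \subset P$), Partial ($P \cap A \ne \emptyset$,
$A \not\subset P$) or Missed ($P \cap A = \emptyset$).

Two conventions deserve note. First, the formula uses the *magnitude* of
the velocity; an optional `direction_filter` additionally excludes
oscillators moving away from the boundary, but it is off by default —
near the saddle the velocity of an almost-arrived switcher is at round-off
scale, so its sign is noise while the magnitude ratio remains meaningful,
and with the filter on, genuine switchers get discarded. Second, the
Perfect/Good split (though not their sum) is sensitive to the
event-timing convention: with the transversal detection above, the
snapshot precedes the collective perturbation, bystanders are still at
rest ($\eta = \infty$) and almost never enter $P$, so Good events are
rarer here than under a later-stamping convention where the snapshot falls
inside the order-parameter spike and perturbed bystanders carry finite
$\eta$. The overall success rate is the robust quantity.

`run_prediction_experiment()` wraps the full protocol: per realization it
draws random initial conditions, integrates $1.8\times10^6$ steps, scores
every event after $0.3\,T_{\rm total}$, and aggregates categories. At
$N = 10$, $\varepsilon_1 = 0.01$, $\varepsilon_2 = 10^{-4}$ the first
post-transient escape typically occurs only around step $5$–$7\times10^5$
(the slow couplings need $\sim 1/\varepsilon_2$ time units to drag the
system into the saddle's neighbourhood), so meaningful runs must keep the
full length; scaled-down replication reduces the number of realizations
instead (the acceptance checks use 30–50 realizations per size against the
full study's 1000).

## Linear stability of the two-cluster saddle

`equilibrium_two_cluster()` builds the exact fixed point for any split
$(N_A, N_B)$: phases at the reference and reference$+\pi$, upper couplings
$+1$ within / $-1$ across clusters, lower couplings the reverse. At this
state the Jacobian (`jacobian_blocks()`) is block-triangular: the
phase-coupling block vanishes identically, the coupling-coupling block is
diagonal with entries $-\varepsilon_1$, $-\varepsilon_2$, so stability
reduces to the $N \times N$ phase block. That block has the closed form
$+1/N$ above the diagonal, $-1/N$ below, diagonal $-(N - 2i + 1)/N$
(`phase_block_at_equilibrium()`) — independent of the split, a fact the
tests verify rather than assume. Its rows sum to zero (the marginal global
phase shift) and it anticommutes with the index-reversal flip, forcing a
$\pm$-paired spectrum: eigenvalues $\pm(1 - 2k/N)$, $k = 1, \dots, m-1$
plus a double zero for $N = 2m$, $k = 1, \dots, m$ plus a single zero for
$N = 2m+1$ (`analytic_spectrum()`). The numerical eigendecomposition
matches this ladder to $10^{-9}$ for $N = 2\ldots40$; the positive half
counts the unstable directions ($m - 1$ resp. $m$), which is why
metastable switching accelerates with system size. The zero tolerance
$10^{-9}$ (absolute) reflects entries that are $O(1/N)$ rationals.

## Parameter studies and their desk-scale sizes

Each experiment in `R/experiments.R` exposes its grid, realization count
and run length so that the full-resolution studies (a $101\times31$ rate
grid at 200 realizations; 1000-realization prediction runs) and reduced
versions run through the same code. The sizes used by the package's own
acceptance checks, chosen to resolve each effect rather than to exhaust
it, are:

* rate phase diagram: coarse grids, $2\times10^4$ steps, final-1000-step
  averaging, a handful of realizations per pixel; the transition boundary
  (smallest incoherent $\varepsilon_2$ per $\varepsilon_1$ column) is
  fitted by least-squares quadratic, with residuals reported, never hidden.
* prediction: 40 ($N=6$) and 30 ($N=10$) realizations of $1.8\times10^6$
  steps.
* connectivity: 50 realizations per mean degree $\langle k\rangle \in
  \{3,5,7,9\}$ of $1.2\times10^6$ steps. Shorter windows right-censor the
  dwell intervals of the denser graphs and the degree-5/7 ordering drowns
  in sampling noise; at this length the mean dwell rises cleanly with
  $\langle k\rangle$ and peaks at the complete graph.
* noise sweep: identical initial conditions across
  $\sigma \in \{0, 10^{-5}, 10^{-3}, 0.1\}$; the strongest level
  destroys coherence.
* $\Gamma_0$/$\alpha$ scan: weak gain ($\le 0.2$) keeps metastable
  anti-phase clusters with incoherent instantaneous frequencies, strong
  gain ($> 0.6$) is incoherent; the scan also measures the inter-cluster
  phase separation.

## What the generator emulates — and what passing tests do not show

All inputs are synthetic by design: the study's randomness lives entirely
in initial conditions (and the noise stream), drawn exactly as specified
above. Passing tests therefore demonstrate properties of this model under
its stated distributions; they say nothing about robustness to
heterogeneous natural frequencies beyond small normal perturbations, about
other network ensembles (only Erdős–Rényi conditioned on connectivity is
generated), or about real neural recordings, for which the oscillators are
at best a mesoscopic abstraction.

## Numerical choices and known limitations

* Chaotic sensitivity: metastable trajectories amplify round-off, so event
  times are reproducible only under a fixed seed *and* a fixed operation
  order; the compiled loop fixes both.
* $N = 4$ long-time behaviour: the two-cluster saddle is reached exactly in
  finite precision — in-cluster phases become bitwise identical and the
  trajectory freezes on the symmetric configuration, after isolated
  switches whose spacing grows. The coupling evolution is therefore
  *eventually constant*, the degenerate (period-zero) case of periodic
  evolution; a sustained limit cycle is not observed in double precision.
  The periodicity check asserts exactly this eventual constancy.
* The sparse variant keeps the couplings of absent links frozen at their
  initial values; they never influence the dynamics and are excluded from
  reports.
* Degenerate inputs are rejected up front: isolated nodes in the sparse
  variant (zero-degree division), disconnected adjacency matrices,
  non-orthogonal $\beta$ values in the equilibrium construction, and
  out-of-range order parameters all raise validation errors rather than
  propagate.
* Ties: an oscillator exactly on a cluster boundary is assigned to cluster
  0; an escape time exactly at $\eta_{\max}$ is kept; ties at the minimal
  $\eta$ put both oscillators in $P$.
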