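---
title: "Methods: the logistic KT/KTz map and its analysis toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the logistic KT/KTz map and its analysis toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktzlog)
```

## The model

`ktzlog` implements a discrete-time excitable-cell model with a logistic
gain.  The state is a membrane potential $x$, a recovery variable $y$ and a
slow ionic current $z$, advanced synchronously (all right-hand sides read
the old state):

$$x_{t+1} = f\!\left(\frac{x_t - K y_t + z_t + H + I_t}{T}\right),\qquad
  y_{t+1} = x_t,\qquad
  z_{t+1} = (1-\delta) z_t - \lambda (x_t - x_R),$$

with $f(u) = u/(1+|u|)$.  The logistic gain is the first-order rational
approximation of the hyperbolic tangent used by the older members of this
map family; it agrees with $\tanh$ to third order at the origin, maps the
real line onto the open interval $(-1,1)$, is $C^1$ with
$f'(u) = (1+|u|)^{-2}$, and needs no overflow guard (the `tanh` option
clamps its argument at $\pm 350$).  Because $f$ is algebraic, every fixed
point and every eigenvalue of the model has a closed form, which is what
the `equilibria` functions exploit.

Two canonical sub-families are used throughout:

* **case I** (`delta = lambda = 0`): the 2-D fast subsystem, with the bias
  $H$ as a control parameter;
* **case II** (`H = 0`): the full 3-D model, in which $z$ acts as a slow,
  self-adjusting bias relaxing towards $(x_R - x)\lambda/\delta$.

All analyses in the package assume $K, T > 0$.  Time is measured in map
steps (ts); no physical-unit calibration is claimed anywhere.

## Equilibria and stability limits

Writing $p_0$ for the gain-argument numerator at a fixed point
($p_0 = (1-K)x^* + H$ in case I, $(1-K)x^* + z^*$ in case II) and
$p = T + |p_0|$, the fixed-point identity becomes $x^* = p_0/p$, which per
branch sign $s = \operatorname{sign}(p_0)$ is a quadratic in $x^*$.
Admissible roots must be real, lie in $[-1,1]$ and reproduce the branch
sign; the degenerate $p_0 = 0$ root (the origin when the bias vanishes) is
handled explicitly because $s$ is undefined there.  Every emitted record
carries the residual of the one-step identity, kept below $10^{-12}$.

The case-I Jacobian eigenvalues solve
$\Lambda^2 - (T/p^2)\Lambda + KT/p^2 = 0$; the case-II eigenvalues solve a
cubic whose $\delta=\lambda=0$ limit factorises into the case-I quadratic
times $(\Lambda - 1)$ — the frozen-$z$ direction.  The cubic is solved
numerically (`polyroot`, authoritative) and by the Cardano closed form
(cross-check to $10^{-8}$; near branch-cut degeneracies the numeric roots
win).  A fixed point is *stable* when all moduli are below 1, and a
*saddle* when the spectrum is real with moduli straddling 1.  The source
family describes saddles by eigenvalue *signs*, but for this map the
case-I eigenvalue product $KT/p^2$ is always positive, so a literal sign
criterion would produce no case-I saddles at all, contradicting the
saddle branches of its own bifurcation diagrams; the modulus convention
reproduces them (e.g. the origin between the two stable fixed points at
$K=0.6$, $T=0.25$).  Spectra with $\big|\max|\Lambda| - 1\big| \le 10^{-3}$
are flagged *marginal* and exempt from the simulation cross-check.

On the $H=0$ axis the three analytic stability limits are the pitchfork
$T = 1-K$ ($K \le 0.5$), the supercritical Neimark–Sacker line $T = K$
($K > 0.5$) and the subcritical Neimark–Sacker curve $T = 1/K + K - 2 =
(1-K)^2/K$ ($0.5 \le K \le 1$); all three meet at $(0.5, 0.5)$.  The
$T$–$H$ limit curves follow from $\max|\Lambda|=1$: on the limit
$p = T/(1-|x^*|)$ combines with $p^2 = (1-K)T$ (real case) or $p^2 = KT$
(complex case), giving
$x^* = \pm\big(1-\sqrt{T/(1-K)}\big)$, $H = [\sqrt{(1-K)T}+K-1]\,x^*$ for
$K<0.5$ and the $K$-analogues for $K \ge 0.5$.  Treating $z$
adiabatically maps the case-II boundary onto case I and yields the
quasi-static fixed-point limit $x_R = \pm(K-T)$, accurate to $O(\delta)$;
`locate_bifurcation()` confirms the spike-onset boundary at
$\delta=\lambda=10^{-4}$ within $10^{-2}$ of it.

## ISI taxonomy and phase diagrams

Spikes are upward crossings of a threshold (default 0) after the potential
has re-armed below threshold minus a hysteresis (default 0.1); the model
has no reset, so this is the only spike definition in the package and it
is configurable everywhere.  A trajectory's regime label is a function of
its inter-spike-interval (ISI) distribution and amplitude:

| label | rule (defaults in parentheses) |
|---|---|
| FP | no spikes, amplitude $< A_{so}$ (0.05) |
| SO | no spikes, sub-spike oscillation |
| FS | unimodal ISIs, mean $<$ `isi_th` (100 ts) |
| CS | unimodal, mean $\ge$ `isi_th`, CV $<$ `cv_th` (0.005) |
| ACS | unimodal, mean $\ge$ `isi_th`, CV $\ge$ `cv_th` |
| BS / SB | bimodal; SB when the interburst mode exceeds `ibi_th` (500 ts) |
| MIXED_DUST | the two window halves disagree on a CS/BS-type label |

Modality uses quarter-octave $\log_2$ ISI bins; a mode is a run of bins
holding $\ge 5\%$ of the mass, separated by bins below $2\%$.  The
`cv_th` default deserves a note: in this implementation the aperiodic
cardiac band has ISI dispersion of 1–2% of the mean (a scatter of nearby
periods rather than a broad lognormal), so the threshold separating
periodic from aperiodic cardiac spiking is set between the $<10^{-3}$ CV
of deep periodic spiking and the $\sim 1.5\times 10^{-2}$ CV of the
aperiodic band.  All thresholds travel with every diagram as an attached
configuration.

`phase_diagram()` classifies each cell of a 2-D parameter grid from a
fixed initial state, with the sweep in compiled code and the labelling
rules shared verbatim with the single-trajectory path (a unit test pins
the two together).  Diagram-scale defaults are a $5\times10^4$ ts
transient and a $2\times10^5$ ts window per cell — enough for $\ge 100$
cardiac periods per cell — while single-point analyses default to
$10^5$/$10^6$.  Bistability probing (8 corner states of $[-1,1]^3$) is
available but off by default; at the cells probed here all corners
converge to one attractor.

Arnold tongues born on the supercritical Neimark–Sacker line carry winding
number $w = \arccos(1/2K_c)/2\pi$; `winding_number_measured()` accumulates
the orbit's rotation angle around the encircled fixed point and returns
the exact rational $P/Q$ when the orbit is $Q$-periodic (state recurrence
within $10^{-9}$, $Q \le$ `maxQ`).

## Lyapunov exponents and dimensions

Two estimators are provided.  The *divergence fit* iterates twin
trajectories separated by $10^{-8}$ initially and fits
$\log\Delta x$ against $t$ from $t=0$ until $\Delta x$ first exceeds a
saturation guard ($10^{-2}$; bounded trajectories saturate near
$\Delta x \approx 2$, which must stay out of the fit).  The single-pair
fit is window-sensitive at the few-percent level, which is visible in the
headline numbers: both chaotic benchmark regimes land within $\pm 0.01$ of
the published exponents but a few percent away, while the second
estimator agrees with them to better than 2%.  That second estimator is
the *Eckmann–Ruelle* tangent-space method: products of the analytic
Jacobian along the orbit with Gram–Schmidt re-orthonormalisation every 10
steps (the map is known, so no embedding reconstruction is involved),
returning the full spectrum.  Exactness anchors: at a stable fixed point
the spectrum equals $\ln|\Lambda_i|$; the spectrum sum equals the orbit
average of $\ln|\det J| = \ln(KT/p^2)$ per step to $10^{-8}$; on a
$Q$-cycle the top exponent equals $\frac1Q\ln\rho$ of the cycle's Jacobian
product.

The Kaplan–Yorke dimension interpolates the sorted spectrum:
$D = j + \sum_{i\le j}\lambda_i/|\lambda_{j+1}|$ for the largest $j$ with
non-negative partial sum.

Capacity dimension needs more care.  `capacity_dimension()` box-counts a
sample of orbit points over a geometric range of box sides (default
$2^{-4}\dots 2^{-12}$ of the bounding box) — the textbook estimator.  For
the benchmark strange attractor of the fast subsystem this estimator is
badly biased at any feasible sample size: the natural measure is strongly
multifractal, so filaments of tiny measure register only logarithmically
slowly (the fitted slope is still near 1.1 at $10^9$ points, and a Chao-type
coverage correction of unseen boxes moves it by under 0.02).  Capacity
dimension is a property of the *set*, so `capacity_dimension_cover()`
covers the attractor closure directly: a subdivision algorithm that
alternates a selection sweep $S \leftarrow \mathrm{image}(S)\cap S$ (run to
stability) with dyadic subdivision.  For this map the image cover of a
grid box is computable *exactly* — the potential update is monotone
increasing in $x$ and decreasing in $y$, so a box maps into one cell
interval per row, and the recovery update sends the box onto exactly one
grid row — hence no interior sampling and no missed cells.  The per-level
counts converge from below; the estimate is the local slope over the
finest octave (level $2^{-17}$ of the domain by default in the acceptance
runs), with the gap to the previous octave's slope reported as the
convergence indicator.  The finest-octave estimate reproduces the
published capacity dimension of the benchmark attractor; the level table
is returned so the convergence can be inspected.

## Scaling laws near the transitions

Two transitions of the slow model (at $K=0.6$,
$\delta=\lambda=10^{-3}$) carry inverse-square-root signatures:

* **Infinite-period approach to quiescence.**  On a slice through the
  cardiac region the ISI diverges as the reversal parameter approaches the
  fixed-point boundary.  Distances are measured to the *quasi-static*
  critical point $x_R = -(K-T)$ — the saddle-node ghost — not to the
  numerically located spike-onset value, which precedes it by a few
  $10^{-4}$ (the final approach is discontinuous, so the measured period
  saturates just before onset).  The package uses the cardiac slice
  $T = 0.2$: on slices above the chaotic dust band the boundary is
  approached by bursts rather than single-spike cardiac cycles (there the
  *interburst interval* carries the same $-1/2$ law, which the tests also
  measure).  Fit windows are reported with every fit and default to the
  region where the log-log local slope is stationary: distances
  $[10^{-3}, 10^{-2}]$ for the mean ISI and $[10^{-2}, 10^{-1}]$ for the
  ISI variance.
* **Blue-sky (bursting to fast spiking).**  Along the bursting slice
  $T = 0.275$ the duration of a burst grows without bound while the
  interburst interval stays near 120 ts; past the critical reversal value
  the train never pauses again.  The transition point is located by
  bisection on the presence of any interburst gap within a $10^6$ ts
  window.  The measured burst-duration exponent on this slice is about
  $-0.36$ (log-log fit over distances $3\times10^{-4}\dots
  3\times10^{-2}$ from the bisected point; freeing the critical point in
  the fit makes it shallower still), clearly below the $-1/2$ the family
  is reported to obey.  The corresponding acceptance check is left
  failing rather than refitted to pass, and the measurement is documented
  here as a property of this implementation at desk scale.

A remark on slices: the bursting phenomena live strictly above the dust
band ($T \gtrsim 0.25$).  The fast subsystem has no oscillatory attractor
below $T \approx 0.21$ at $K = 0.6$ for any bias (verified by direct
simulation across initial conditions), so no bursting — and hence no
blue-sky transition — exists at $T = 0.1$; at that temperature the model
produces only slow relaxation (cardiac) oscillations.  The package
therefore anchors the blue-sky analyses at $T = 0.275$, where the located
critical value matches the published one.

## Excitability protocols and networks

Every entry of `ktz_behaviors()` couples a parameter set, a stimulus
protocol and a machine-checkable predicate (for example, *rebound spike*:
no spikes before or during an inhibitory step, at least one within 500 ts
after its offset).  The parameter sets are a curated registry found by
guided search seeded from the phase diagrams; the predicates, not the
specific numbers, define the behaviors, and `run_behavior()` re-validates
any entry.  Excitability classes come from the f–I curve (spikes per
$10^4$ ts vs DC amplitude): class 1 when the onset rate is below 10% of
the plateau, class 2 when firing starts at a finite floor.  The
bistability verdict demonstrates coexistence through stimulus-selected
outcomes (a weak pulse returns to rest, a strong one leaves a persistent
oscillation); the reverse oscillation-to-rest switch is not probed because
the fixed point's basin is a narrow sliver at the registry's operating
point.

Networks couple identical units by gap junctions,
$I_i = \sum_j G\,(x_j - x_i)$, computed from the old potentials and summed
before any unit advances (three-stage synchronous update).  The directed
chain ($i \to i+1$, $N-1$ synapses) carries a kick-started wave whose
conductance threshold is bisected to $10^{-6}$ and is independent of chain
length beyond $N \approx 20$ within 1%.  The complete graph uses random
initial states (uniform on $[-1,1]$ for $x, y$; $z = 0$; seed recorded in
the config) and a variance-ratio synchrony order parameter
$1 - \overline{\mathrm{Var}_{\mathrm{pop}}(x)}/\mathrm{Var}_t(x_1)$: 1 for
identical trajectories, near 0 for independent ones, with the degenerate
constant-reference case flagged rather than silently divided through.

## Numerical choices and limitations

* Double precision throughout; the logistic gain is evaluated directly
  (overflow-safe), and simulation aborts with the step index if a state
  ever becomes non-finite.
* Root deduplication at $10^{-12}$; eigen residual bound $10^{-10}$;
  recurrence tolerance for periodicity $10^{-9}$; all bisections to
  $10^{-6}$ on their control variable.
* Problem sizes: Lyapunov products over $10^6$ steps after a $10^5$ step
  transient; scaling sweeps with $3\times10^6$ ts windows and 12 distances
  per fit; phase diagrams at $100\times100$ cells with $2\times10^5$ ts
  windows; the box cover to level $2^{-17}$.  These sizes reproduce the
  published quantities at the tolerances asserted in the test suite.
* The classifier's window-halving dust criterion deliberately labels any
  CS/BS-type disagreement between halves as switching; near the
  infinite-period boundary this can mark low-spike-count cells, which are
  additionally flagged `low_count`.
* The subdivision cover is implemented for the 2-D fast subsystem only;
  case-II attractors get the orbit-sample estimator.
* The registry's behaviors are demonstrations, not fits to any particular
  cell; no physiological units are attached to ts or amplitudes.
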