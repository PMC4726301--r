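---
title: "The energy-depot model under cross-correlated noise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The energy-depot model under cross-correlated noise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotABP)
```

## The model

An active Brownian particle (ABP) of unit mass carries an internal energy
depot $e(t)$ that is charged by the environment at a constant flux $q$,
leaks by internal dissipation at rate $c\,e$, and is converted into kinetic
energy at rate $d_2 v^2 e$:

$$\dot e = q - c\,e - d_2 v^2 e .$$

The velocity feels Stokes drag $-\gamma_0 v$, the propulsive feedback
$+d_2 e\,v$ from the depot, and two zero-mean Gaussian white noises: a
*multiplicative* one $\eta_1$ entering through the coupling $h_1(v) = -v$
(random modulation of the drag coefficient) and an *additive* one $\eta_2$
with $h_2(v) = 1$ (internal agitation):

$$\dot v = -(\gamma_0 - d_2 e)\,v - v\,\eta_1(t) + \eta_2(t),
\qquad \dot x = v ,$$

with $\langle \eta_i(t)\eta_j(t')\rangle = 2 M_{ij}\,\delta(t - t')$,
$M_{11} = M_1$, $M_{22} = M_2$, and cross intensity
$M_{12} = \mu\sqrt{M_1 M_2}$, $\mu \in [-1, 1]$. $\mu = 0$ means
independent noises; $|\mu| = 1$ perfect correlation (the pair is rank
one).

Setting $\dot e = 0$ gives the quasistationary depot
$e_{qs}(v) = q/(c + d_2 v^2)$ and the *reduced* velocity equation
$\dot v = f(v) - v\eta_1 + \eta_2$ with drag force
$f(v) = -\gamma(v)\,v$, $\gamma(v) = \gamma_0 - d_2 q/(c + d_2 v^2)$.
When $d_2 q > \gamma_0 c$ (the *active regime*) the drag is negative at
small speeds, $v = 0$ is unstable, and two symmetric stable states sit at
$v_\pm = \pm\sqrt{q/\gamma_0 - c/d_2}$. At the reference parameters
($\gamma_0 = 20$, $q = 2$, $c = 0.01$, $d_2 = 1$) these are
$v_\pm = \pm 0.3$.

## The Fokker–Planck layer (Stratonovich)

For the reduced dynamics read in the Stratonovich sense, the
Fokker–Planck equation for the velocity density $Q(v,t)$ has drift and
diffusion

$$F(v) = f(v) + M_1 v - \mu\sqrt{M_1 M_2}, \qquad
  G(v) = M_1 v^2 - 2\mu\sqrt{M_1 M_2}\, v + M_2 .$$

The convention is pinned by the model's defining property: at $\mu = 0$
only the multiplicative intensity contributes to the effective drag
($F = f + M_1 v$); an Itô reading would add no drift at all. The
zero-flux stationary solution is

$$Q_{st}(v) = N^{-1} e^{-U_{FP}(v)}, \qquad
  U_{FP}(v) = \ln G(v) - \int_0^v \frac{F(u)}{G(u)}\,du ,$$

normalised so $U_{FP}(0) = 0$ (only differences are physical). The
integral is evaluated by adaptive Gauss–Kronrod quadrature
(`stats::integrate`, relative tolerance $10^{-10}$) accumulated between
the nodes of the velocity grid; `stationary_distribution()` exponentiates
stably (shifting by $\min U_{FP}$, so arbitrarily deep wells cannot
overflow), normalises by trapezoid, and widens the grid automatically if
more than $10^{-8}$ of the mass sits in the outermost cells. The default
grid spans $[-1.2, 1.2]$ with 2001 points, a wide margin around
$v_\pm = \pm 0.3$ at the reference noise levels.

For $|\mu| < 1$, $G > 0$ everywhere (its discriminant is
$4 M_1 M_2(\mu^2 - 1)$). At $|\mu| = 1$, $G$ degenerates to a perfect
square with a double root at $v^* = \mathrm{sign}(\mu)\sqrt{M_2/M_1}$
where the effective noise vanishes; a grid crossing that point is
rejected with an explicit degenerate-noise error, because the stationary
formula is only defined piecewise on one side of the root.

Two exact symmetries are used as oracles throughout the test suite:
$U_{FP}(v;\mu) = U_{FP}(-v;-\mu)$ (mirror law), and for $\mu > 0$ the
well at $v_+$ is deeper than at $v_-$, which is the mechanism of
noise-induced transport: correlation tilts the effective potential and
the ensemble develops a net drift whose sign follows $\mu$.

## Stochastic integration

All three dynamical forms — *full* $(x, v, e)$, *reduced* $(x, v)$ and
the *equivalent* single-noise Langevin equation
$\dot v = a(v) + \sqrt{G(v)}\,\Gamma(t)$ — are integrated with a
stochastic second-order Runge–Kutta (Heun) scheme: the predictor takes an
Euler step, the corrector averages the drift over the current and
predicted states, and both stages reuse the *same* Wiener increments.
Correlated increment pairs are built from the lower-triangular square
root of the covariance
$\begin{pmatrix} 2M_1 & 2M_{12}\\ 2M_{12} & 2M_2\end{pmatrix} dt$; at
$|\mu| = 1$ the factor is rank one and $\Delta W_2$ is proportional to
$\Delta W_1$ exactly.

**The convention switch.** The treatment of the *noise coefficient*
selects the stochastic calculus, and the package exposes it
(`sim_config(convention = )`):

* `"ito"` (default): the coupling $-v$ is evaluated at the pre-point.
* `"stratonovich"`: the coupling is averaged over predictor and
  corrector, which adds the noise-induced drift $M_1 v - M_{12}$.

This is not a cosmetic choice here. The deterministic full system
linearised about $(v_\pm, e_{qs}(v_\pm))$ is a *weakly damped spiral*:
its Jacobian trace is $-(c + d_2 v_\pm^2) = -0.1$ at the reference
parameters, while the spiral frequency is
$\omega \approx \sqrt{2 d_2^2 v_\pm^2\, e_{qs}(v_\pm)} \approx 1.9$. The
Stratonovich drift adds $+M_1 v$ to the velocity equation, so for
$M_1 > c + d_2 v_\pm^2 = 0.1$ it makes the spiral *unstable*: trajectories
orbit indefinitely, cross $v = 0$ constantly, and the ensemble diffusion
is largest at $|\mu| = 1$. Under the Itô reading the spiral stays stable,
and at $|\mu| = 1$ the ensemble locks into the well adjacent to the
zero-noise velocity $v^*$ — nearly pure drift with strongly suppressed
diffusion, which is the transport phenomenology this model is known for.
The package therefore integrates with the Itô convention by default
(matching the behaviour of a plain second-order stochastic Runge–Kutta
applied to these equations), keeps the analytic layer Stratonovich (as
its $F(v)$ requires), and forces Stratonovich in the harness that checks
the simulator against the analytic layer, so that each comparison is made
within a single consistent calculus.

**Timescales, and why the reduced equation is not the workhorse.** The
usual justification for eliminating the depot is that it is fast. At the
reference parameters it is not: the depot relaxes at rate
$c + d_2 v_\pm^2 = 0.1$ while the velocity relaxes at
$|f'(v_\pm)| = 36$ near the wells — the depot is the *slow* variable, by
a factor of several hundred. Two consequences, both verified empirically
by the test suite:

* the full system keeps switching wells through its weakly damped,
  noise-sustained oscillations, so stationary averages converge at desk
  scale;
* the reduced scalar equation has effective-potential barriers of order
  $15$–$35$ (in the Arrhenius units of $U_{FP}$), giving well-escape
  times of order $10^5$–$10^9$ time units. A reduced-dynamics ensemble
  started from the symmetric uniform law is frozen in its initial wells
  for any feasible horizon.

The figure-style experiments (mean velocity, mean position, depot
observables, effective diffusion) therefore run the **full** variant; the
reduced and equivalent variants are retained for the analytic-layer
consistency checks and for single-well studies.

**Checking the simulator against the Fokker–Planck solution.** Because
of those frozen barriers, "simulate from uniform initial conditions and
compare the histogram with $Q_{st}$" cannot converge at desk scale —
$Q_{st}$ at, e.g., $(M_1, M_2, \mu) = (0.5, 0.05, 0.5)$ puts essentially
all mass in one well, while the frozen ensemble keeps half its
trajectories in the other. `compare_sde_fpe()` instead verifies
*invariance*: initial velocities are drawn from $Q_{st}$ itself
(inverse-CDF sampling) and the ensemble must *stay* distributed as
$Q_{st}$ under the Stratonovich reduced dynamics (Kolmogorov–Smirnov
distance below 0.05 after a burn-in). Any error in $F$, $G$ or the
integrator's convention would show up as a drift away from the invariant
law; errors in the relative well weights would not, which is the honest
limit of what a desk-scale comparison can establish here. The KS
statistic is reported as a plain distance, never as a test p-value: the
pooled samples are strongly autocorrelated in time.

## Initial conditions

Initial velocity and position are uniform on $[-1, 1]$ (configurable
bounds). The depot starts **empty**, $e(0) = 0$, as the cold start is the
natural initial state for a particle that has not yet harvested energy:
under passive drag the velocity first collapses toward zero while the
depot charges, and the propulsive instability then switches on with every
trajectory near the noise-dominated region, so the choice between the two
wells is made by the noise (and its cross-correlation) rather than by the
arbitrary sign of $v(0)$. The alternatives
(`depot_init = "quasistationary"` or `"reservoir"`) are kept for studies
of the charged regime. In practice the full system's continual well
switching makes the long-run observables insensitive to this choice; it
mainly shapes the transient.

## Observables

* `mean_velocity()`: mean over retained (post burn-in) states; the SE is
  the between-trajectory standard error of the per-trajectory time
  means, since trajectories are the independent replicates. The default
  burn-in is the first 20% of steps.
* `mean_position()`: ensemble mean of $x$ at a chosen time; with drift
  it grows as $\langle v\rangle t$, which is asserted as a consistency
  identity.
* `depot_observables()`: stationary $\langle e\rangle$ and conversion
  rate $d_2\langle e v^2\rangle$, both reported because either is a
  sensible "velocity of the internal energy depot"; at stationarity they
  satisfy the balance $q = c\langle e\rangle + d_2\langle e v^2\rangle$,
  asserted within replicate SEs.
* `effective_diffusion()`: $D_{eff}$ is half the slope of the ensemble
  variance of position *about the mean* versus time, fitted by least
  squares over the final half of the run, so coherent drift does not
  contaminate the diffusive spread. Two uncertainties are reported: the
  regression SE (which badly understates the error because the variance
  path is autocorrelated) and a replicate-based SE from refitting on
  trajectory blocks; comparisons across parameter points use the latter.
* `sign_change()`: linear interpolation of the zero crossing of
  $\langle v\rangle(\mu)$, with a bootstrap (200 resamples over
  trajectories within each sweep point) for its standard error.

## Reproducibility

Every trajectory owns an RNG substream spawned deterministically from
the master seed by an exact-integer-arithmetic Lehmer hash, so ensembles
are bit-reproducible and independent of block size or integration order.
Sweeps derive one sub-seed per parameter point from the same master
seed; rerunning any row's recorded provenance reproduces the row, and
repeated sweep runs produce byte-identical CSV output (timing goes to
stderr only).

## Problem sizes

Interactive defaults are 100 trajectories of $2\times 10^4$ steps at
$\Delta t = 0.01$; the reference protocol (500 trajectories of
$10^5$ steps, uniform $[-1,1]$ initial conditions) is available behind
`preset(..., scale = "reference")` and is used where precision demands it
(for example the zero-crossing sweep in `scripts/acceptance.R`, which
needs per-point standard errors below $10^{-3}$ because the selection
bias at $M_1 = 0.01$ is weak). Shape assertions in the test suite use
whatever ensemble size makes the asserted difference resolvable at two
replicate SEs; the depot-clamp rate is monitored and stays below
$10^{-4}$ of updates at reference parameters.

## What the generator does and does not emulate

The simulator *is* the data generator: there is no external data. It
reproduces the model's study conditions — reference constants
($\gamma_0 = 20$, $q = 2$, $c = 0.01$, $d_2 = 1$, $M_2 = 0.05$), the
uniform initial law, $\Delta t = 0.01$, and the two-noise correlation
structure. It does not emulate features of real self-propelled systems
that the model itself omits: inertia of the medium, coloured noise,
spatial forces or confinement, interactions between particles, or any
space-dependent energy supply $q(x)$. Passing tests therefore certify
the internal consistency of this idealised model, not agreement with
experimental trajectories of motile cells or bacteria.

## Known limitations

* The printed claim that perfect correlation yields *exactly* zero
  diffusion is an idealisation: because the zero-noise velocity
  $v^* = \sqrt{M_2/M_1}$ does not coincide exactly with $v_+$, a small
  residual switching diffusion survives at $|\mu| = 1$
  ($D_{eff} \approx 0.03$ at reference parameters, against
  $\approx 0.06$ at $\mu = 0$). The suppression is robust; the ratio is
  not below 5%, and the corresponding check in the acceptance suite
  documents this honestly.
* On the coarse grid $\mu \in \{-1, -0.5, 0, 0.5, 1\}$ the effective
  diffusion at $\mu = 0$ and $|\mu| = 0.5$ are statistically
  indistinguishable at desk scale; the tests assert the resolvable
  statements ($D_{eff}$ at $\mu = 0$ exceeds the $|\mu| = 1$ values, and
  no grid point exceeds $\mu = 0$ significantly).
* The equivalent single-noise variant shares the reduced equation's
  frozen-barrier caveat; at $|\mu| = 1$ its trajectories cannot cross
  $v^*$ from below, which is asserted as a property, and comparisons
  with the reduced variant are made within a single well.
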