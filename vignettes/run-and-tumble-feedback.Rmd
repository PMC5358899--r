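---
title: "Motion-sensation feedback in run-and-tumble navigation: models, solvers and simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-sensation feedback in run-and-tumble navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runtumble)
```

## The model

A run-and-tumble navigator (the package's vocabulary is that of *E. coli*
chemotaxis, but nothing depends on the organism) alternates straight runs at
speed $v_0$ with zero-speed tumbles. An internal state $F$ integrates the
perceived signal $\phi(C)$ with receptor gain $N$ and relaxes back to the
adapted value $F_0$ over the memory time $t_M$:
$$\dot F = -\frac{F - F_0}{t_M} + N\,\frac{d\phi}{dt}.$$
Switching between runs and tumbles is Poissonian with total rate $1/t_S$ and
run probability $r(f) = 1/(1+e^{-f})$, $f = HF$, where $H$ is the motor gain.
During runs the heading diffuses rotationally with coefficient $D_R$, during
tumbles with $D_T > D_R$; the direction therefore decorrelates at rate
$t_D^{-1}(f) = (n-1)\,[r(f) D_R + (1 - r(f)) D_T]$ in $n$ dimensions.

Measuring time in units of $t_M$ and length in units of $v_0 t_M$, two ratios
govern everything:
$$\tau_E = \frac{L}{t_M N H v_0}, \qquad
  \tau_D(f) = \frac{t_D(f)}{t_M},$$
with $L = 1/\lVert\nabla\phi\rVert$ the local gradient length scale. $\tau_E$
compares the *positive* feedback (moving up the gradient raises $f$, which
raises the run probability, which prolongs motion up the gradient) to the
adaptive negative feedback; $\tau_D$ compares direction persistence to
memory. When $\tau_E \gtrsim 1$ adaptation wins and the classical picture of
a weakly biased random walk holds. When $\tau_E < 1$ the positive feedback
dominates: runs up the gradient are selectively elongated, runs down the
gradient are cut short, and the cell climbs like a ratchet at speeds
approaching $v_0/2$.

The defaults throughout are the study conditions used in all the package's
cross-validations: $r_0 = r(f_0) = 0.8$, $D_T/D_R = 37$, $n = 3$, and
$t_S = 0.01\,t_M$ so the fast-switching coarse-graining is valid
(`model_params()` warns above $0.1\,t_M$).

## Five routes to the same physics

The package implements the model at every level and leans on the agreement
between levels as its main correctness argument:

1. **Agent simulator** (`agent_simulate()`, compiled): explicit run/tumble
   states, positions in $\mu$m, rotational diffusion of the heading vector,
   receptor saturation, arbitrary gradient geometry.
2. **$(f, s, x)$ Langevin engine** (`langevin_fs()`, compiled):
   the fast-switching reduction; $s$ is the orientation cosine with
   multiplicative noise $\sqrt{2(1-s^2)/((n-1)\tau_D)}$, reflected into
   $[-1, 1]$.
3. **$(r, v)$ Langevin engine** (`langevin_rv()`, compiled): the same process
   in run-probability/projected-speed coordinates, where the mechanism is
   visible: the drift of $v = rs$ carries the always-positive $v^2$ term that
   amplifies uphill fluctuations only.
4. **Spectral Fokker-Planck solver** (`solve_steady()`): the joint density in
   Gegenbauer/Legendre angular moments (10 orders by default, $10^4$ grid
   points, integration horizon $\tau = 10$), conservative finite-volume
   transport in $f$ with characteristic upwinding.
5. **Closed forms** (`steady_state_pdf()`, `exact_bounds()`, `mft_drift()`,
   `gaussian_limit()`): the first-moment closure of the moment hierarchy and
   its limits.

The stationary drift obeys the identity $V_D = \tau_E\,\langle f - f_0
\rangle$ (in units of $v_0$), which ties the spatial flux to the
internal-state excess and is checked for every simulated ensemble.

```{r drift-example, eval = FALSE}
p <- dimensionless_params(tau_e = 0.1, tau_d0 = 1)
ens <- langevin_fs(p, n_walkers = 2000, dt = 1e-3, tau_end = 100, seed = 1)
estimate_drift(ens, discard = 5)     # ~ 0.49 v0: the ratchet regime
```

## The closed-form steady state and its honest limitations

Truncating the angular-moment hierarchy after the first moment gives the
stationary marginal
$$\bar p(f) \propto \frac{r(f)/\tau_E}{B(f)}
  \exp\!\left(-\int_{f_0}^f \frac{f' - f_0}{\tau_D(f')\,B(f')}\,df'\right),
  \qquad B(f) = \left(\frac{r(f)}{\sqrt n\,\tau_E}\right)^2 - (f-f_0)^2,$$
supported where $B > 0$. Two families of support bounds coexist: the *exact*
process bounds $f_{L,U} = f_0 \mp r(f_{L,U})/\tau_E$ (no orientation can push
$f$ beyond them; every simulation honours them to within one Euler step) and
the *truncated* bounds of the closure, which carry an extra $1/\sqrt n$ and
are strictly nested inside. Both are exposed (`exact_bounds()`,
`truncated_bounds()`).

Three properties of the closure matter in practice; all were measured with
this package and drive the design:

* **Its drift is excellent.** $V_D$ from the closure matches the 10-moment
  solver and Monte-Carlo within a few percent across
  $\tau_E \in [0.1, 10]$ (e.g. 0.4736 vs 0.4898 $\pm$ 0.0043 at
  $\tau_E = 0.1$, $\tau_D = 1$).
* **Its shape is not trustworthy at $\tau_D \sim 1$.** The true distribution
  carries substantial mass between the truncated and exact bounds (17% of it
  at $\tau_E = 3$, 46% at $\tau_E = 0.1$, $\tau_D = 1$), so
  Kolmogorov-Smirnov distances between the closure and either the spectral
  solution or simulations are 0.10-0.46 there. The closure was derived for
  $\tau_D \ll 1$; at $\tau_D = 0.1$ the KS distance to the solver drops to
  0.003. At $\tau_E = 3$, $\tau_D = 1$ the closure is even weakly U-shaped
  across its narrow support while the true density is a bell at $f_0$ —
  identical mean and variance, inverted fine shape. Distribution-level
  validation in the tests therefore pairs the solver with Monte-Carlo
  everywhere, and adds the closure only in its validity domain.
* **Its edges are power laws.** Near a truncated bound the density behaves
  as $B^{c-1}$ with $c = |f_{\rm edge} - f_0| / (\tau_D(f_{\rm edge})
  |B'(f_{\rm edge})|)$; under strong positive feedback $c$ can be as small
  as 0.06, putting a large fraction of the mass closer to the edge than any
  floating-point grid can reach. `steady_state_pdf()` therefore combines a
  uniform core grid with geometrically edge-clustered points (down to
  $10^{-13}$ of the half-width; beyond that the bracket $B$ suffers
  catastrophic cancellation) and carries the unresolved tails as explicit
  point masses with the analytic exponents. The reported `edge_mass` is part
  of the distribution: means, variances, CDFs and the KS distance all
  include it, and total mass is 1 to $10^{-6}$.

The same truncation underlies the potential picture
(`potential_decomposition()`): $\bar p \propto e^{-V}$ with a spring constant
$k(f) = 1/(\tau_D(f) B(f))$ that stiffens to infinity at the truncated edges,
softens with $\tau_D$, and is weaker above $f_0$ than below it whenever
$r(f)$ and $\tau_D(f)$ increase with $f$ — the asymmetry that shifts mass
toward the upper bound.

Two classical limits close the analytics. For $\tau_E \gtrsim 1$ *and*
$\tau_D \ll 1$ the distribution is nearly Gaussian with
$\sigma^2 = \tau_D r_0^2/(n \tau_E^2)$ and normalization correction
$1 + \tau_D/4$ (`gaussian_limit()`); the mean-field drift is
$V_D = r_0 \tau_D'/(n \tau_E (1+\tau_D))$ with
$\tau_D' = \tau_D (D_T - D_R) r_0(1-r_0)/(r_0 D_R + (1-r_0) D_T)$
(`mft_drift()`, leading order only: the printed higher-order corrections in
the source derivation render ambiguously and are omitted). Both are
expansions in small $\tau_D$: at $\tau_D = 1$ the actual variance is half of
$\sigma^2$ (measured 0.50 by closure, solver and simulation alike, converging
to 1.0 as $\tau_D \to 0.01$), so `gaussian_limit()` flags validity and the
package's variance checks run at $\tau_D = 0.1$. The MFT drift is much more
forgiving: it sits within 3% of the closure already at $\tau_E = 10$,
$\tau_D = 1$.

## The spectral solver

`solve_steady()` expands $P(f, s)$ in orthonormal Gegenbauer polynomials of
the orientation cosine (Legendre for $n = 3$, with coupling entries
$k/\sqrt{4k^2-1}$ decreasing toward $1/2$ from above; for $n = 2$ the basis
degenerates to Chebyshev, with entries $1/\sqrt 2$ and then exactly $1/2$).
Multiplication by $s$ becomes a
symmetric tridiagonal coupling $S$, rotational diffusion a diagonal decay
$-k(k+n-2)/((n-1)\tau_D(f))$, and the $f$-advection operator
$A(f) = -(f - f_0)I + (r/\tau_E) S$ shares the $f$-independent eigenvectors
of $S$ — which makes exact characteristic (Roe) upwinding cheap. Numerical
choices, each visible in the API:

* uniform grid over the exact bounds plus a margin of 0.5 (fluxes vanish
  naturally outside the bounds; domain-end fluxes are zero, so mass is
  conserved to machine precision),
* explicit Euler at CFL 0.9 with the step also capped by the stiffest
  angular decay,
* isotropic Gaussian initial condition at $f_0$ (width 0.05), integration to
  $\tau = 10$ with early stop at a relative residual of $10^{-8}$,
* truncation closes the hierarchy by dropping order $K+1$; $K = 10$ changes
  the drift by under $10^{-6}$ relative to $K = 14$,
* magnitudes below $10^{-280}$ are flushed to zero (subnormal arithmetic in
  the far tails otherwise dominates the runtime).

The reached residual is reported; the operative convergence contract is
stability of $V_D$ under doubling $K$, the grid, or the horizon. The drift is
computed two ways from one solution — flux average
$\langle r s\rangle = \hat s_{01} \int r\, m_1\, df$ and the identity
$\tau_E \langle f - f_0\rangle$ — and their agreement within 1% is enforced.

## What the simulations emulate, and what they do not

The Langevin engines and the agent simulator generate all data in the
package; nothing is fitted to external measurements. They reproduce: Poisson
run/tumble statistics, rotational decorrelation at
$(n-1)(r D_R + (1-r) D_T)$ (verified at small $t_S$; at $t_S = 0.01\,t_M$
with $D_T/D_R = 37$ the *measured* rate sits a few tens of percent below the
formula because the instantaneous rate fluctuates between $2D_R$ and $2D_T$
with correlation time $t_S$ — a real effect of finite switching time, not an
integrator artifact), receptor log-sensing with saturation between
$K_i = 0.0182$ mM and $K_a = 3$ mM, and the stationary internal-state
distributions and drift speeds of the theory. They do not include cell-cell
interactions, attractant consumption, hydrodynamics, pathway-level
biochemistry (methylation kinetics, motor switching), or phenotypic
diversity; `sigma_f` provides a minimal additive stand-in for signaling
noise, with `sigma_m_from_expression_noise()` documenting the mapping from
expression noise to an equivalent methylation-noise amplitude. Passing tests
therefore validate the mathematics of the minimal model, not any particular
organism's parameters.

Euler-Maruyama steps default to $d\tau = 10^{-3}$ (dimensionless) and
$dt = 0.01$ s (agent); both engines refuse steps above
$0.01\,\min(1, \tau_D, \tau_E)$ and $t_S$ respectively. The orientation
cosine is reflected at $\pm 1$, the $(r, v)$ engine clips $r$ to
$[10^{-6}, 1 - 10^{-6}]$ and projects $|v| \le r$. All engines draw from R's
RNG in a fixed interleaved walker order, so a single `seed` argument makes
every trajectory reproducible.

## Phase-plane mechanics, precisely

Near the fixed point $(r_0, 0)$ the relaxation matrix is
$[[-1,\ r_0(1-r_0)/\tau_E], [0,\ -1/\tau_D]]$: always stable, with
eigenvector collinearity $\to 1$ as $\tau_E \to 0$
(`nonnormality_index()`; at $\tau_D = 1$ the matrix is defective and the
index is defined as 1). Two quantitative facts discovered while testing are
worth stating because they sharpen the usual telling of the mechanism:

* Deterministically, small symmetric perturbations $(r_0, \pm\delta)$ both
  decay monotonically — growth requires $v$ above the balance nullcline
  $v^* = \tau_E[(f(r) - f_0) + 1/((1-r)\tau_D(r))]$, which is $0.5$ at
  $r_0$ for $\tau_E = 0.1$, $\tau_D = 1$. The amplitude asymmetry of the
  noise-free flow is therefore bounded (uphill excursions saturate near
  $v \approx 0.6$ from $\delta = 0.6$), but the *persistence* asymmetry is
  enormous: the uphill excursion outlives its mirrored downhill twin by a
  factor $\approx 19$ at $\tau_E = 0.1$ versus $\approx 1.1$ at
  $\tau_E = 3$ (`excursion_asymmetry()`). Elongated uphill runs, abbreviated
  downhill ones — the ratchet.
* With noise, the regimes separate through the reachable speeds: ensembles
  started at $(r_0, \pm 0.05)$ reach mean maximal uphill speeds 1.6 times
  the downhill ones within two memory times at $\tau_E = 0.1$, and equal
  ones at $\tau_E = 3$.

The noise amplitude $\sqrt{2(r^2 - v^2)/((n-1)\tau_D(r))}$ is maximal at the
fixed point and vanishes at $|v| = r$: fluctuations evict the system from
the adapted state quickly, and the quiet corner at $(1, 1)$ lets it ride
long uphill runs.

## Gradient geometries and the desk-scale experiments

`gradient_profile()` provides the exponential field ($L = L_0$ constant:
steady-state drift exists), the linear field ($L = C_1/a_1 - R$ grows toward
the source: climbing slows down), the localized source
($C = C_2 R_0/R$ outside a ball, $L = R$ shrinks toward it: climbing
accelerates), and monotone-cubic tabulated profiles. With the two-state
receptor, saturation above $K_a$ inflates $L$ — near a 10 mM exponential
source the effective $L$ exceeds $L_0$ more than fourfold — which is how a
constant-$\tau_E$ environment turns into a position-dependent one.

`run_gradient_context()` reruns the three geometries with standard field
parameters ($C_0 = 10$ mM, $L_0 = 1000$ um; $C_1 = 1$ mM,
$a_1 = 10^{-4}$ mM/um; $C_2 = 1$ mM, $R_0 = 100$ um). Choices that were
genuinely open, decided once:

* Cells are matched-reorientation ($\tau_D \approx 1$, i.e.
  $D_R = 0.00625$, $D_T = 0.23125$ rad$^2$/s at $t_M = 10$ s,
  $v_0 = 20$ um/s): with literature-scale diffusivities ($\tau_D \approx
  0.1$) the weak-feedback classes need $> 10^4$ simulated seconds to move
  visibly, which defeats a desk-scale experiment without changing the
  science being illustrated.
* The `tau_e0` classes differ in receptor gain $N$ (cell types), fixed so
  that $\tau_E$ at the release position matches 0.1, 1, 3.
* The linear gradient is a planar ridge ($C = C_1 - a_1 |R|$, source plane
  at $R = 0$), so that overshoot past the source is geometrically possible;
  the localized source and exponential stay radial. Release at 600 um
  (linear) and 1000 um (localized), 1200/600 s horizons, $dt = 0.01$ s.

The runs reproduce: rising $\tau_E$ along the climb in the linear ridge,
falling $\tau_E$ during the approach to the localized source, and
first-arrival of the lowest-$\tau_E$ class. One often-expected trade-off —
that the strongest-feedback cohort overshoots and therefore settles
*farther* from the source than an intermediate one — does **not** appear in
the minimal model: here the opposite holds robustly, because the stationary
aggregate width scales like $D_x/V_D(\tau_E^{\rm local})$ and is smallest
for the strongest-feedback class (measured settle radii ~97 um vs ~460 um).
Overshoot-dominated settling requires ingredients beyond this model
(pathway-level dynamics, or observation at a finite horizon before the slow
cohorts equilibrate). The corresponding acceptance expectation is left
failing rather than redefined; it is the one known qualitative discrepancy
between the minimal model and the full-pathway picture.

## Experiment runners and the command line

`run_heatmap()` (drift over a $(\tau_E, \tau_D)$ grid),
`run_pdf_compare()` (closure vs solver vs Monte-Carlo with KS distances and
all four drift estimates), `run_gradient_context()` and
`run_consistency_report()` (machine-readable pass/fail table of the
cross-method invariants) are plain functions returning data frames; each
optionally writes CSV/JSON into an output directory together with the JSON
spec that regenerates it (`experiment_spec()`, `read_config()`,
`write_config()`). Desk-scale defaults use 1000-2000 walkers; `full = TRUE`
restores $10^4$-walker ensembles. `inst/scripts/runtumble.R` wraps the
runners for shell use. Trajectory exports are CSV/JSON throughout.

Problem sizes used by the test suite (chosen once for a single-CPU desk
budget, with standard errors always reported so scaled runs remain
interpretable): 2000-walker ensembles with $d\tau = 10^{-3}$ and horizons of
20-100 memory times for drift and distribution checks; the solver at its
full settings ($K = 10$, $10^4$ points, $\tau = 10$) for the three-way
comparison; 1500-2500-point grids and shorter horizons for unit-level
properties; 300-400 walkers for the agent-based geometry runs.

## Known limitations

* The first-moment closure misstates the distribution's shape (not its
  drift) outside $\tau_D \ll 1$; see above.
* The Gaussian-limit variance is wrong by a factor ~2 at $\tau_D = 1$ —
  a property of the expansion, reproduced by every method in the package.
* Agent-level decorrelation follows the composite-rate formula only for
  $t_S$ well below $t_M$ and $1/D_T$; the package defaults satisfy this,
  but the formula should not be expected to 10% accuracy at
  $t_S = 0.01 t_M$ with strongly unequal diffusivities.
* The deterministic amplitude ratio of symmetric $(r_0, \pm\delta)$
  excursions is 1 below the balance-nullcline threshold; asymmetry lives in
  persistence times and in the noisy dynamics.
* No pathway biochemistry: quantitative comparisons to organism-level data
  would need the full signaling model and its parameters, which are outside
  this package's scope.
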