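---
title: "A discrete Langevin model of ant movement in a bounded arena: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete Langevin model of ant movement in a bounded arena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antarena)
```

## The model

A single ant confined to a square arena (`|x| < L/2`, `|y| < L/2`, with
`L = 30` cm) is described by a discrete-time Langevin update at the camera
frame interval `dt`:

$$
\mathbf{x}(t + \Delta t) = \mathbf{x}(t) + \mathbf{v}(t)\,\Delta t, \qquad
\mathbf{v}(t + \Delta t) = \mathbf{v}(t) + \mathbf{F}(\mathbf{v})\,\Delta t
  + \mathbf{q}(t).
$$

The deterministic force combines a linear drag and a constant forward drive,

$$
\mathbf{F}(\mathbf{v}) = -\frac{\mathbf{v}}{\tau_D}
  + \frac{v_0}{\tau_D}\,\hat{\mathbf{d}},
$$

which balance at speed $v_0$. The random impulse is applied in the body
frame, $\mathbf{q} = q_T\,\hat{\mathbf{z}}\times\hat{\mathbf{v}} +
q_L\,\hat{\mathbf{v}}$, with $q_T$ and $q_L$ independent zero-mean Laplace
(double-exponential) variates of standard deviation $\sigma_T$ and
$\sigma_L$. A positive $q_T$ is a left turn; $q_L$ changes speed. The heavy
Laplace tails are an empirical property of tracked velocity changes, not a
convenience.

Three modelling commitments deserve emphasis:

* **The discrete map is the model.** `dt` is a model constant equal to the
  tracking interval (1/15 s), not a numerical discretization of an
  underlying SDE, so no higher-order integrator is appropriate. Analyses
  treat simulated trajectories exactly as the camera data are treated:
  velocities are forward differences of positions.
* **Persistent heading.** $\hat{\mathbf{v}}$ is undefined at
  $\mathbf{v}=0$, which matters because the ant is stopped at walls. The
  simulator carries a persistent unit heading, initialized uniformly at
  random, updated to the velocity direction whenever the speed is positive;
  it supplies the drive direction and the impulse frame at zero speed. This
  mirrors the fact that a stationary ant still has a body orientation.
* **Stop-at-wall protocol.** If a proposed position leaves the arena it is
  replaced by the nearest boundary point and the wall-normal velocity
  component is zeroed; the tangential component is untouched, so rapid
  motion along an edge survives contact. While the ant remains on a wall,
  the transverse impulse of the next step is sign-reflected to point away
  from the wall (for a symmetric zero-mean law this is distributionally
  identical to redrawing, at deterministic cost). Elastic reflection and a
  full stop were rejected as boundary rules: the first cannot produce the
  observed distributions, the second forbids the wall-running that is
  plainly visible in the data. No position-dependent force is included —
  any wall affinity in the model output is an emergent property of bounded
  stochastic motion, which is precisely the hypothesis the model exists to
  test.

Corner contacts are not discussed by the source analysis; our convention is
the natural composition of the per-wall rule: the proposal is clamped to the
corner, both velocity components are zeroed, the heading is retained, and
the inward-sign constraint is applied per wall (in the fixed order `+x, -x,
+y, -y`; at a corner the last applicable wall decides the transverse sign).
Corner contacts are rare enough that this choice is statistically
invisible, but it is pinned down for reproducibility.

## Parameters

All quantities are in cm and s; dimensionless numbers are separate fields.

| Parameter | Default | Meaning |
|---|---|---|
| `sigma_T` | 1.00 cm/s | sd of the transverse (turning) impulse |
| `sigma_L` | 1.25 cm/s | sd of the longitudinal (speed) impulse |
| `tau_D`   | 0.55 s    | drag relaxation time |
| `v0`      | 6.3 cm/s  | drive speed (drag/drive balance) |
| `dt`      | 1/15 s    | frame interval of the tracking camera |
| `L`       | 30 cm     | arena side length |

The defaults are the values estimated from the interior of the tracked-ant
data set; they are the *generative* conditions every simulation-based check
in this package uses. The ensemble protocol they emulate is 60 trials of
4500 steps (300 s), each trial started at the origin at rest with a uniform
random heading. Equilibrium statistics are insensitive to the initial
state, which the test suite verifies by comparing origin-started and
wall-started ensembles.

Derived scales (`derive_scales()`):

$$
v_\infty^2 = \frac{\sigma_L^2 \tau_D}{2\Delta t}, \qquad
\ell = v_\infty \tau_D, \qquad
\alpha = \frac{\sigma_L^2 - \sigma_T^2}{\sigma_L^2}, \qquad
u_0 = v_0 / v_\infty,
$$

giving $v_\infty \approx 2.54$ cm/s, $\ell \approx 1.40$ cm,
$\alpha = 0.36$ at the defaults. $v_\infty$ measures the random spread of
speeds around the drive; $\ell$ is the distance over which an ant stays
localized before turning around and sets the width of the near-wall density
enhancement.

## Equilibrium theory and an anisotropy correction

With periodic boundaries the model is homogeneous and isotropic and its
equilibrium distribution depends on speed only. `equilibrium_speed_pdf()`
implements the closed form

$$
\Pi(u) \propto \exp\!\left(\frac{-u^2 + 2u_0u + 2\alpha\ln u}{2}\right),
\qquad u = v/v_\infty,
$$

whose normalization $N_0$ is computed by adaptive quadrature on
$[0, u_0 + 12]$ (the exponent decays as $-u^2/2$; the neglected tail mass
is verified to be below $10^{-9}$, and the $u$-weight keeps the integrand
integrable at the origin for any exponent above $-1$). The speed at which
the ring-shaped shoulder of this distribution peaks is

$$
v_s = \frac{v_0 + v_\infty\sqrt{(v_0/v_\infty)^2 + 4\alpha}}{2}
\approx 6.65 \ \mathrm{cm/s},
$$

the positive root of $u^2 - u_0u - \alpha = 0$.

The $+\alpha\ln u$ weight descends from a kinetic expansion that treats the
direction-dependent diffusion coefficients as constants under the velocity
derivatives. The simulated map, however, applies its impulses in the frame
of the *pre-update* heading — a pre-point (Itô-like) construction. Carrying
the diffusion tensor $D = (1-\alpha)\,\mathbb{I} +
\alpha\,\hat{\mathbf{v}}\hat{\mathbf{v}}^\mathsf{T}$ through the
Fokker–Planck divergence properly, the radial probability flux is

$$
J_u = (u_0 - u)\Pi - \partial_u \Pi - \frac{\alpha}{u}\Pi,
$$

and the zero-flux equilibrium carries the opposite correction,
$\Pi \propto u^{-\alpha} e^{-u^2/2 + u_0 u}$. The two forms coincide for
isotropic impulses. At the default anisotropy the difference is visible at
large sample sizes: the acceptance suite shows that a Kolmogorov–Smirnov
comparison of $10^6$ simulated periodic-mode speeds against the
$+\alpha$ closed form fails a 0.01 bound by an order of magnitude, while
the unit tests verify the same samples match the $-\alpha$ law within
KS < 0.01 (and the agreement tightens as `dt` is refined). Both laws are
exposed via the `anisotropy_sign` argument; the printed $+\alpha$ form
remains the default because it is the published theory the package
implements, with this paragraph as the caveat. The shoulder location
shifts only mildly between the two ($v_s$ 6.65 versus 5.91 cm/s at the
defaults), consistent with anisotropy being a modest correction.

## The impulse law: sampling and estimation

The Laplace law is parameterized by its standard deviation,
$p(q) = (2\sigma^2)^{-1/2}\exp(-\sqrt{2}|q - \bar q|/\sigma)$, i.e. scale
$b = \sigma/\sqrt 2$. Sampling is by inverse CDF on R's uniform stream;
the compiled simulator uses the identical transformation and draw order
($q_T$ then $q_L$, two uniforms per step), so the pure-R reference stepper
`step_ant()` reproduces compiled trajectories bit-for-bit given the same
seed — a property the test suite asserts at $10^{-12}$.

Fitting uses the exact Laplace maximum-likelihood estimator: location =
sample median (midpoint convention for even counts), scale = mean absolute
deviation about the median, $\hat\sigma = \sqrt2\,b$. The source analysis
says only that the distributions were "fit"; MLE was chosen because it is
deterministic, fast, unbinned, and its bias is testable (below 1% at
$n = 10^5$ in the suite). Per-speed-bin fits require a minimum occupancy
(default 200 samples) so that the per-bin $\hat\sigma$ standard error stays
near 5%; sparser bins are dropped rather than fitted noisily.

## The measurement pipeline

`decompose_dv()` reproduces the tracking analysis: forward-difference
velocities, velocity changes $\Delta\mathbf{v}(t) = \mathbf{v}(t+\Delta t)
- \mathbf{v}(t)$ resolved in the frame of $\mathbf{v}(t)$, samples tagged
`interior` versus `boundary_strip` by a 3 cm rule on the position at time
$t$. Choices that the source leaves open:

* **Speed floor 0.1 cm/s.** The decomposition frame is ill-defined as
  $v \to 0$; excluded samples are counted and reported. The lowest-speed
  bins are where the constant-$\sigma$ approximation is weakest anyway.
* **Bins.** Speed 1 cm/s, position 1 cm, velocity 0.5 cm/s — matching the
  granularity at which the distributions are usually plotted; all
  configurable.
* **Force-fit window [3, 10] cm/s.** The longitudinal mean
  $\bar q(v) = \Delta t\,(v_0 - v)/\tau_D$ is linear in the model
  everywhere, but in data the relation is linear only where most samples
  fall; the window is configurable and echoed in the output. Weighted
  least squares (weights = bin occupancy) on the bin means, then
  $\hat\tau_D = -\Delta t/\mathrm{slope}$,
  $\hat v_0 = -\mathrm{intercept}/\mathrm{slope}$.
* **Lag-3 Pearson correlation.** Lags 1 and 2 are excluded because the two
  finite differences share position measurements by construction;
  correlations are computed within trajectories, pooled with sample-size
  weights, and restricted to interior samples — near walls the stop
  protocol imprints genuine correlations on the measured velocity changes
  that say nothing about the impulse stream. (Pooling boundary samples
  raises the magnitude to about 0.012 at experiment scale; interior-only
  gives a few parts in $10^3$, consistent with iid impulses.)
* **Averaging $\hat\sigma$ across bins.** Whether per-bin values should be
  weighted equally or by occupancy when quoting a single number is
  unspecified in the source; the acceptance script reports the
  occupancy-weighted mean, and both are trivially computable from the
  returned fit table.

## Residence-time statistics

A boundary visit starts at a discrete local maximum of $|x(t)|$ within
0.5 cm of the $|x| = L/2$ wall (half a body length: contact) and ends at
the first later sample with $|x| < L/2 - 3$ cm. Only the $x$ coordinate is
used, avoiding corner special cases; `+x` and `-x` events are pooled by
symmetry. Conventions chosen here: plateau runs of equal $|x|$ (exact on
the wall in stop mode) collapse to their first index; within one strip
sojourn only the first qualifying maximum opens an event (later maxima are
absorbed — we verified that logging every maximum instead changes the
residence-time distribution immaterially); events not closed before the
series ends are censored and dropped, with the count reported. The contact
velocity is reported with motion *toward* the wall positive, so events
always have $v_x(t_1) \le 0$.

The model's residence-time distribution decays on the scale of $\tau_D$
past its peak, but the 3 cm strip imposes a transit-time offset of roughly
0.5–1 s, so an appreciable fraction of events (about a fifth, as the
acceptance suite computes) outlasts $5\tau_D$. A stricter reading — under
a tenth of events beyond $5\tau_D$ — is not satisfied by the model at the
study conditions; the qualitative statement (decay scale $\approx\tau_D$,
no long tail of the kind produced by active wall-following) is what the
model supports.

## The one-dimensional reduction and near-wall asymptotics

The 1D variant advances $v \leftarrow v + \Delta t\,(v_0\,\mathrm{sign}(v)
- v)/\tau_D + q_L$ with stop walls at $\pm L/2$ and the first post-contact
impulse directed inward. The $\mathrm{sign}(v)$ drive is our construction
of the scalar analogue (the original 1D appendix is not available to us);
at a wall, $v = 0$ and the drive vanishes until an impulse restarts the
motion.

Continuum theory for this class of dynamics predicts an integrable density
divergence $n \sim d^{-2/3}$ at wall distance $d \ll \ell$.
`near_wall_exponent()` fits a log–log line over $d \in [\ell/50, \ell/2]$
(log-spaced bins; the wall-contact atom at $d = 0$ sits below the fit
range). The fitter is validated on synthetic $d^{-2/3}$ draws. At the
study time step, however, the discrete map does not reach the continuum
regime: crossing the whole fit window takes only a few steps, and the
fitted exponent comes out near $-0.2$, drifting toward $-2/3$ only as
`dt` is refined with $\sigma_L \propto \sqrt{\Delta t}$. The acceptance
suite therefore records a failure against the $-2/3 \pm 0.15$ band — a
genuine property of the discrete model at `dt = 1/15` s, not a fitting
artefact.

## Reproducibility and problem sizes

Randomness enters only through R's RNG. Trajectory $j$ of an ensemble is
seeded as $(\texttt{base\_seed} + 1000003\,j) \bmod (2^{31}-1)$, so
ensembles are reproducible trial-by-trial and independent of evaluation
order. The test suite uses ensembles between 4 and 240 trials of 300 s
(the acceptance checks use the experiment's 60-trial and a 200-trial
ensemble, $10^6$ equilibrated periodic-mode samples, and $10^7$ 1D steps),
sizes at which every stochastic tolerance asserted is several standard
errors wide.

## What the generator does and does not emulate

Simulated ensembles reproduce the study conditions: geometry, frame rate,
trial count and duration, and the fitted movement constants. They contain
no ant–ant interactions, no active (position-dependent) wall attraction,
and no environmental asymmetry — the measured preference for one arena
side (a window-facing wall) is deliberately outside the model, whose
distributions respect square symmetry exactly. Passing tests therefore
demonstrate internal consistency of simulator, theory and analysis
pipeline, and parameter recoverability at realistic sample sizes; they do
not certify that real ants follow the model, and the known discrepancies —
the residence-time tail attributed to active wall-following, and the
low-speed bending of the impulse spread in real data — are exactly the
places where the model is expected to fail.

## Known limitations

* The closed-form equilibrium carries the anisotropy correction with the
  opposite sign to the simulated map's true continuum limit (see above);
  use `anisotropy_sign = -1` when a quantitative reference distribution
  for simulation output is needed.
* The $d^{-2/3}$ near-wall law is a continuum statement not realized at
  the study time step.
* Constant $\sigma_T$, $\sigma_L$: the speed dependence visible in data at
  low speeds is not modelled.
* The boundary protocol is the minimal one; pausing, turning biases, or
  wall-attraction forces would need new parameters and data to fit them.
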