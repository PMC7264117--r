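---
title: "Modeling eye-position gain fields: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling eye-position gain fields: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainfields)
```

Many cortical visual neurons respond to a stimulus at a preferred retinal
location, with the *amplitude* — but not the retinotopic preference — of the
response modulated by where the eye is pointing. This vignette documents how
`gainfields` models that phenomenon, which knobs matter, and the numerical
and design decisions baked into the implementation.

## The hardwired model

Every neuron in the hardwired population is defined by a pair of Gaussian
tuning components that *add* at the level of internal activation:

$$h(x, y) = h_{max,r}\,e^{-(x-\alpha)^2/2\sigma^2}
          + h_{max,e}\,e^{-(y-\beta)^2/2\rho^2},$$

where $x$ is the retinal stimulus location, $y$ the eye position (both in
degrees), $\alpha$/$\beta$ the neuron's preferred values and $\sigma$/$\rho$
the tuning widths. The firing rate is the sigmoid
$v = 1/(1+e^{-2\varphi(h-\theta)})$. The essential mechanism is that an
*additive* activation, pushed through a saturating nonlinearity, yields an
approximately *multiplicative* interaction in the rate domain — which is what
gain fields look like in parietal recordings. Gaussian eye-position tuning
(rather than the linear tuning of earlier models) is the biologically
motivated choice, and the resulting population contains peaked, monotonic and
nearly linear modulation profiles at once.

Default parameters (`build_population()`): slope $\varphi = 1.9$, threshold
$\theta = 0.99$, $h_{max,r} = h_{max,e} = 0.485$, $\sigma = 6°$,
$\rho = 20°$, with $\alpha$ covering $[-10, 10]°$ and $\beta$ covering
$[-35, 35]°$ in $1°$ steps (1491 neurons; $\pm 35°$ is the functional limit
of orbital eye position during natural viewing). Note that at the preferred
condition $h = 0.97 < \theta$: the sigmoid's operating point is deliberately
below threshold, so rates stay in the lower, expansive part of the curve and
eye position can amplify strongly.

Why $\rho$ matters: a neuron whose preferred eye position sits at the edge of
the oculomotor range sees only one flank of its Gaussian across the testable
sweep. The broader the flank ($\rho$ large), the closer that flank is to a
straight line, so linearity — summarized by the $R^2$ of a least-squares line
fit to the eye sweep — rises with $\rho$ across the population. Experiments
override $\rho$ explicitly (`build_population(eye_width = ...)`); the
multiplicativity demonstrations conventionally use $\rho = 15°$.

Neurons are identified throughout by their $(\alpha, \beta)$ pair, never by a
storage index. The internal ordering (eye-major, retinal-fastest) is a
recorded convention with no analytical meaning.

## The self-organizing model

The second model asks how such responses could *develop*. A layer of 92 input
units (71 eye-position units, 21 retinal units, same Gaussian tuning shapes,
peaks $h_{max} = 2$, sigmoid $\varphi = 4.5$, $\theta = 0$) drives 100 output
neurons through a sparse random feedforward matrix:

* **Dynamics.** Each output is a leaky integrator,
  $\tau_h\,dh_i/dt = -h_i + \sum_j w_{ij} v_j$ with $\tau_h = 100$ ms,
  integrated by Forward Euler with $dt = \tau_h/10$.
* **Competition.** The rate is
  $v_i = 1/(1+e^{-2\varphi(h_i - p_\pi - \theta)})$, where $p_\pi$ is the
  $\pi$-th percentile of the current activations ($\pi = 90$ by default, so
  roughly 10% of outputs fire above half-maximum — the abstraction of lateral
  inhibition via interneurons).
* **Learning.** $dw_{ij}/dt = \varrho\,v_i v_j$ on existing synapses only,
  followed by renormalizing each output's weight vector to unit Euclidean
  norm (preventing unbounded growth). Rates and initial weights are
  non-negative, so weights remain non-negative: Dale's law is respected by
  construction.

Connectivity is $\phi = 10\%$: each output draws its afferents without
replacement from the inputs. Since $10\%$ of 92 is fractional we take
`floor`, i.e. 9 afferents per output, for determinism. Weights are drawn
uniformly on $[0, 1]$ on the mask and renormalized once at $t = 0$, so the
unit-norm invariant holds from the very start rather than only after the
first update.

### The training schedule

Training data are generated, not loaded: the generator *is* the experimental
protocol. Each of 10 epochs presents the stimulus at every retinal location
in $[-10, 10]°$ (sequential order by default; shuffling is available). While
a location is presented, the eye makes 15 fixations at uniform random integer
positions in $[-35, 35]°$, joined by 14 constant-velocity saccades at
400°/s; eye position interpolates linearly during saccades and the saccade
endpoint is exact (saccade durations are rounded up to whole integration
steps). The first fixation of each period is reached by an *un-counted*
transition saccade from wherever the previous period ended, which keeps the
15-fixations/14-saccades accounting exact.

Two stated timing conventions of the protocol cannot both hold: 15 fixations
of 300 ms alone last 4.5 s, yet each retinal location is nominally presented
for 2 s (giving the 21 × 2 s × 10 = 420 s nominal duration that
`nominal_training_duration()` reports). Both readings are implemented:
`schedule_mode = "fixation_defined"` (default) takes the fixation durations
literally (~5.3 s per period), `"nominal_2s"` rescales fixation durations so
each period lasts exactly 2 s. Neither is asserted to be the "true" protocol;
the default was chosen because fixation duration is the behaviorally
meaningful quantity.

What the generator does *not* emulate: realistic saccade kinematics
(main-sequence velocity profiles), neuronal noise, head or hand signals, and
any correlation structure between successive fixation targets. Tests passing
on this generator therefore show that the learning dynamics behave as
specified under idealized stationary input statistics — not that the model is
robust to biological variability.

### Units and the learning rate

The protocol gives $\tau_h$ in milliseconds and a bare $\varrho = 0.05$. We
use seconds throughout: $\tau_h = 0.1$ s, $dt = 0.01$ s, and
$\varrho = 0.05\ \mathrm{s}^{-1}$, so each Euler step adds
$dt\,\varrho\,v_i v_j = 5\times10^{-4}\,v_i v_j$ to a synapse before
renormalization. Because renormalization makes the *direction* of the weight
vector the learned quantity, the absolute scale of $\varrho$ mostly sets the
settling speed; under these units the per-epoch weight change is largest in
the first epoch and falls to less than half of it by the last (the
`mean_abs_dw` column of the training log; asserted over a 3-seed median in
the tests), i.e. self-organization settles within the nominal 420 s — which
is the behavior the protocol describes. A zero learning rate is treated as an exact no-op
(no renormalization jitter), so untrained and trained states are bitwise
comparable.

Learning is active during saccades as well as fixations by default — the
protocol does not gate it — and `learn_during_saccades = FALSE` provides the
gated alternative. Saccades are brief (~6% of simulated time), so the choice
is not load-bearing.

### Measuring trained responses

Responses of trained outputs are measured at the *fixed point* of the
dynamics for a held stimulus, $h_i = \sum_j w_{ij} v_j$, with the competitive
sigmoid applied across the population per condition — equivalent to holding
the condition for many time constants, without paying the settling time.
`trained_population_linearity()` evaluates the full 21 × 71 condition grid,
defines each output's *best retinal location* as the one maximizing its peak
rate, and computes eye-sweep linearity there. An activity gate (peak rate
≥ 0.1 and range ≥ 0.05 by default) excludes outputs too weak to interpret —
$R^2$ of a near-flat curve is noise. The gate is applied to self-organized
outputs only; hardwired neurons always respond well above it at their
preferred retinal location.

## Analyses

* **Linearity.** `linearity_r2()` fits rate against eye position by ordinary
  least squares (with intercept, via `stats::lm`) and reports
  $R^2 = 1 - SSE/SST$. Curves with $SST < 10^{-12}$ (constant) are flagged
  degenerate and assigned $R^2 = 0$ by convention — a profile that is flat or
  symmetric about the sweep midpoint is maximally non-linear, not undefined.
  The vectorized population path uses the closed-form normal equations and is
  tested to agree with the per-curve path to $10^{-10}$.
* **Histograms.** `r2_histogram()` uses half-open bins $[0, 0.2), \ldots$
  with a *closed* top bin so $R^2 = 1$ is counted exactly once; proportions
  are percentages of the population.
* **Multiplicativity.** For a family of retinal sweeps at different
  fixations, the best per-fixation scale constant relative to the
  straight-ahead curve has the closed form
  $c_e = \langle r_0, r_e\rangle / \langle r_0, r_0\rangle$; the family
  passes when the worst relative residual
  $\lVert c_e r_0 - r_e\rVert/\lVert r_e\rVert$ is at most the tolerance
  (default 0.05). The default is strict: in both models the fixation adjacent
  to the preferred eye position — the one with the largest amplification —
  carries a residual above 5% (the sigmoid compresses the peak of the scaled
  curve), while the remaining fixations sit well under it. The acceptance
  tests assert the strict criterion and record this as a known failure;
  "approximately multiplicative" behavior in this model family corresponds
  to worst-case residuals in the 5–20% range.
* **Profile classification.** `classify_profile()` is deliberately coarse
  plumbing, not science: *unresponsive* if the activity gate fails;
  *monotonic* if the argmax is within 2 grid steps of a sweep boundary and
  total variation ≤ 1.1 × range; *peaked* if the argmax is ≥ 5° interior and
  the curve falls by ≥ 20% of its range on both sides; ties resolve to
  monotonic. All thresholds are arguments.

## Numerical conventions

* Sigmoid exponents are clamped to ±700 before exponentiation: rates saturate
  to 0/1 instead of overflowing, with no effect in the models' operating
  range.
* The competition percentile uses the nearest-rank definition (the
  $\lceil \pi/100 \cdot N\rceil$-th smallest activation), recomputed at every
  integration step; interpolating definitions differ only between adjacent
  activation values and the choice is configurable at the call sites that
  need it.
* The compiled training loop (RcppArmadillo) is an optimization of the
  plain-R reference engine (`run_training(..., engine = "reference")`), which
  chains the exported single-step functions; the two are cross-checked to
  $10^{-12}$ in the tests, and identical seeds give bitwise-identical
  trajectories within an engine.
* A master seed expands into named sub-seeds (network initialization,
  schedule) so changing one consumer of randomness does not perturb the
  others.

## Problem sizes

The full hardwired population (1491 neurons × 71 eye positions) evaluates in
well under a second, and a complete 10-epoch training run (~113,000 Euler
steps) takes on the order of a second through the compiled loop, so the test
suite runs the *actual* study conditions rather than scaled-down surrogates:
the stochastic self-organization properties are asserted over 3 independent
seeds at full schedule length, and the width sweeps use the full
$\rho \in \{2.5, \ldots, 25\}°$ grids.

## Known limitations

* Multiplicativity is approximate by construction (see above); there is no
  parameter regime in this family where the strongest-amplified fixation
  aligns to within 5%.
* The profile classifier's thresholds are heuristics tuned for 1°-step
  sweeps over the default ranges; exotic grids deserve custom thresholds.
* No noise model: statistical significance testing of gain modulation
  against trial-to-trial variability is out of scope.
* The self-organized output population's composition (how many monotonic vs
  peaked units emerge) is seed- and $\rho$-dependent; individual trained unit
  identities are not reproducible across configurations and are never
  asserted — only population-level properties are.
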