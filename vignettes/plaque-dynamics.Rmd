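---
title: "Modeling atherosclerotic plaque dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling atherosclerotic plaque dynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquedyn)
```

plaquedyn implements two complementary families of discrete-time models
for atherosclerotic plaque dynamics: a logistic-map model of plaque burden
with a dynamic growth rate, and a ladder of Markov models — chain, spatial
chain, Markov random field — for plaque stability. Both are theoretical
instruments: surveillance imaging observes lesions at discrete visits, so
discrete-time models map naturally onto clinical follow-up, and the goal
is to reason about which dynamical signatures (oscillation, instability,
spatial clustering) a progressing lesion could exhibit and how they might
be read off serial measurements. No clinical dataset ships with the
package; every input is produced by the seeded synthetic generators.

## The logistic-map model

Plaque burden is the proportion $P_t \in [0,1]$ of the arterial lumen
occupied by plaque at visit $t$, evolving as

$$P_{t+1} = r\,P_t(1 - P_t),$$

with $r$ the net growth rate aggregating all pro- and anti-atherogenic
processes. The map's behavior is governed by $r$: burdens regress to zero
for $r \le 1$, converge monotonically to the fixed point $(r-1)/r$ for
$1 < r \le 2$, converge with damped fluctuation for $2 < r \le 3$,
oscillate through a period-doubling cascade above 3, and become chaotic at
the accumulation point $r \approx 3.56995$. `classify_regime()` encodes
this taxonomy. Boundary rates (exactly 1, 2 or 3) are assigned to the
lower regime — an arbitrary but documented tie-break; the clinically
motivated instability rule is the *strict* condition $r > 2$
(`classify_plaque_risk()`), so the tie-break never affects risk labels.

A decrease in burden is the model's signature of plaque erosion or
rupture: at rates above 2 the trajectory overshoots its equilibrium and
enters an oscillatory phase, which is the regime associated with
symptomatic disease. `simulate_trajectory()` records the first visit at
which the burden decreases as `oscillation_onset`.

One behavior worth knowing about: under a slowly drifting growth-rate
schedule (e.g. +0.08 per visit) starting from a rate near 1, the burden
*adiabatically tracks* the rising fixed point from below and never
decreases while the drift lasts — the oscillatory signature requires the
trajectory to overshoot its equilibrium, which happens when a small
plaque meets a rate already above 2 (or when the rate sits still long
enough for fluctuations to develop). The test suite pins down both
behaviors. Note also that with a rate near 1 and a small burden
($r < 1/(1-P_0)$), the very first visits contract the plaque, so a
literal "first decrease" can occur trivially early under such schedules.

### The growth rate as an aggregate

`growth_aggregate()` implements

$$r(P) = \alpha\,\bigl(1 + \beta_1 f_1(P) + \beta_2 f_2(P) +
  \beta_3 f_3(P) + \beta_4 f_4(P)\bigr),$$

with $\alpha$ the baseline rate and $f_1 \ldots f_4$ factor functions for
hemodynamic, inflammatory, mechanical and metabolic influences, weighted
by $\beta_i$. The model family names the factors but no functional forms,
so the factors are user-supplied callables with a small shipped library
(`factor_constant()`, `factor_linear()`, `factor_saturating()`). Because
established lesions rarely regress, the emitted rate is floored at
`r_lower_bound` (default 1); an optional per-visit increment models
secular drift of the rate. The evaluation order is fixed and tested:
aggregate, then increment, then floor (and a hard clamp at 0, since a
negative rate is meaningless in the map).

The increment is *additive* by default (`r + increment * (visit - 1)`);
a multiplicative mode is available. Where the source material describes a
"constant factor per generation" of 0.05–0.08, a literal multiplicative
factor of that size would collapse the rate toward zero, so the additive
reading is the only dynamically sensible one and is the default.

### Lumen remodeling

Positive remodeling expands the lumen from $A_0$ toward a maximal area
$A_{max}$ in early disease. Only the limit is specified by the biology;
the approach is realized geometrically, $A \leftarrow A + \rho\,(A_{max}
- A)$ with per-visit rate $\rho \in (0,1]$ (`remodeling_lumen()`,
`update_lumen()`), which is monotone and converges to $A_{max}$. $P$ is
interpreted relative to the *current* lumen, so remodeling lowers the
derived quantity `stenosis_vs_baseline` $= P\,A(t)/A_0$ at fixed plaque
mass; this auxiliary series is reported but never fed back into the map
(the two equations are deliberately decoupled — the source model never
couples them).

### Instability as a function of stenotic degree

For a plaque of burden $P$, the fraction of growth rates
$r \in [0, r_{max}]$ that produce a decrease at the next visit is

$$\Pr\bigl(rP(1-P) < P\bigr) = \min\!\left(1,
  \frac{1}{r_{max}(1-P)}\right),$$

rising with $P$ and saturating at 1 at $P = 1 - 1/r_{max}$ — for the
default $r_{max} = 3.5$, at $P = 5/7 \approx 0.714$, i.e. around a 70%
stenosis, which echoes the clinical threshold for severe disease.
`instability_proportion()` evaluates the closed form; a brute-force grid
method is kept as an independent cross-check and the tests compare the
two to $2\times10^{-6}$ on a $10^6$-point grid.

### Chaos diagnostics

`lyapunov_exponent()` averages $\ln|r(1-2P_t)|$ along the orbit (1e5
iterations after burn-in by default; terms where the derivative is
exactly zero are skipped). `chaos_onset()` scans $r \in [3.4, 3.7]$ in
steps of $2\times10^{-3}$ for the first positive exponent and bisects the
bracketing interval; taking the first crossing *from below* makes the
search robust to the periodic windows interleaved above the onset. The
burn-in is $10^4$ iterations — longer than the generic default — because
transients decay slowly on the high-period cycles just below the
accumulation point. The result is 3.56995 to five decimals.

`first_bifurcation()` bisects the period-1/period-2 boundary of
`attractor_period()`. Period counting uses a long burn-in ($10^6$
iterations; cheap in the compiled kernel) because of critical slowing
near the bifurcation: with only a few thousand burn-in steps, the decaying
transient at $r$ just below 3 is still larger than the $10^{-8}$
distinctness tolerance and masquerades as a 2-cycle, biasing the boundary
by several $10^{-3}$. With the long burn-in the misclassification band
shrinks to about $2\times10^{-5}$ and the estimate is 3.000.

### Reading growth rates from surveillance

Serial planimetric measurements invert the recurrence interval by
interval: $\hat r_t = P_{t+1} / (P_t(1-P_t))$ (`estimate_r_series()`).
The inversion is exact on noiseless series; intervals starting at a
degenerate measurement (0 or 1) are flagged `"undefined"` rather than
dropped. `classify_plaque_risk()` applies the strict $r > 2$ rule to the
latest (default) or mean estimate. This estimator is deliberately naive —
it is the direct algebraic reading of the recurrence, not a smoothed or
regularized fit — and its noise sensitivity is quantified by the
parameter-recovery tests: with truncated-Gaussian measurement noise, the
median absolute error of $\hat r$ shrinks roughly in proportion to the
noise SD across {0.02, 0.01, 0.005}.

## The Markov ladder

### Two-state chain

Plaque stability is a two-state system (Stable, Unstable; indexed in that
order everywhere). The destabilization probability is the linear
covariate model

$$P(S \to U) = \text{base} + w_1 I + w_2 L + w_3 S + w_4 B,$$

over inflammation, lipid content, shear stress and plaque burden
(`transition_probability()`). A linear form can leave $[0,1]$; values are
clamped and *every clamping event is recorded* (and counted at the grid
level, with a warning when more than 1% of sites clamp), because silent
clamping would hide misconfigured weights. A logistic link — the same
linear predictor on the log-odds scale — is available behind the `link`
argument; the linear-clamped form remains the default because the model
is specified linearly. The reverse transition has no covariate model and
is a constant `p_us`.

`stationary_distribution()` computes the long-run occupancy as the left
eigenvector of the transition matrix at eigenvalue 1 (via `eigen()`); the
closed form $\pi_S = p_{us}/(p_{su}+p_{us})$ is used as the *oracle* in
tests, not as the implementation, so the two routes check each other. The
degenerate chains $p_{su}=p_{us}=0$ (reducible) and $=1$ (periodic) are
rejected with the mixing conditions spelled out.

The destabilization parameter appears in two roles that the source model
uses interchangeably: a one-step probability (in the matrix) and a
continuous-time hazard (in the survival curves $P(S\to S) = e^{-\alpha t}$,
`event_probabilities()`). Both readings are retained in separate
operations with separate parameter names, and
`hazard_from_step_probability()` converts explicitly
($\lambda = -\ln(1-p)$ per unit interval). Neither is "corrected" —
flattening the distinction would misrepresent the model family.

### Spatial chain

The lattice (`plaque_grid()`) represents a flattened plaque-surface patch:
4-neighbor adjacency and non-periodic boundaries by default (a patch has
edges); 8-neighbor and periodic variants are available. The dependence
matrix $D$ (`build_dependence_matrix()`) holds kernel weights $d_{ij}$ of
the Euclidean inter-site distance — uniform or exponential decay, zero
beyond the kernel `range`, diagonal 1 by convention. The spatial term of
the transition model is the dependence-weighted fraction of unstable
neighbors, $D_i = \sum_j d_{ij}\mathbf{1}[s_j = U] / \sum_j d_{ij}$
(`neighbor_term()`, diagonal excluded), entering as $+\,w_5 D_i$.

The element-wise (Hadamard) coupling of dependence into the transition
matrix is dimensionally ambiguous as specified ($D$ is site-by-site, the
transition matrix state-by-state), so two faithful readings ship:

* **scalar pathway** (default, used by `instability_heatmap()`): $D$
  collapses to the per-site scalar $D_i$ entering the linear model above;
* **matrix pathway** (`spatial_transition_matrix()`): each site derives a
  2×2 modifier block whose $S\!\to\!U$ entry is inflated by $1 + D_i$,
  combined with the base matrix by `hadamard_combine()`. (Scaling an
  entire row — the most literal reading — is a no-op after
  renormalization, so the modifier acts on the destabilization entry.)

The Hadamard product of a stochastic matrix with an arbitrary
non-negative modifier is not stochastic, so rows are always renormalized
and the total mass adjusted is reported (`"mass_adjusted"` attribute); a
row annihilated by the product is a degenerate model and an error.

Heatmaps are written by `write_heatmap()` as CSV (authoritative, 12
significant digits) plus a PNG render on a fixed blue-to-red $[0,1]$
scale so that heatmaps from different models are directly comparable.

### Markov random field

`mrf_model()` defines the Gibbs distribution
$P(\text{config}) \propto e^{-\beta E(\text{config})}$ with
$E = \sum_i V(s_i) + \sum_{(i,j)} U(s_i, s_j)$, the pair sum running
*once over each undirected edge* (the double-sum notation is ambiguous;
edges-once is the convention here, and $U$ must be symmetric). The
"transition matrix" language sometimes attached to this object is
mathematically a distribution over configurations, which is what is
implemented; the per-site conditional flip probabilities used by the
sampler are the transition-flavored reading.

No functional form for the potentials is prescribed by the model family,
so the default is the simplest family consistent with neighboring sites
sharing stability: $V(U) = v_u$ (optionally plus a per-site field, e.g. a
covariate-linear predictor, via `ising_model(v_site = )`) and the
attractive Ising coupling $U(s,s') = -J\,\mathbf{1}[s = s']$, $J \ge 0$.
Arbitrary potential tables are accepted.

`exact_distribution()` enumerates all $2^n$ configurations for lattices
of at most 20 sites and is the oracle for the sampler;
`gibbs_sample()` is a systematic-scan single-site Gibbs sampler (raster
order, one retained configuration per sweep, burn-in default 1000,
seeded). `marginal_instability()` returns the per-site probability of
instability by either route, in the same matrix layout as the spatial
heatmaps.

On sampler validation: the tests compare sampled marginals against
enumeration across 50 random Ising-family potentials
($v_u \sim U(-1,1)$, $J \sim U(0, 0.5)$) on lattices up to 12 sites,
using batch-means standard errors (50 batches) to account for sweep
autocorrelation. With ~400 simultaneous site comparisons, a *correct*
sampler still produces the nominal 0.27% share of $|z|>3$ excursions, so
the band is enforced per site at 3 SE together with the matching 1%
familywise allowance and a hard 5 SE ceiling — a biased sampler fails
this check by a wide margin, while a correct one passes it with
probability essentially 1.

## Synthetic data

`generate_measurement_series()` emulates surveillance imaging: a
noiseless trajectory under a constant or drifting rate, plus additive
Gaussian measurement noise truncated (by rejection) so observations stay
strictly inside $(0,1)$. The default noise SD of 0.01 is a stand-in — no
observation model is prescribed by the source material — chosen as
roughly sub-resolution of surveillance ultrasound. The generating rate of
every interval travels with the series for recovery studies.
`generate_covariate_grid()` produces covariate fields as white Gaussian
noise (SD 0.3 around unit means), optionally smoothed by a moving-average
filter to induce spatial correlation, clipped at zero, with an optional
rectangular hotspot (e.g. a focal inflamed region).

What the generators do *not* emulate: ultrasound physics, segmentation
error structure (noise is homoscedastic and independent across visits),
registration drift between visits, or any mapping from real 3-D plaque
geometry to the flattened lattice. Passing tests therefore demonstrate
internal consistency of the models and estimators under idealized
observation, not clinical validity — the $r > 2$ instability rule in
particular is a modeling hypothesis, not a validated biomarker.

## Numerical and testing choices

* Problem sizes: Lyapunov estimates average $10^5$ iterations; period
  detection uses $10^6$ burn-in steps; the stationary-distribution
  oracle comparison runs 1000 random chains; chain simulations use
  $10^5$ steps; Gibbs validation uses 5000 sweeps per model. These sizes
  make every quantity reproducible to well inside its stated tolerance
  while keeping the full suite under a minute for the deterministic
  parts.
* All randomness flows through R's RNG: every stochastic routine takes a
  `seed` argument (or inherits the caller's RNG state when `seed = NULL`),
  and the compiled kernels use R's generator, so `set.seed()` governs
  everything.
* Convergence-to-fixed-point properties are tested for
  $r \in (1.1, 2.9)$: arbitrarily close to the neutral boundaries
  $r = 1, 3$ the geometric convergence rate degenerates and no fixed
  iteration budget suffices.
* Degenerate inputs fail loudly and specifically: out-of-range burdens
  and rates name the offending parameter, trajectory escapes report the
  visit index, non-finite factor evaluations name the factor, unknown
  config keys are all listed, oversized enumeration requests point to the
  sampler.

## Known limitations

The growth-rate estimator is exact only under the model; model
misspecification (true dynamics not logistic) biases $\hat r$ in ways the
package does not quantify. The MRF offers no parameter estimation — the
potentials are inputs, reflecting the acknowledged difficulty of fitting
such fields. The spatial model's two Hadamard readings are both provided
precisely because the intended operand shapes are ambiguous; neither is
claimed as the definitive interpretation.
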