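---
title: "Noise suppression by proxy-mediated feedback and feedforward circuits"
author: "proxyreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise suppression by proxy-mediated feedback and feedforward circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyreg)
```

## The model

Two species are produced under the control of a common input signal $u$: a
species of interest $Y$ and an intermediary $X$ whose abundance carries
information about $Y$ because their production is co-regulated ($X$ is a
*proxy* for $Y$, like a reporter fused to the same promoter). Regulation can
use that information in two ways:

* **Feedback (FB)** — $X$ inhibits the production of both species: rates
  $f(u)\,g(x)$ for production, $l_1 x$ and $l_2 y$ for degradation.
* **Incoherent feedforward (IFF)** — $X$ mediates the degradation of $Y$:
  production at $f(u)$, degradation at $k_1 x$ and $k_2 y + k_{12} x y$.

Each motif comes in a **coupled** flavour (one reaction emits $X$ and $Y$
together, as for genes on one transcript) and a **decoupled** flavour (two
reactions with identical rate laws). A **combined** circuit lets $X$ act on
both production and degradation, and **direct feedback** dispenses with the
proxy altogether ($Y$ inhibits its own production).

To compare architectures fairly, every circuit is *normalized* to the same
nominal operating point: $k_1 = l_1$, $k_2 + k_{12}\bar x = l_2$ and
$g(\bar x) = 1$, where $\bar x = f(\bar u)/l_1$ and $\bar y = f(\bar u)/l_2$
are the common steady-state means. All circuits then consume the same
production and degradation fluxes, and differ only in how aggressively they
regulate. That aggressiveness is a dimensionless **effective gain**:

$$\alpha_{fb} = -\bar x\, g'(\bar x), \qquad
  \alpha_{ff} = \frac{\bar x\, k_{12}}{k_2}, \qquad
  \alpha_{comb} = \alpha_{fb} + \alpha_{ff} + \alpha_{fb}\alpha_{ff}.$$

```{r}
circ <- make_circuit("fb", "coupled", input_spec(a = 5, b = 0, u_nominal = 10),
                     l1 = 5, l2 = 1, alpha_fb = 1)
steady_state(circ)
effective_gain(circ)
```

Two inhibition families are implemented. The **ramp**
$g_R(x) = \max(1 + \alpha - \alpha x/\bar x,\, 0)$ is linear down to zero at
$x_0 = \frac{1+\alpha}{\alpha}\bar x$; it makes all propensities affine on
the reachable lattice, so stationary moments are exact. The **Hill** form
$g_H(x) = (1+c)/(1 + c (x/\bar x)^n)$ is the smooth counterpart; we expose
the gain as the user-facing knob and solve $n = \alpha(1+c)/c$ at fixed
$c = 10$, which makes ramp and Hill circuits gain-matched by construction
(e.g. $n = 11$ realizes $\alpha = 10$). Infinite gains are tagged limits,
never floating-point infinities inside rate arithmetic: the IFF limit is
represented exactly as $k_2 = 0$; an "infinite" FB gain must be approximated
by a large finite ramp slope.

## Three sources of variability

**Static cell-to-cell input differences** (e.g. plasmid copy number): each
cell holds one value of $u$ for its lifetime, drawn here from a Poisson law.
Both motifs respond through the same steady-state curve
$$y_{ss}(u) = \bar y\,\frac{(1+\alpha) f(u)}{f(\bar u)\,
  \bigl(1 + \alpha f(u)/f(\bar u)\bigr)},$$
whose slope at the nominal input is
$\partial y_{ss}/\partial u = \bar y f'(\bar u) / \bigl(f(\bar u)(1+\alpha)\bigr)$.
Gain suppresses static variability without limit, identically for FB and
IFF, and the combined circuit obeys the same formulas with $\alpha_{comb}$
(which exceeds the sum of its parts). The closed form above is fixed by its
three limits ($u = \bar u$, $\alpha = 0$, $\alpha \to \infty$) and is
verified against ODE steady states in the tests.

**Dynamic input fluctuations**: the package linearizes a circuit about its
operating point and computes the squared H2 norm of the input-to-output map
by solving the stationary Lyapunov equation $AP + PA^\top + BB^\top = 0$;
this equals the stationary output variance under white-noise input. Feedback
can drive it to zero as the gain grows; any feedforward implementation is
bounded below by $\sigma^2 / (2(l_1 + l_2))$, approached as
$\alpha_{ff} \to \infty$. For slower inputs, a birth–death process drives
the full nonlinear ODE and the trajectory cv is reported.

**Intrinsic reaction stochasticity** is where the architectures hit a hard
wall, analysed by four routes that cross-validate each other (exact moments,
moment closure, LNA, and FSP/SSA oracles).

## Exact moments for ramp feedback

With ramp inhibition the production propensity is affine in $x$ on its
support, so first- and second-order moment equations close *exactly*. The
package builds and solves this linear system from the reaction scheme
(`fb_stationary_moments()`), rather than hard-coding results, and
cross-checks the solution against the closed forms
$$\mathrm{var}(y) = \frac{\bar y}{1+\alpha} + P_{proxy} \;(+\, P_{dec}),\quad
  P_{proxy} = \bar y\,\frac{\alpha(\alpha+r)}{(1+\alpha)(1+\alpha+r)},\quad
  P_{dec} = \bar y\,\frac{\alpha}{1+\alpha+r},$$
with $r = \bar x/\bar y$. The exact solution requires the ramp cutoff $x_0$
to sit on the integer lattice; for arbitrary requested gains the cutoff is
rounded and the realized gain $\alpha_{eff} = \bar x/(x_0 - \bar x)$ is
reported alongside the request. Direct feedback ($Y$ inhibiting itself)
gives a binomial stationary law with $\mathrm{var}(y) = \bar y/(1+\alpha)$ —
noise suppression without limit. The proxy penalty is what changes the
story: minimizing the coupled variance over the gain gives
$\alpha^\ast = \sqrt{1+r}$, a best-case 25% reduction as $r \to 0$,
about 17% at $r = 1$, and nothing as $r \to \infty$; with decoupled
production any feedback makes things worse.

When both noise sources act at once (random static input *and* reaction
noise), `static_mixture_variance()` applies the law of total variance with
exact per-input conditional moments, and provides the closed forms for the
three limiting realizations (no feedback; strong coupled; strong decoupled,
the latter two stated at the maximal lattice-consistent gain with
$\bar x = \bar y$). The preference threshold between no feedback and strong
decoupled feedback is computed as the exact crossing of the two variance
expressions, $\bar u^\ast = C^2/(l_2(C+b) - l_2^2)$ with $C = a\bar u$.

## Derivative-matching closure for the feedforward circuit

The mediated degradation $X + Y \to X$ makes second-order moment equations
depend on $\langle x^2 y\rangle$ and $\langle x y^2\rangle$. These are
closed by derivative matching, which for a two-species network approximates
a third-order moment by a product of lower-order ones:
$$\langle x^2 y\rangle \approx
   \frac{\langle x^2\rangle \langle xy\rangle^2}
        {\langle x\rangle^2 \langle y\rangle}, \qquad
  \langle x y^2\rangle \approx
   \frac{\langle y^2\rangle \langle xy\rangle^2}
        {\langle y\rangle^2 \langle x\rangle}.$$
(The exponents follow from matching time derivatives on point-mass
distributions; $x$ itself is exactly Poisson because its production rate is
constant, so its moments enter as knowns.) The resulting three-equation
algebraic system is solved by damped Newton iteration with continuation in
the gain from the analytic no-regulation start; negative-variance roots are
rejected and retried from a perturbed start. Special cases bypass the
closure: $\alpha_{ff} = 0$ and the coupled $k_2 = 0$ limit are Poisson
($\mathrm{var}(y) = \bar y$, which FSP confirms *exactly* for the coupled
limit), while the decoupled $k_2 = 0$ limit pays
$P = \bar y/(1 + \bar x/\bar y)$ — doubling the variance as $\bar x \to 0$,
vanishing as $\bar x \to \infty$.

The optimal gain is $\alpha^\ast_{ff} = (\bar x + \bar y)/(1 + \bar x + \bar y)$,
always below 1, and the achievable reduction mirrors feedback's: about 25%
at best for populations of at least one molecule, under 25% for populations
of at least 2. **Validity region**: the closure's stationary mean should sit
within a few percent of $\bar y$. Below roughly one mean molecule it drifts
by more than 10% (checked against FSP) and the apparent reduction keeps
growing — FSP confirms true reductions above 30% down there, so the
sub-molecule regime is excluded from the default population scan
(`iff_reduction_scan()` covers means from 1 to 200); this is a documented
limitation of both the closure and the "≈25–30% cap" summary itself.

## LNA and the per-reaction variance budget

The linear noise approximation writes fluctuations as a Gaussian process
$dz = Az\,dt + S\,\mathrm{diag}(\sqrt{w})\,dW$ with one diffusion column per
reaction channel. Because the Lyapunov equation is linear in the diffusion
matrix, the stationary $\mathrm{var}(y)$ splits *exactly* into per-channel
contributions (`per_reaction_decomposition()`), which the package verifies
sum to the total at $10^{-9}$ relative. Two structural facts follow:

* at zero gain, channels whose propensities do not involve the gain carry
  exactly 50% of $\mathrm{var}(y)$ — the controller cannot touch that half;
* the coupled controller acts on one *correlated* source (shared
  production) and one *uncorrelated* one (degradations): the tradeoff
  yields at most a 50% cut of the controllable half (25% overall, at
  $r \to 0$), while the decoupled controller acts only on uncorrelated
  noise and any gain inflates the variance.

For the ramp feedback scheme the LNA variance coincides *algebraically*
with the exact moment solution
($\mathrm{var}(y)/\bar y = 1 - \alpha/((1+\alpha)(1+\alpha+r))$), a
coincidence of affine propensities that the tests exploit as a strong
cross-method check. The combined circuit, optimized over both gains
(`optimize_gain_lna()`), hits the same 25% cap with the optimum on the
ridge $\alpha_{comb} = 1$: the bottleneck is the noisy proxy, not the
regulation strategy.

## Oracles

**FSP**: the stationary distribution of the truncated chemical master
equation is obtained as the null vector of the truncated generator (sparse
LU). Out-of-bounds transition targets are *projected onto the box* rather
than deleted — plain propensity zeroing creates an absorbing corner state
for the pure mediated-degradation scheme ($k_2 = 0$: at $x = 0$ on the $y$
boundary nothing can fire) and with it a spurious stationary solution. The
truncation certificate is the stationary mass on the outermost boundary
shell, auto-expanded below $10^{-8}$; the ramp bounds the $x$ marginal
exactly at $x_0$, and tests verify that one further expansion moves moments
by less than $10^{-6}$. For extreme probability ranges the solve falls back
to a diagonally regularized factorization polished by iterative refinement.

**SSA**: an exact-jump (direct method) simulator, compiled, with three input
regimes — fixed $u$, one Poisson draw per run (cell-to-cell variability),
or $u$ co-simulated as a birth–death species. Cross-run moments of
$y(t_{final})$ carry bootstrap standard errors; within-run time averages
over the second half of each trajectory provide cv estimates. Stationarity
horizon: $t_{final} = 20/\min(l_1, l_2)$.

## Synthetic inputs

`sample_static_poisson_u()` and `simulate_birth_death_u()` generate the two
explicit input regimes (white noise is carried as an intensity and consumed
by the SDE integrator, since its sampling is step-size dependent). Both are
bit-reproducible under a seed and leave the caller's RNG stream untouched.
The generators emulate idealized regimes — a Poisson copy-number law and a
memoryless birth–death signal. Real inputs have burstier distributions and
non-exponential correlation; passing tests therefore certify the *methods*
under the stated laws, not the behaviour of any particular biological input.

## Numerical choices

* **ODE integration**: `lsoda` at `rtol = atol = 1e-9`; the maximum step is
  capped at $0.1/\max(l_1(1+\alpha_{fb}), l_2)$ for constant inputs (so the
  ramp corner is not stepped over) and at the mean inter-event gap, capped
  at 0.05, for piecewise-constant input trajectories.
* **SDE ensembles**: Euler–Maruyama with
  $dt = \min(10^{-3},\, 0.1/\text{fastest rate})$, the same scalar Wiener
  increment on both equations ($\sigma[1,1]^\top$), reflection at zero by
  clipping, 10% transient discard where time averages are taken, bootstrap
  CIs across runs. The H2-vs-ensemble cross-validation scales $\sigma$ into
  the linearization's validity region,
  $\sigma = \min(5,\, 2\bar x/(1+\alpha))$: at gain $\alpha$ the ramp's
  active region has halfwidth $\bar x/\alpha$, and noise beyond it
  saturates the inhibition (plus clipping at zero), so large-$\sigma$
  ensembles sit far above the linear prediction at high gain — a real
  nonlinear effect, visible in the `fig1f` experiment tables, not a solver
  artifact.
* **Closure continuation**: 25 gain steps, Newton tolerance $10^{-11}$
  relative, positivity-preserving damping.
* **Gain optimizations**: golden-section (`optimize`) for one gain;
  box-constrained quasi-Newton plus coordinate polishing for the combined
  circuit (the valley is flat along $\alpha_{comb} = 1$, so the *value* is
  sharp while individual gains are not).
* **Problem sizes**: FSP lattices are sized mean $+\,10\sqrt{\text{mean}} + 10$
  per species (a few $10^4$ states at the reference populations); SSA
  defaults to 4,000 runs with standard-error columns so the precision of
  any comparison is explicit; ensemble SDE defaults to 500–1,000 runs.

## Known limitations

* The exact feedback solution is restricted to ramp inhibition and burst
  size 1; Hill circuits are handled numerically (FSP tracks the
  gain-matched ramp within ~1% at the reference populations, but *static*
  response distributions under input variability can differ from the ramp's
  by tens of percent at intermediate gain, since slope matching fixes only
  the local behaviour).
* The derivative-matching closure loses accuracy below about one mean
  molecule, and its variance-reduction summary is not capped there.
* The LNA is a second-moment description; for nonlinear propensities
  (Hill, mediated degradation) it inherits the usual small-noise bias.
* Strong-feedback mixture formulas assume the maximal lattice-consistent
  gain with $\bar x = \bar y$; other abundance ratios shift the intrinsic
  term by $O(\bar y/\bar x)$.
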