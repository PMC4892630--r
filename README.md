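# proxyreg

Noise analysis of gene-regulatory circuits in which an intermediary
("proxy") species *X* regulates a species of interest *Y* — either by
inhibiting production (negative **feedback**, FB) or by mediating
degradation (**incoherent feedforward**, IFF). The package is for systems
and synthetic biologists asking a design question: *given that I can only
sense Y through a co-produced proxy, how much output noise can regulation
remove, and which architecture should I build?*

Both motifs are normalized to the same operating point
(`k1 = l1`, `k2 + k12*x̄ = l2`, `g(x̄) = 1`, so `x̄ = f(ū)/l1`,
`ȳ = f(ū)/l2`) and compared at matched *effective gain*

    α_fb = −x̄ g′(x̄),   α_ff = x̄ k12 / k2,   α_comb = α_fb + α_ff + α_fb α_ff.

Headline results the package derives and verifies:

* **Static input variability** (cell-to-cell differences in `u`): both
  motifs follow the same steady-state curve with sensitivity
  `ȳ f′(ū) / (f(ū)(1+α))` — suppression without limit as gain grows.
* **Dynamic input noise**: the squared H2 norm of the linearized circuit
  (a Lyapunov solve) equals the stationary output variance; feedback can
  drive it to zero, feedforward is floored at `σ²/(2(l1+l2))`.
* **Intrinsic reaction noise**: with ramp inhibition the FB stationary
  moments are exact, `var(y) = ȳ/(1+α) + P_proxy (+ P_decouple)`; the best
  coupled-FB reduction is 25% (at gain `α* = √(1+r)`, `r = x̄/ȳ → 0`),
  ≈17% at `r = 1`, and decoupled production makes any feedback harmful.
  The IFF counterpart (derivative-matching moment closure) is capped
  similarly, with optimum `α* = (x̄+ȳ)/(1+x̄+ȳ)`. A per-reaction LNA
  decomposition shows why: half of the unregulated variance comes from
  gain-independent channels, and even the combined FB+IFF circuit cannot
  beat the 25% cap (optimum on the ridge `α_comb = 1`).
* **Oracles**: finite state projection (sparse stationary CME solve with a
  truncation certificate) and a compiled exact-jump SSA with fixed,
  static-Poisson, or birth–death inputs, cross-validating every analytic
  route.

## Worked example

```r
library(proxyreg)

## a normalized feedback circuit: f(u) = 5u, ū = 10, l1 = 5, l2 = 1, gain 1
circ <- make_circuit("fb", "coupled", input_spec(a = 5, b = 0, u_nominal = 10),
                     l1 = 5, l2 = 1, alpha_fb = 1)
circ
#> <circuit_spec> motif=fb coupling=coupled
#>   f(u) = 5*u + 0, u_nominal = 10
#>   l1 = 5, l2 = 1 (k2 = 1, k12 = 0)
#>   alpha_fb = 1 (ramp), alpha_ff = 0
#>   x_bar = 10, y_bar = 50

## exact stationary moments at x̄ = ȳ = 50, gain 1 ...
flat <- make_circuit("fb", "coupled", input_spec(0, 50, 1), 1, 1, alpha_fb = 1)
fb_stationary_moments(flat)
#> <stationary_moments method=exact>
#>   mean: x = 50, y = 50
#>   var:  x = 25, y = 41.6667, cov = 8.33333

## ... confirmed by the finite-state-projection oracle
fsp_stationary_moments(build_network(flat))$moments
#> <stationary_moments method=fsp>
#>   mean: x = 50, y = 50
#>   var:  x = 25, y = 41.6667, cov = 8.33333
```

`var(y) = 41.67 = ȳ/(1+α) + P_proxy = 25 + 16.67`: regulation removed half
of the intrinsic variance in principle, but paid a 16.7-count proxy
penalty for sensing *Y* through *X*. Optimizing the gain:

```r
unlist(optimal_gain_fb(1e-6, "coupled"))   # vanishing proxy abundance
#>          alpha_opt            var_opt reduction_fraction
#>          1.0000005          0.7500001          0.2499999
unlist(optimal_gain_iff(50, 50))           # feedforward at x̄ = ȳ = 50
#>          alpha_opt  alpha_opt_numeric            var_opt reduction_fraction
#>          0.9900990          0.9901651         43.5717674          0.1285647
```

The best possible feedback reduction is 25% of the uncontrolled variance;
the matched feedforward circuit manages 12.9% at its own optimal gain.

Figure-style experiments (tables, not plots) run from one call or from the
thin CLI wrapper in `inst/scripts/proxyreg-run.R`:

```r
run_experiment("fig2_compare", out_dir = "out", seed = 1)
```

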