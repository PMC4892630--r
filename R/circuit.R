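#' Affine input specification
#'
#' The production rate of both species is driven by an input signal `u`
#' through a positive, monotone increasing function `f`.  All closed-form
#' results in the package use the affine form `f(u) = a*u + b`; an arbitrary
#' monotone function can be supplied through `fn`, in which case only the
#' numerical code paths (ODE integration, numeric steady states) are
#' available.
#'
#' @param a Production rate gained per unit of input (>= 0).
#' @param b Basal production rate (>= 0).
#' @param u_nominal Nominal input level \eqn{\bar u} (> 0 unless `b > 0`).
#' @param fn Optional function of `u` overriding the affine form.
#' @return An object of class `input_spec`.
#' @examples
#' input_spec(a = 5, b = 0, u_nominal = 10)
#' @export
input_spec <- function(a, b = 0, u_nominal, fn = NULL) {
  if (is.null(fn)) {
    stopifnot(is.numeric(a), is.numeric(b), a >= 0, b >= 0)
    if (a * u_nominal + b <= 0)
      stop("f(u_nominal) must be positive")
  }
  structure(list(a = a, b = b, u_nominal = u_nominal, fn = fn),
            class = "input_spec")
}

#' Evaluate the input function f(u)
#' @param input An [input_spec()].
#' @param u Input value(s), >= 0.
#' @return `f(u)`.
#' @export
f_value <- function(input, u) {
  if (!is.null(input$fn)) return(input$fn(u))
  input$a * u + input$b
}

f_slope <- function(input, u) {
  if (!is.null(input$fn)) {
    h <- 1e-6 * max(1, abs(u))
    return((input$fn(u + h) - input$fn(u - h)) / (2 * h))
  }
  rep(input$a, length(u))
}

#' Inhibition function specification
#'
#' Two parametric families of nonnegative monotone decreasing inhibition
#' functions, both normalized so that `g(x_anchor) = 1`:
#' * `"ramp"`: `g(x) = max(1 + alpha - alpha * x / x_anchor, 0)`, linear down
#'   to zero at `x0 = (1 + alpha)/alpha * x_anchor` and identically zero
#'   beyond.  The slope at the anchor defines the effective gain `alpha`.
#' * `"hill"`: `g(x) = (1 + c) / (1 + c * (x / x_anchor)^n)`.  The Hill
#'   exponent is calibrated from the requested gain as `n = alpha*(1 + c)/c`
#'   (at fixed `c`, default 10) so that the slope at the anchor matches the
#'   ramp of the same gain.
#' * `"none"`: `g(x) = 1` identically (no feedback).
#'
#' @param kind One of `"none"`, `"ramp"`, `"hill"`.
#' @param alpha Effective gain (dimensionless, >= 0).
#' @param c Hill strength (> 0), default 10.
#' @param n Hill exponent; computed from `alpha` when `NULL`.
#' @param x_anchor Count at which `g` equals 1 (the nominal mean of the
#'   inhibiting species).
#' @return An object of class `inhibition_spec`.
#' @export
inhibition_spec <- function(kind = c("ramp", "hill", "none"), alpha = 0,
                            c = 10, n = NULL, x_anchor) {
  kind <- match.arg(kind)
  stopifnot(alpha >= 0, c > 0, x_anchor > 0)
  if (kind == "none") alpha <- 0
  if (kind == "hill" && is.null(n)) n <- alpha * (1 + c) / c
  structure(list(kind = kind, alpha = alpha, c = c, n = n,
                 x_anchor = x_anchor),
            class = "inhibition_spec")
}

#' Evaluate an inhibition function
#' @param g An [inhibition_spec()].
#' @param x Count(s) at which to evaluate, >= 0.
#' @return `g(x)` (dimensionless, >= 0).
#' @export
inhibition_value <- function(g, x) {
  switch(g$kind,
    none = rep(1, length(x)),
    ramp = pmax(1 + g$alpha - g$alpha * x / g$x_anchor, 0),
    hill = (1 + g$c) / (1 + g$c * (x / g$x_anchor)^g$n))
}

#' Slope of an inhibition function
#' @inheritParams inhibition_value
#' @return `dg/dx` evaluated at `x`.
#' @export
inhibition_slope <- function(g, x) {
  switch(g$kind,
    none = rep(0, length(x)),
    ramp = ifelse(x < (1 + g$alpha) / max(g$alpha, 1e-300) * g$x_anchor,
                  -g$alpha / g$x_anchor, 0),
    hill = {
      s <- x / g$x_anchor
      -(1 + g$c) * g$c * g$n * s^(g$n - 1) / g$x_anchor /
        (1 + g$c * s^g$n)^2
    })
}

#' Construct a normalized proxy-regulation circuit
#'
#' Builds one of the four circuit variants in which a proxy species X carries
#' information about a species of interest Y: negative feedback (`"fb"`,
#' X inhibits production of both), incoherent feedforward (`"iff"`, X
#' mediates degradation of Y), their combination (`"combined"`), or direct
#' autoinhibition of Y with no proxy (`"direct_fb"`).  The production of X
#' and Y is either `"coupled"` (one reaction produces both) or `"decoupled"`
#' (two reactions with identical rate laws).
#'
#' All variants are normalized to share the same nominal steady state and
#' production propensity: `k1 = l1`, `k2 + k12*x_bar = l2` and
#' `g(x_bar) = 1`, where `x_bar = f(u_nominal)/l1` and
#' `y_bar = f(u_nominal)/l2`.  Under this normalization the feedforward
#' split is `k2 = l2/(1 + alpha_ff)` and `k12*x_bar = l2*alpha_ff/(1 +
#' alpha_ff)`; infinite feedforward gain is represented exactly as `k2 = 0`.
#'
#' @param motif One of `"fb"`, `"iff"`, `"combined"`, `"direct_fb"`.
#' @param coupling `"coupled"` or `"decoupled"` production.
#' @param input An [input_spec()].
#' @param l1,l2 Degradation rates of X and Y (per unit time, > 0).
#' @param alpha_fb Effective feedback gain (>= 0; must be 0 for `"iff"`).
#' @param alpha_ff Effective feedforward gain (>= 0 or `Inf`; must be 0 for
#'   `"fb"` and `"direct_fb"`).
#' @param g_kind Inhibition family for the feedback part (`"ramp"` or
#'   `"hill"`).
#' @param g_c Hill strength when `g_kind = "hill"`.
#' @return An object of class `circuit_spec` carrying the derived rates
#'   `k1`, `k2`, `k12`, the inhibition spec anchored at `x_bar`, and the
#'   nominal means `x_bar`, `y_bar`.
#' @examples
#' circ <- make_circuit("fb", "coupled", input_spec(5, 0, 10),
#'                      l1 = 5, l2 = 1, alpha_fb = 1)
#' steady_state(circ)
#' @export
make_circuit <- function(motif = c("fb", "iff", "combined", "direct_fb"),
                         coupling = c("coupled", "decoupled"),
                         input, l1, l2, alpha_fb = 0, alpha_ff = 0,
                         g_kind = c("ramp", "hill"), g_c = 10) {
  motif <- match.arg(motif)
  coupling <- match.arg(coupling)
  g_kind <- match.arg(g_kind)
  stopifnot(inherits(input, "input_spec"), l1 > 0, l2 > 0,
            alpha_fb >= 0, alpha_ff >= 0)
  if (motif %in% c("fb", "direct_fb") && alpha_ff != 0)
    stop("alpha_ff must be 0 for a pure feedback motif")
  if (motif == "iff" && alpha_fb != 0)
    stop("alpha_fb must be 0 for the feedforward motif")
  if (is.infinite(alpha_fb))
    stop("infinite feedback gain is not representable; use a large finite gain")

  fbar <- f_value(input, input$u_nominal)
  x_bar <- fbar / l1
  y_bar <- fbar / l2
  if (is.infinite(alpha_ff)) {         # tagged limit: pure mediated degradation
    k2 <- 0
    k12 <- l2 / x_bar
  } else {
    k2 <- l2 / (1 + alpha_ff)
    k12 <- l2 * alpha_ff / (1 + alpha_ff) / x_bar
  }
  anchor <- if (motif == "direct_fb") y_bar else x_bar
  g_k <- if (alpha_fb == 0) "none" else g_kind
  g <- inhibition_spec(g_k, alpha = alpha_fb, c = g_c, x_anchor = anchor)

  structure(list(motif = motif, coupling = coupling, input = input,
                 l1 = l1, l2 = l2,
                 alpha_fb = alpha_fb, alpha_ff = alpha_ff,
                 k1 = l1, k2 = k2, k12 = k12,
                 g = g, x_bar = x_bar, y_bar = y_bar),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> motif=%s coupling=%s\n", x$motif, x$coupling))
  cat(sprintf("  f(u) = %s, u_nominal = %g\n",
              if (is.null(x$input$fn)) sprintf("%g*u + %g", x$input$a, x$input$b)
              else "<function>", x$input$u_nominal))
  cat(sprintf("  l1 = %g, l2 = %g (k2 = %g, k12 = %g)\n",
              x$l1, x$l2, x$k2, x$k12))
  cat(sprintf("  alpha_fb = %g (%s), alpha_ff = %g\n",
              x$alpha_fb, x$g$kind, x$alpha_ff))
  cat(sprintf("  x_bar = %g, y_bar = %g\n", x$x_bar, x$y_bar))
  invisible(x)
}

#' Effective gain of a circuit
#'
#' The strength of regulation at the nominal operating point: the feedback
#' gain is the normalized slope of the inhibition function,
#' `alpha_fb = -x_bar * g'(x_bar)`; the feedforward gain is the ratio of
#' mediated to unmediated degradation of Y, `alpha_ff = x_bar*k12/k2`; and
#' the combined circuit has gain
#' `alpha_fb + alpha_ff + alpha_fb*alpha_ff`.
#'
#' @param circuit A [make_circuit()] object.
#' @return The effective gain (dimensionless; `Inf` for the `k2 = 0`
#'   feedforward limit).
#' @export
effective_gain <- function(circuit) {
  a_fb <- if (circuit$motif %in% c("fb", "combined", "direct_fb")) {
    anchor <- circuit$g$x_anchor
    -anchor * inhibition_slope(circuit$g, anchor)
  } else 0
  a_ff <- if (circuit$motif %in% c("iff", "combined")) {
    if (circuit$k2 == 0) Inf else circuit$x_bar * circuit$k12 / circuit$k2
  } else 0
  switch(circuit$motif,
    fb = , direct_fb = a_fb,
    iff = a_ff,
    combined = a_fb + a_ff + a_fb * a_ff)
}

#' Deterministic nominal steady state
#'
#' Under the normalization conditions the macroscopic fixed point at the
#' nominal input is `x_bar = f(u_nominal)/l1`, `y_bar = f(u_nominal)/l2`
#' for every motif and coupling.
#'
#' @param circuit A [make_circuit()] object.
#' @return A list with elements `x_bar` and `y_bar` (mean counts).
#' @export
steady_state <- function(circuit) {
  list(x_bar = circuit$x_bar, y_bar = circuit$y_bar)
}

circuit_rhs <- function(circuit) {
  force(circuit)
  function(t, state, parms, u_fun) {
    u <- u_fun(t)
    f <- f_value(circuit$input, u)
    if (circuit$motif == "direct_fb") {
      y <- state[1]
      dy <- f * inhibition_value(circuit$g, y) - circuit$l2 * y
      return(list(dy))
    }
    x <- state[1]; y <- state[2]
    prod <- f * inhibition_value(circuit$g, x)
    dx <- prod - circuit$l1 * x
    dy <- prod - circuit$k2 * y - circuit$k12 * x * y
    list(c(dx, dy))
  }
}

#' Integrate the deterministic circuit ODE
#'
#' Integrates the macroscopic rate equations with the input either constant
#' or a piecewise-constant trajectory (e.g. from
#' [simulate_birth_death_u()]).  The ramp inhibition makes the right-hand
#' side continuous but only piecewise smooth; `lsoda` handles the kink, and
#' the maximum step is capped so the corner at `x0` is not stepped over.
#'
#' @param circuit A [make_circuit()] object.
#' @param u Either a single number (constant input) or an object of class
#'   `input_trajectory`.
#' @param t_grid Increasing vector of output times.
#' @param init_state Initial `(x, y)` (or `y` for `"direct_fb"`); defaults
#'   to the nominal steady state.
#' @return A data.frame with columns `t`, `u`, `x`, `y`.
#' @export
integrate_ode <- function(circuit, u, t_grid, init_state = NULL) {
  stopifnot(all(diff(t_grid) > 0))
  if (inherits(u, "input_trajectory")) {
    u_fun <- stats::approxfun(u$t, u$u, method = "constant", rule = 2)
  } else if (is.numeric(u) && length(u) == 1) {
    u_fun <- function(t) u
  } else stop("u must be a number or an input_trajectory")
  if (is.null(init_state)) {
    ss <- steady_state(circuit)
    init_state <- if (circuit$motif == "direct_fb") ss$y_bar
                  else c(ss$x_bar, ss$y_bar)
  }
  if (any(init_state < 0)) stop("init_state must be nonnegative")
  # step cap: fine enough to resolve the ramp corner for constant input,
  # and the mean inter-event gap for piecewise-constant trajectories
  hmax <- if (inherits(u, "input_trajectory")) {
    max(min(0.05, diff(range(u$t)) / max(length(u$t) - 1, 1)), 1e-3)
  } else {
    0.1 / max(circuit$l1 * (1 + circuit$alpha_fb), circuit$l2)
  }
  out <- deSolve::lsoda(y = init_state, times = t_grid,
                        func = circuit_rhs(circuit), parms = NULL,
                        u_fun = u_fun, hmax = hmax,
                        rtol = 1e-9, atol = 1e-9)
  if (any(!is.finite(out)))
    stop("ODE integration produced non-finite states; check parameters")
  if (circuit$motif == "direct_fb") {
    data.frame(t = out[, 1], u = u_fun(out[, 1]), x = NA_real_, y = out[, 2])
  } else {
    data.frame(t = out[, 1], u = u_fun(out[, 1]), x = out[, 2], y = out[, 3])
  }
}

#' Steady-state output as a function of a static input
#'
#' Closed-form steady state of Y under ramp inhibition (identical for the
#' feedback and feedforward motifs at equal effective gain):
#' `y_ss(u) = y_bar*(1+alpha)*f(u) / (f(u_nominal)*(1 + alpha*f(u)/f(u_nominal)))`.
#' For Hill inhibition the fixed point is computed numerically.
#'
#' @param circuit A [make_circuit()] object.
#' @param u Input value(s), >= 0.
#' @return Steady-state count(s) of Y.
#' @export
yss_static <- function(circuit, u) {
  alpha <- effective_gain(circuit)
  fbar <- f_value(circuit$input, circuit$input$u_nominal)
  fu <- f_value(circuit$input, u)
  if (circuit$motif %in% c("fb", "combined", "direct_fb") &&
      circuit$g$kind == "hill") {
    return(vapply(u, function(ui) yss_numeric(circuit, ui), numeric(1)))
  }
  if (is.infinite(alpha)) return(rep(circuit$y_bar, length(u)))
  circuit$y_bar * (1 + alpha) * fu / (fbar * (1 + alpha * fu / fbar))
}

# numeric fixed point at fixed input u (used for hill inhibition)
yss_numeric <- function(circuit, u) {
  f <- f_value(circuit$input, u)
  if (circuit$motif == "direct_fb") {
    h <- function(y) f * inhibition_value(circuit$g, y) - circuit$l2 * y
    up <- max(2 * f / circuit$l2, 2 * circuit$y_bar)
    return(stats::uniroot(h, c(0, up), tol = 1e-12)$root)
  }
  hx <- function(x) f * inhibition_value(circuit$g, x) - circuit$l1 * x
  up <- max(2 * f / circuit$l1, 2 * circuit$x_bar,
            if (circuit$g$kind == "ramp" && circuit$alpha_fb > 0)
              (1 + circuit$alpha_fb) / circuit$alpha_fb * circuit$x_bar else 0)
  xs <- stats::uniroot(hx, c(0, up * (1 + 1e-9)), tol = 1e-12)$root
  prod <- f * inhibition_value(circuit$g, xs)
  prod / (circuit$k2 + circuit$k12 * xs)
}

#' Local sensitivity of the steady state to the input
#'
#' Returns `d y_ss / d u` at the nominal input, which for all motifs equals
#' `y_bar * f'(u_nominal) / (f(u_nominal) * (1 + alpha))` with `alpha` the
#' motif's effective gain (combined gain for the combined circuit).  Higher
#' gain means better adaptation of the output to static input differences.
#'
#' @param circuit A [make_circuit()] object.
#' @return Sensitivity (counts per input-unit).
#' @export
sensitivity_yss <- function(circuit) {
  alpha <- effective_gain(circuit)
  if (is.infinite(alpha)) return(0)
  ubar <- circuit$input$u_nominal
  circuit$y_bar * f_slope(circuit$input, ubar) /
    (f_value(circuit$input, ubar) * (1 + alpha))
}

#' Steady-state output distribution under static input variability
#'
#' Maps a sample of static input values (one per cell) through the
#' steady-state curve and summarizes the resulting distribution of Y.
#' Emulates cell-to-cell variability, e.g. plasmid copy-number differences,
#' where each cell holds a constant input drawn once.
#'
#' @param circuit A [make_circuit()] object.
#' @param u_samples Nonnegative input samples (e.g. from
#'   [sample_static_poisson_u()]).
#' @return A list with `samples` (data.frame `u`, `y_ss`) and `summary`
#'   (mean, variance, cv of `y_ss`).
#' @export
static_response_distribution <- function(circuit, u_samples) {
  if (length(u_samples) == 0) stop("u_samples must be non-empty")
  stopifnot(all(u_samples >= 0))
  y <- yss_static(circuit, u_samples)
  m <- mean(y); v <- stats::var(y)
  if (length(y) == 1) v <- 0
  list(samples = data.frame(u = u_samples, y_ss = y),
       summary = list(mean = m, variance = v,
                      cv = if (m > 0) sqrt(v) / m else NA_real_))
}

#' Serialize a circuit to a config list / YAML
#'
#' @param circuit A [make_circuit()] object.
#' @param path Optional file path; when given, YAML is written there.
#' @return The config list, invisibly when written to file.
#' @export
circuit_to_config <- function(circuit, path = NULL) {
  cfg <- list(motif = circuit$motif, coupling = circuit$coupling,
              f = list(a = circuit$input$a, b = circuit$input$b),
              u_nominal = circuit$input$u_nominal,
              l1 = circuit$l1, l2 = circuit$l2,
              alpha_fb = circuit$alpha_fb,
              alpha_ff = if (is.infinite(circuit$alpha_ff)) "inf"
                         else circuit$alpha_ff,
              g = list(kind = circuit$g$kind, c = circuit$g$c))
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
    return(invisible(cfg))
  }
  cfg
}

#' Build a circuit from a config list / YAML file
#' @param cfg A config list as produced by [circuit_to_config()], or a path
#'   to a YAML file holding one.
#' @return A `circuit_spec`.
#' @export
circuit_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  a_ff <- if (identical(cfg$alpha_ff, "inf")) Inf else cfg$alpha_ff %||% 0
  g_kind <- if (identical(cfg$g$kind, "hill")) "hill" else "ramp"
  make_circuit(motif = cfg$motif, coupling = cfg$coupling,
               input = input_spec(cfg$f$a, cfg$f$b %||% 0, cfg$u_nominal),
               l1 = cfg$l1, l2 = cfg$l2,
               alpha_fb = cfg$alpha_fb %||% 0, alpha_ff = a_ff,
               g_kind = g_kind, g_c = cfg$g$c %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
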