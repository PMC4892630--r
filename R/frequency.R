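#' Linearize a circuit about its nominal steady state
#'
#' Builds the transfer model `dz = A z dt + B dw`, `output = C z`, where
#' `z = (x - x_bar, y - y_bar)`.  The drift Jacobian is
#' `A = [[-l1(1+alpha_fb), 0], [-l1*alpha_fb - k12*y_bar, -l2]]`, which
#' specializes to the pure feedback (`k12 = 0`) and pure feedforward
#' (`alpha_fb = 0`) motifs.  Two noise channels are supported:
#' * `"additive"`: white noise of intensity `sigma` added to both equations
#'   through the same scalar Wiener process, `B = sigma*[1, 1]`;
#' * `"input_derivative"`: input fluctuations entering through the
#'   production rate, `B = f'(u_nominal)*[1, 1]`.
#'
#' @param circuit A [make_circuit()] object (not `"direct_fb"`).
#' @param noise_mode `"additive"` or `"input_derivative"`.
#' @param sigma Noise intensity for the additive mode (rate units).
#' @return An object of class `transfer_model` with fields `A`, `B`, `C`,
#'   `sigma`.
#' @export
linearize <- function(circuit, noise_mode = c("additive", "input_derivative"),
                      sigma = 50) {
  noise_mode <- match.arg(noise_mode)
  if (circuit$motif == "direct_fb")
    stop("linearize() expects a two-species circuit")
  a_fb <- circuit$alpha_fb
  A <- matrix(c(-circuit$l1 * (1 + a_fb), 0,
                -circuit$l1 * a_fb - circuit$k12 * circuit$y_bar,
                -circuit$l2),
              2, 2, byrow = TRUE)
  if (any(Re(eigen(A, only.values = TRUE)$values) >= 0))
    stop("internal error: drift matrix is not Hurwitz")
  B <- if (noise_mode == "additive") sigma * c(1, 1)
       else f_slope(circuit$input, circuit$input$u_nominal) * c(1, 1)
  structure(list(A = A, B = matrix(B, 2, 1), C = matrix(c(0, 1), 1, 2),
                 sigma = sigma, noise_mode = noise_mode, circuit = circuit),
            class = "transfer_model")
}

# Solve A P + P A' + Q = 0 for P (A Hurwitz, Q symmetric), via vec/kron.
lyapunov_solve <- function(A, Q) {
  n <- nrow(A)
  M <- kronecker(diag(n), A) + kronecker(A, diag(n))
  if (rcond(M) < 1e-14)
    stop("Lyapunov solve is ill-conditioned; check circuit parameters")
  P <- matrix(solve(M, -as.vector(Q)), n, n)
  (P + t(P)) / 2
}

#' Squared H2 norm of a transfer model
#'
#' Solves the stationary covariance (Lyapunov) equation
#' `A P + P A' + B B' = 0` and returns `C P C'`, which equals the
#' stationary variance of the output when the input is driven by a standard
#' Wiener process.  High-gain feedback drives this to zero, while any
#' feedforward implementation is bounded below by
#' `sigma^2 / (2*(l1 + l2))`.
#'
#' @param model A [linearize()] result.
#' @return Stationary output variance (counts squared).
#' @export
h2_norm_squared <- function(model) {
  P <- lyapunov_solve(model$A, model$B %*% t(model$B))
  drop(model$C %*% P %*% t(model$C))
}

#' Ensemble SDE simulation of a circuit under additive white noise
#'
#' Euler-Maruyama integration of the nonlinear rate equations with
#' `sigma*[1,1]' dw` added to the right-hand side (the same scalar Wiener
#' increment perturbs both equations, matching the single-channel noise of
#' the linearized model).  States are reflected at zero by clipping.
#'
#' @param circuit A [make_circuit()] object.
#' @param sigma Noise intensity (rate units).
#' @param t_final Final time; the ensemble variance of `y(t_final)` is
#'   returned.
#' @param dt Time step; default `min(1e-3, 0.1/(l1*(1+alpha_fb)))`.
#'   An error is raised if `dt` exceeds the explicit-scheme stability bound.
#' @param n_runs Ensemble size (>= 100).
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for the CI of the variance.
#' @return A list with `var_y`, `ci` (95% bootstrap interval), `mean_y`,
#'   `n_runs`, `dt`.
#' @export
simulate_sde_ensemble <- function(circuit, sigma, t_final = 20,
                                  dt = NULL, n_runs = 1000, seed = 1L,
                                  n_boot = 400) {
  stopifnot(n_runs >= 100)
  rate_max <- max(circuit$l1 * (1 + circuit$alpha_fb), circuit$l2,
                  circuit$k2 + circuit$k12 * circuit$x_bar * 4)
  if (is.null(dt)) dt <- min(1e-3, 0.1 / rate_max)
  if (dt > 2 / rate_max)
    stop("dt violates the stability bound for the fastest rate")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ss <- steady_state(circuit)
  x <- rep(ss$x_bar, n_runs); y <- rep(ss$y_bar, n_runs)
  n_steps <- ceiling(t_final / dt)
  sq <- sqrt(dt)
  for (i in seq_len(n_steps)) {
    f <- f_value(circuit$input, circuit$input$u_nominal)
    prod <- f * inhibition_value(circuit$g, x)
    dw <- stats::rnorm(n_runs, 0, sq)
    x <- pmax(x + (prod - circuit$l1 * x) * dt + sigma * dw, 0)
    y <- pmax(y + (prod - circuit$k2 * y - circuit$k12 * x * y) * dt +
                sigma * dw, 0)
  }
  v <- stats::var(y)
  boot <- replicate(n_boot, stats::var(sample(y, replace = TRUE)))
  list(var_y = v, ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       mean_y = mean(y), n_runs = n_runs, dt = dt)
}

#' Coefficient of variation of the output under a dynamic input
#'
#' Integrates the deterministic circuit driven by a piecewise-constant input
#' trajectory, discards the initial transient (first 10% of the grid), and
#' returns `sd(y)/mean(y)` over the retained portion.
#'
#' @param circuit A [make_circuit()] object.
#' @param u_traj An `input_trajectory` from [simulate_birth_death_u()].
#' @param t_grid Output time grid; defaults to 2000 points over the
#'   trajectory's span.
#' @param transient_frac Fraction of the grid discarded as transient.
#' @return A list with `cv`, `mean_y`, `sd_y` and the retained trajectory.
#' @export
cv_dynamic_response <- function(circuit, u_traj, t_grid = NULL,
                                transient_frac = 0.1) {
  if (is.null(t_grid))
    t_grid <- seq(0, u_traj$t_final, length.out = 2000)
  tr <- integrate_ode(circuit, u_traj, t_grid)
  keep <- tr$t >= transient_frac * max(tr$t)
  y <- tr$y[keep]
  m <- mean(y)
  if (m < 1e-12) stop("mean output is ~0; cv undefined")
  list(cv = stats::sd(y) / m, mean_y = m, sd_y = stats::sd(y),
       trajectory = tr[keep, ])
}
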