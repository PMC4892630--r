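#' Stationary moments container
#'
#' @param mean_x,mean_y Stationary means (counts; `mean_x` may be `NA` for
#'   one-species schemes).
#' @param var_x,var_y Stationary variances (counts squared).
#' @param cov_xy Stationary covariance.
#' @param method One of `"exact"`, `"closure"`, `"lna"`, `"fsp"`, `"ssa"`.
#' @param extra Optional named list appended to the object.
#' @return An object of class `stationary_moments`.
#' @export
stationary_moments <- function(mean_x = NA_real_, mean_y, var_x = NA_real_,
                               var_y, cov_xy = NA_real_,
                               method = c("exact", "closure", "lna",
                                          "fsp", "ssa"),
                               extra = list()) {
  method <- match.arg(method)
  if (!is.na(var_y) && var_y < -1e-9) stop("negative variance")
  obj <- c(list(mean_x = mean_x, mean_y = mean_y, var_x = var_x,
                var_y = var_y, cov_xy = cov_xy, method = method), extra)
  structure(obj, class = "stationary_moments")
}

#' @export
print.stationary_moments <- function(x, ...) {
  cat(sprintf("<stationary_moments method=%s>\n", x$method))
  cat(sprintf("  mean: x = %.6g, y = %.6g\n", x$mean_x, x$mean_y))
  cat(sprintf("  var:  x = %.6g, y = %.6g, cov = %.6g\n",
              x$var_x, x$var_y, x$cov_xy))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Exact moment equations for reaction networks with affine propensities.
#
# For jump processes whose propensities are affine in the state, the first-
# and second-order moment equations close exactly.  `reactions` is a list of
# lists with fields `s` (stoichiometry, length n) and `p` (length n + 1:
# constant term followed by linear coefficients).  Returns raw moments.
affine_moment_solve <- function(reactions, n_species) {
  n <- n_species
  pairs <- list()
  for (i in seq_len(n)) for (j in i:n) pairs[[length(pairs) + 1]] <- c(i, j)
  n_unk <- n + length(pairs)
  idx_mean <- seq_len(n)
  idx_pair <- function(i, j) {
    ij <- sort(c(i, j))
    for (k in seq_along(pairs))
      if (all(pairs[[k]] == ij)) return(n + k)
    stop("bad pair")
  }
  M <- matrix(0, n_unk, n_unk)
  cvec <- numeric(n_unk)

  # accumulate coefficients of E[w] and E[z_i w] as linear forms in the
  # unknown raw moments: (const, coef over unknowns)
  lf_w <- function(p) {
    v <- numeric(n_unk); v[idx_mean] <- p[-1]
    list(const = p[1], coef = v)
  }
  lf_zw <- function(i, p) {
    v <- numeric(n_unk)
    v[i] <- p[1]
    for (j in seq_len(n)) v[idx_pair(i, j)] <- v[idx_pair(i, j)] + p[j + 1]
    list(const = 0, coef = v)
  }
  add <- function(row, lf, mult) {
    M[row, ] <<- M[row, ] + mult * lf$coef
    cvec[row] <<- cvec[row] + mult * lf$const
  }
  for (r in reactions) {
    s <- r$s; p <- r$p
    w <- lf_w(p)
    zw <- lapply(seq_len(n), lf_zw, p = p)
    for (i in seq_len(n)) if (s[i] != 0) add(i, w, s[i])
    for (k in seq_along(pairs)) {
      i <- pairs[[k]][1]; j <- pairs[[k]][2]
      row <- n + k
      if (s[i] != 0) add(row, zw[[j]], s[i])
      if (s[j] != 0) add(row, zw[[i]], s[j])
      if (s[i] * s[j] != 0) add(row, w, s[i] * s[j])
    }
  }
  sol <- solve(M, -cvec)
  list(means = sol[idx_mean],
       second = sol[-idx_mean], pairs = pairs)
}

# round the ramp cutoff x0 to the integer lattice and return the effective
# gain actually realized (the exact stationary solution assumes integer x0)
ramp_integer_gain <- function(alpha, anchor) {
  if (alpha == 0)
    return(list(alpha_eff = 0, x0 = Inf))
  x0 <- (1 + alpha) / alpha * anchor
  x0i <- max(round(x0), floor(anchor) + 1)
  list(alpha_eff = anchor / (x0i - anchor), x0 = x0i)
}

#' Exact stationary law of direct (proxy-free) negative autoregulation
#'
#' The one-species scheme in which Y inhibits its own production through a
#' ramp: production propensity `f_nominal * g_R(y)`, degradation `l2*y`.
#' Its stationary law is binomial with mean `y_bar = f_nominal/l2` and
#' variance `y_bar/(1 + alpha)`: direct feedback can suppress intrinsic
#' noise arbitrarily well as the gain grows.
#'
#' The exact solution requires the ramp cutoff `y0 = (1+alpha)/alpha*y_bar`
#' to be an integer; the cutoff is rounded and the realized (effective) gain
#' reported alongside the requested one.
#'
#' @param f_nominal Production rate at the nominal input (per unit time).
#' @param l2 Degradation rate of Y (per unit time).
#' @param alpha Requested feedback gain (>= 0).
#' @return A `stationary_moments` (method `"exact"`) with extra fields
#'   `alpha_requested`, `alpha_eff`, `y0`.
#' @export
direct_fb_stationary <- function(f_nominal, l2, alpha) {
  stopifnot(f_nominal > 0, l2 > 0, alpha >= 0)
  y_bar <- f_nominal / l2
  g <- ramp_integer_gain(alpha, y_bar)
  stationary_moments(mean_y = y_bar, var_y = y_bar / (1 + g$alpha_eff),
                     method = "exact",
                     extra = list(alpha_requested = alpha,
                                  alpha_eff = g$alpha_eff, y0 = g$x0))
}

#' Closed-form stationary variance of the ramp feedback circuit
#'
#' The exact stationary variance of Y for the proxy feedback circuit with
#' ramp inhibition, per unit of `y_bar`:
#' `var(y)/y_bar = 1/(1+alpha) + P_proxy/y_bar` for coupled production,
#' plus `P_decouple/y_bar` for decoupled production, where with
#' `r = x_bar/y_bar`:
#' `P_proxy  = y_bar * alpha*(alpha + r) / ((1+alpha)*(1+alpha+r))`
#' `P_decouple = y_bar * alpha / (1+alpha+r)`.
#' The proxy penalty is the price of sensing Y through the noisy
#' intermediary X; the decoupling penalty is the price of producing X and Y
#' in separate (uncorrelated) reactions.
#'
#' @param alpha Feedback gain(s) (>= 0).
#' @param r Mean-abundance ratio `x_bar/y_bar` (> 0).
#' @param y_bar Nominal mean of Y.
#' @param coupling `"coupled"` or `"decoupled"`.
#' @return Stationary variance of Y (vectorized over `alpha`).
#' @export
fb_variance_ramp <- function(alpha, r, y_bar = 1,
                             coupling = c("coupled", "decoupled")) {
  coupling <- match.arg(coupling)
  v <- y_bar / (1 + alpha) +
    y_bar * alpha * (alpha + r) / ((1 + alpha) * (1 + alpha + r))
  if (coupling == "decoupled") v <- v + y_bar * alpha / (1 + alpha + r)
  v
}

#' Exact stationary moments of the proxy feedback circuit
#'
#' Solves the closed linear moment equations of the ramp-inhibition
#' feedback scheme (exact for affine propensities on the reachable lattice)
#' and returns the stationary moments together with the proxy and
#' decoupling penalty terms.  The solution is cross-checked internally
#' against the closed forms of [fb_variance_ramp()].
#'
#' @param circuit A `"fb"` circuit with ramp (or no) inhibition.
#' @return A `stationary_moments` (method `"exact"`) with extra fields
#'   `p_proxy`, `p_decouple`, `alpha_requested`, `alpha_eff`, `x0`.
#' @export
fb_stationary_moments <- function(circuit) {
  if (circuit$motif != "fb")
    stop("fb_stationary_moments() expects motif 'fb'")
  if (!circuit$g$kind %in% c("ramp", "none"))
    stop("exact moments require ramp inhibition (use FSP for hill)")
  f <- f_value(circuit$input, circuit$input$u_nominal)
  x_bar <- circuit$x_bar; y_bar <- circuit$y_bar
  g <- ramp_integer_gain(circuit$alpha_fb, x_bar)
  a <- g$alpha_eff
  l1 <- circuit$l1; l2 <- circuit$l2

  prod_p <- c(f * (1 + a), -f * a / x_bar, 0)  # affine in (x, y)
  degx <- list(s = c(-1, 0), p = c(0, l1, 0))
  degy <- list(s = c(0, -1), p = c(0, 0, l2))
  reactions <- if (circuit$coupling == "coupled") {
    list(list(s = c(1, 1), p = prod_p), degx, degy)
  } else {
    list(list(s = c(1, 0), p = prod_p),
         list(s = c(0, 1), p = prod_p), degx, degy)
  }
  sol <- affine_moment_solve(reactions, 2)
  mx <- sol$means[1]; my <- sol$means[2]
  vx <- sol$second[1] - mx^2
  cxy <- sol$second[2] - mx * my
  vy <- sol$second[3] - my^2

  r <- x_bar / y_bar
  p_proxy <- vy - y_bar / (1 + a)
  p_dec <- 0
  if (circuit$coupling == "decoupled") {
    p_proxy <- y_bar * a * (a + r) / ((1 + a) * (1 + a + r))
    p_dec <- vy - y_bar / (1 + a) - p_proxy
  }
  closed <- fb_variance_ramp(a, r, y_bar, circuit$coupling)
  if (abs(vy - closed) > 1e-6 * max(1, closed))
    warning(sprintf(
      "moment-equation variance %.10g deviates from closed form %.10g", vy,
      closed))
  stationary_moments(mean_x = mx, mean_y = my, var_x = vx, var_y = vy,
                     cov_xy = cxy, method = "exact",
                     extra = list(p_proxy = p_proxy, p_decouple = p_dec,
                                  alpha_requested = circuit$alpha_fb,
                                  alpha_eff = a, x0 = g$x0))
}

#' Variance-optimal feedback gain
#'
#' Minimizes the exact stationary variance of the coupled ramp feedback
#' circuit over the gain.  The interior optimum is `alpha* = sqrt(1 + r)`
#' with `r = x_bar/y_bar`; as `r -> 0` this gives `alpha* = 1` and the
#' best-case 25% variance reduction, at `r = 1` the reduction is
#' `2*sqrt(2) - 2 ~ 17.2%`, and as `r -> infinity` no gain helps.  For
#' decoupled production any feedback increases the variance, so the optimum
#' is `alpha* = 0`.
#'
#' @param r Mean-abundance ratio `x_bar/y_bar` (> 0).
#' @param coupling `"coupled"` or `"decoupled"`.
#' @param y_bar Nominal mean of Y (scales `var_opt`).
#' @return A list with `alpha_opt`, `var_opt`, `reduction_fraction`
#'   (fraction of the uncontrolled variance removed at the optimum).
#' @export
optimal_gain_fb <- function(r, coupling = c("coupled", "decoupled"),
                            y_bar = 1) {
  coupling <- match.arg(coupling)
  stopifnot(r > 0)
  if (coupling == "decoupled") {
    return(list(alpha_opt = 0, var_opt = y_bar, reduction_fraction = 0))
  }
  obj <- function(a) fb_variance_ramp(a, r, 1, "coupled")
  opt <- stats::optimize(obj, c(0, max(10, 4 * sqrt(1 + r))), tol = 1e-10)
  list(alpha_opt = opt$minimum, var_opt = y_bar * opt$objective,
       reduction_fraction = 1 - opt$objective)
}

#' Output variance under simultaneous input variability and reaction noise
#'
#' Treats the static input as random (Poisson with mean `u_mean`) and
#' decomposes the stationary variance of Y by the law of total variance:
#' `var(y) = E_u[var(y|u)] + var_u(E[y|u])`, i.e. a chemical-reaction
#' stochasticity term plus an input-variability term.  With affine input
#' `f(u) = a*u + b` and `C = a*u_mean`, three limiting feedback
#' realizations admit closed forms:
#' * `"no_fb"`:            `var(y) = (C+b)/l2 + C^2/(l2^2*u_mean)`
#' * `"coupled_strong"`:   `var(y) = (C+b)/l2 - 1`
#' * `"decoupled_strong"`: `var(y) = 2*(C+b)/l2 - 1`
#' Strong feedback cancels the input-variability term entirely; coupled
#' strong feedback is always preferable to no feedback, while decoupled
#' strong feedback pays a doubled reaction-noise term and wins only when
#' the input is noisy enough, i.e. `u_mean` below the threshold at which
#' the `"no_fb"` and `"decoupled_strong"` variances cross.
#'
#' For `realization = "finite"` the circuit's own gain is used: exact
#' conditional moments of the ramp scheme are computed at each input value
#' (the conditional steady state shifts with `u`) and mixed over the
#' Poisson law, truncated at mass `1 - 1e-10`.
#'
#' @param circuit A `"fb"` circuit with affine input.
#' @param u_mean Mean of the Poisson input law; defaults to the circuit's
#'   nominal input.
#' @param realization One of `"no_fb"`, `"coupled_strong"`,
#'   `"decoupled_strong"`, `"finite"`.
#' @return A list with `var_y`, `chem_component`, `input_component`,
#'   `u_threshold` (the crossing point described above) and `realization`.
#' @export
static_mixture_variance <- function(circuit, u_mean = NULL,
                                    realization = c("no_fb",
                                                    "coupled_strong",
                                                    "decoupled_strong",
                                                    "finite")) {
  realization <- match.arg(realization)
  if (!is.null(circuit$input$fn)) stop("affine input required")
  a <- circuit$input$a; b <- circuit$input$b; l2 <- circuit$l2
  if (is.null(u_mean)) u_mean <- circuit$input$u_nominal
  C <- a * u_mean
  if (C <= 0) stop("C = a*u_mean must be positive")
  thr <- if ((C + b) / l2 > 1) C^2 / (l2 * (C + b) - l2^2) else Inf

  if (realization == "no_fb") {
    chem <- (C + b) / l2; inp <- C^2 / (l2^2 * u_mean)
    return(list(var_y = chem + inp, chem_component = chem,
                input_component = inp, u_threshold = thr,
                realization = realization))
  }
  if (realization == "coupled_strong") {
    chem <- (C + b) / l2 - 1
    return(list(var_y = chem, chem_component = chem, input_component = 0,
                u_threshold = thr, realization = realization))
  }
  if (realization == "decoupled_strong") {
    chem <- 2 * (C + b) / l2 - 1
    return(list(var_y = chem, chem_component = chem, input_component = 0,
                u_threshold = thr, realization = realization))
  }
  # finite gain: mix exact conditional ramp moments over the Poisson input
  supp <- poisson_support(u_mean, 1e-10)
  wts <- stats::dpois(supp, u_mean); wts <- wts / sum(wts)
  cond <- vapply(supp, function(u) {
    cm <- fb_conditional_moments(circuit, u)
    c(cm$mean_y, cm$var_y)
  }, numeric(2))
  mu <- cond[1, ]; vy <- cond[2, ]
  chem <- sum(wts * vy)
  inp <- sum(wts * mu^2) - sum(wts * mu)^2
  list(var_y = chem + inp, chem_component = chem, input_component = inp,
       u_threshold = thr, realization = realization)
}

poisson_support <- function(mean, tail_mass) {
  lo <- stats::qpois(tail_mass / 2, mean)
  hi <- stats::qpois(1 - tail_mass / 2, mean)
  lo:hi
}

# exact conditional stationary moments of the ramp FB scheme at a fixed
# (off-nominal) input value; the inhibition stays anchored at the nominal
# x_bar, so the production propensity is still affine in x
fb_conditional_moments <- function(circuit, u) {
  f <- f_value(circuit$input, u)
  x_bar <- circuit$x_bar
  g <- ramp_integer_gain(circuit$alpha_fb, x_bar)
  a <- g$alpha_eff
  if (f <= 0) return(list(mean_y = 0, var_y = 0))
  prod_p <- c(f * (1 + a), -f * a / x_bar, 0)
  degx <- list(s = c(-1, 0), p = c(0, circuit$l1, 0))
  degy <- list(s = c(0, -1), p = c(0, 0, circuit$l2))
  reactions <- if (circuit$coupling == "coupled") {
    list(list(s = c(1, 1), p = prod_p), degx, degy)
  } else {
    list(list(s = c(1, 0), p = prod_p),
         list(s = c(0, 1), p = prod_p), degx, degy)
  }
  sol <- affine_moment_solve(reactions, 2)
  list(mean_y = sol$means[2], var_y = sol$second[3] - sol$means[2]^2)
}
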