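# ---------------------------------------------------------------------------
# Ground-truth oracles: reaction networks, finite state projection (FSP)
# stationary solutions, and exact-jump (SSA) simulation.

#' Build the reaction network of a circuit
#'
#' Expands a circuit into explicit reaction channels: coupled production is
#' one channel emitting both species, decoupled production is two channels
#' with identical rate laws, and the mediated degradation `k12*x*y` is its
#' own channel.  Ramp inhibition uses the integer-cutoff effective gain so
#' that the exact moment solutions and the oracles describe the same
#' process.
#'
#' @param circuit A [make_circuit()] object.
#' @return An object of class `reaction_network` with fields `species`,
#'   `channels` (label, stoichiometry, propensity function of `(x, y)` at
#'   the nominal input), `ssa` (the encoded propensity table for the
#'   compiled simulator), `x_support_max` (natural ramp bound on x, or
#'   `Inf`), and `circuit`.
#' @export
build_network <- function(circuit) {
  inp <- circuit$input
  fa <- inp$a %||% 0; fb_ <- inp$b %||% 0
  if (!is.null(inp$fn)) stop("SSA/FSP oracles require an affine input")
  f_fixed <- f_value(inp, inp$u_nominal)
  g <- circuit$g
  x_max <- Inf
  if (g$kind == "ramp" && g$alpha > 0) {
    gi <- ramp_integer_gain(g$alpha, g$x_anchor)
    g <- inhibition_spec("ramp", alpha = gi$alpha_eff, x_anchor = g$x_anchor)
    x_max <- gi$x0
  }
  gkind_code <- switch(g$kind, none = 0, ramp = 1, hill = 2)
  gp1 <- switch(g$kind, none = 0, ramp = g$alpha, hill = g$c)
  gp2 <- switch(g$kind, none = 0, ramp = 0, hill = g$n)
  gtarget <- if (circuit$motif == "direct_fb") 1 else 0
  g_of <- function(s) inhibition_value(g, s)

  ssa_row <- function(sx, sy, su, coef, use_f = 0, gk = 0, ex = 0, ey = 0,
                      eu = 0) {
    c(sx, sy, su, coef, use_f, fa, fb_, gk, gp1, gp2, g$x_anchor, gtarget,
      ex, ey, eu)
  }
  channels <- list(); rows <- list()
  add <- function(label, s, prop, row) {
    channels[[length(channels) + 1]] <<- list(label = label, s = s,
                                              prop = prop)
    rows[[length(rows) + 1]] <<- row
  }

  if (circuit$motif == "direct_fb") {
    add("production", c(0, 1),
        function(x, y) f_fixed * g_of(y),
        ssa_row(0, 1, 0, 1, use_f = 1, gk = gkind_code))
    add("degradation_y", c(0, -1),
        function(x, y) circuit$l2 * y,
        ssa_row(0, -1, 0, circuit$l2, ey = 1))
    species <- "y"
  } else {
    prod_prop <- function(x, y) f_fixed * g_of(x)
    if (circuit$coupling == "coupled") {
      add("production", c(1, 1), prod_prop,
          ssa_row(1, 1, 0, 1, use_f = 1, gk = gkind_code))
    } else {
      add("production_x", c(1, 0), prod_prop,
          ssa_row(1, 0, 0, 1, use_f = 1, gk = gkind_code))
      add("production_y", c(0, 1), prod_prop,
          ssa_row(0, 1, 0, 1, use_f = 1, gk = gkind_code))
    }
    add("degradation_x", c(-1, 0), function(x, y) circuit$k1 * x,
        ssa_row(-1, 0, 0, circuit$k1, ex = 1))
    if (circuit$k2 > 0)
      add("degradation_y", c(0, -1), function(x, y) circuit$k2 * y,
          ssa_row(0, -1, 0, circuit$k2, ey = 1))
    if (circuit$k12 > 0)
      add("degradation_y_mediated", c(0, -1),
          function(x, y) circuit$k12 * x * y,
          ssa_row(0, -1, 0, circuit$k12, ex = 1, ey = 1))
    species <- c("x", "y")
  }
  structure(list(species = species, channels = channels,
                 ssa = do.call(rbind, rows), x_support_max = x_max,
                 circuit = circuit),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species (%s), %d channels\n",
              length(x$species), paste(x$species, collapse = ", "),
              length(x$channels)))
  for (c_ in x$channels)
    cat(sprintf("  %-24s stoich (%s)\n", c_$label,
                paste(c_$s[seq_along(x$species) + (length(x$species) == 1)],
                      collapse = ", ")))
  invisible(x)
}

# stationary distribution of the truncated generator.  Out-of-bounds
# transition targets are projected onto the box (a reflecting truncation
# that cannot create absorbing boundary states, which plain propensity
# zeroing does for the pure mediated-degradation scheme); the projection
# error is certified small by the boundary-shell mass.
fsp_solve_box <- function(net, nx, ny) {
  two <- length(net$species) == 2
  if (two) {
    xs <- rep(0:nx, each = ny + 1)
    ys <- rep(0:ny, times = nx + 1)
  } else {
    xs <- rep(0, ny + 1); ys <- 0:ny
  }
  n <- length(ys)
  idx <- function(x, y) if (two) x * (ny + 1) + y + 1 else y + 1
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  outflow <- numeric(n)
  for (c_ in net$channels) {
    w <- c_$prop(xs, ys)
    tx <- pmin(pmax(xs + c_$s[1], 0), nx)
    ty <- pmin(pmax(ys + c_$s[2], 0), ny)
    ok <- w > 0 & (tx != xs | ty != ys)
    from <- idx(xs, ys)[ok]; to <- idx(tx, ty)[ok]
    ii <- c(ii, to); jj <- c(jj, from); vv <- c(vv, w[ok])
    outflow[from] <- outflow[from] + w[ok]
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n)) -
    Matrix::Diagonal(x = outflow)
  M <- rbind(A[-1, , drop = FALSE],
             Matrix::sparseMatrix(i = rep(1, n), j = 1:n, x = 1,
                                  dims = c(1, n)))
  rhs <- c(rep(0, n - 1), 1)
  p <- tryCatch(as.numeric(Matrix::solve(M, rhs)), error = function(e) NULL)
  if (is.null(p)) {
    # extreme pivot range (probabilities spanning hundreds of orders of
    # magnitude): regularize and polish by iterative refinement
    Mr <- M + 1e-8 * Matrix::Diagonal(n)
    p <- as.numeric(Matrix::solve(Mr, rhs))
    for (k in 1:5) {
      r <- rhs - as.numeric(M %*% p)
      if (max(abs(r)) < 1e-12) break
      p <- p + as.numeric(Matrix::solve(Mr, r))
    }
  }
  p[p < 0] <- 0
  p <- p / sum(p)
  list(p = p, x = xs, y = ys)
}

#' Stationary moments by finite state projection
#'
#' Solves for the stationary distribution of the chemical master equation
#' on a truncated lattice (reflecting truncation), reporting the mass
#' `eps` on the outermost boundary shell as a truncation certificate.  The
#' box is expanded automatically until `eps < eps_tol`; the ramp inhibition
#' bounds the x marginal exactly at the integer cutoff `x0`, so only
#' unbounded directions are expanded.
#'
#' @param net A [build_network()] object.
#' @param bounds Optional list with `x`, `y` upper bounds; defaults to
#'   mean + 10 standard deviations (Poisson scale).
#' @param eps_tol Truncation tolerance on the boundary-shell mass.
#' @param max_states Hard cap on the lattice size before erroring.
#' @param keep_dist Keep the stationary distribution (data.frame
#'   `x, y, p`, zero-probability states dropped)?
#' @return A list with `moments` (a `stationary_moments`, method `"fsp"`),
#'   `eps`, `bounds`, and optionally `dist`.
#' @export
fsp_stationary_moments <- function(net, bounds = NULL, eps_tol = 1e-8,
                                   max_states = 4e5, keep_dist = FALSE) {
  circuit <- net$circuit
  two <- length(net$species) == 2
  pad <- function(m) ceiling(m + 10 * sqrt(m) + 10)
  ny <- bounds$y %||% pad(circuit$y_bar)
  nx <- if (!two) 0
        else if (is.finite(net$x_support_max)) net$x_support_max
        else bounds$x %||% pad(circuit$x_bar)
  x_bounded <- two && is.finite(net$x_support_max)
  repeat {
    if ((nx + 1) * (ny + 1) > max_states)
      stop(sprintf(
        "FSP truncation error above tolerance at cap; last bounds x<=%d y<=%d",
        nx, ny))
    sol <- fsp_solve_box(net, nx, ny)
    shell <- sol$y == ny
    if (two && !x_bounded) shell <- shell | sol$x == nx
    eps <- sum(sol$p[shell])
    if (eps < eps_tol) break
    ny <- ceiling(ny * 1.4)
    if (two && !x_bounded) nx <- ceiling(nx * 1.4)
  }
  p <- sol$p
  my <- sum(p * sol$y); vy <- sum(p * sol$y^2) - my^2
  if (two) {
    mx <- sum(p * sol$x); vx <- sum(p * sol$x^2) - mx^2
    cxy <- sum(p * sol$x * sol$y) - mx * my
  } else {
    mx <- NA_real_; vx <- NA_real_; cxy <- NA_real_
  }
  mom <- stationary_moments(mean_x = mx, mean_y = my, var_x = vx,
                            var_y = vy, cov_xy = cxy, method = "fsp")
  out <- list(moments = mom, eps = eps,
              bounds = list(x = if (two) nx else NA_integer_, y = ny))
  if (keep_dist) {
    keep <- p > 0
    out$dist <- if (two) data.frame(x = sol$x[keep], y = sol$y[keep],
                                    p = p[keep])
                else data.frame(y = sol$y[keep], p = p[keep])
  }
  out
}

#' Stationary moments by exact stochastic simulation
#'
#' Runs the compiled exact-jump (direct method) simulator.  Three input
#' regimes are supported: `"fixed"` (u clamped at the nominal value),
#' `"static_poisson"` (each run draws a constant u once, emulating
#' cell-to-cell variability), and `"birth_death"` (u co-simulated as an
#' extra birth-death species with the given rates).  Cross-run moments of
#' `y(t_final)` are returned with bootstrap standard errors, together with
#' within-run time averages over the second half of each trajectory.
#'
#' @param net A [build_network()] object.
#' @param t_final Final time; defaults to `20/min(l1, l2)` so the terminal
#'   state is effectively stationary.
#' @param n_runs Number of independent runs.
#' @param seed Integer seed.
#' @param input_regime `"fixed"`, `"static_poisson"` or `"birth_death"`.
#' @param birth_rate,death_rate Rates of the input birth-death process
#'   (regime `"birth_death"`); default mean matches the nominal input.
#' @param n_boot Bootstrap replicates for the standard errors.
#' @return A `stationary_moments` (method `"ssa"`) with extra fields
#'   `se_mean_y`, `se_var_y`, `n_runs`, `t_final`, `time_avg` (list with
#'   per-run time-averaged mean/variance of y pooled across runs).
#' @export
ssa_simulate <- function(net, t_final = NULL, n_runs = 4000, seed = 1L,
                         input_regime = c("fixed", "static_poisson",
                                          "birth_death"),
                         birth_rate = NULL, death_rate = NULL,
                         n_boot = 400) {
  input_regime <- match.arg(input_regime)
  circuit <- net$circuit
  stopifnot(n_runs >= 1)
  if (is.null(t_final))
    t_final <- 20 / min(circuit$l1, circuit$l2)
  ubar <- circuit$input$u_nominal
  reacts <- net$ssa
  if (input_regime == "birth_death") {
    if (is.null(birth_rate)) birth_rate <- ubar
    if (is.null(death_rate)) death_rate <- birth_rate / ubar
    zr <- function(su, coef, eu) c(0, 0, su, coef, 0, 0, 0, 0, 0, 0, 1, 0,
                                   0, 0, eu)
    reacts <- rbind(reacts, zr(1, birth_rate, 0), zr(-1, death_rate, 1))
  }
  if (nrow(reacts) > 64) stop("too many reaction channels")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u0 <- switch(input_regime,
    fixed = rep(ubar, n_runs),
    static_poisson = stats::rpois(n_runs, ubar),
    birth_death = rep(round(ubar), n_runs))
  x0 <- rep(round(circuit$x_bar %||% 0), n_runs)
  if (circuit$motif == "direct_fb") x0 <- rep(0, n_runs)
  init <- cbind(x0, round(circuit$y_bar) + numeric(n_runs), u0)
  res <- ssa_run_cpp(init, reacts, t_final, t_final / 2)

  yf <- res$finals[, 2]; xf <- res$finals[, 1]
  my <- mean(yf); vy <- stats::var(yf)
  boot <- vapply(seq_len(n_boot), function(i) {
    s <- sample.int(n_runs, replace = TRUE)
    c(mean(yf[s]), stats::var(yf[s]))
  }, numeric(2))
  two <- length(net$species) == 2
  stationary_moments(
    mean_x = if (two) mean(xf) else NA_real_,
    mean_y = my,
    var_x = if (two) stats::var(xf) else NA_real_,
    var_y = vy,
    cov_xy = if (two) stats::cov(xf, yf) else NA_real_,
    method = "ssa",
    extra = list(se_mean_y = stats::sd(boot[1, ]),
                 se_var_y = stats::sd(boot[2, ]),
                 n_runs = n_runs, t_final = t_final,
                 input_regime = input_regime,
                 time_avg = list(mean_y = mean(res$y_tavg),
                                 var_y = mean(res$y2_tavg) -
                                   mean(res$y_tavg)^2,
                                 cv_y = sqrt(max(mean(res$y2_tavg -
                                                        res$y_tavg^2), 0)) /
                                   mean(res$y_tavg))))
}
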