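test_that("normalization conditions hold for every constructed circuit", {
  grid <- expand.grid(motif = c("fb", "iff", "combined"),
                      coupling = c("coupled", "decoupled"),
                      a = c(0, 0.5, 1, 10, 100),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    m <- grid$motif[i]; a <- grid$a[i]
    circ <- fig1_circuit(m, grid$coupling[i],
                         alpha_fb = if (m %in% c("fb", "combined")) a else 0,
                         alpha_ff = if (m %in% c("iff", "combined")) a else 0)
    expect_equal(circ$k1, circ$l1, tolerance = 1e-12)
    expect_equal(circ$k2 + circ$k12 * circ$x_bar, circ$l2,
                 tolerance = 1e-12)
    expect_equal(inhibition_value(circ$g, circ$x_bar), 1,
                 tolerance = 1e-12)
    ss <- steady_state(circ)
    expect_equal(ss$x_bar, 50 / circ$l1, tolerance = 1e-12)
    expect_equal(ss$y_bar, 50 / circ$l2, tolerance = 1e-12)
  }
})

test_that("effective gains follow the motif definitions", {
  expect_equal(effective_gain(fig1_circuit("fb", alpha_fb = 3)), 3)
  # hill calibration: c = 10, n = 11 realizes gain 10; n = 1.1 realizes 1
  h10 <- fig1_circuit("fb", alpha_fb = 10, g_kind = "hill")
  expect_equal(h10$g$n, 11)
  expect_equal(effective_gain(h10), 10, tolerance = 1e-9)
  h1 <- fig1_circuit("fb", alpha_fb = 1, g_kind = "hill")
  expect_equal(h1$g$n, 1.1)
  expect_equal(effective_gain(h1), 1, tolerance = 1e-9)
  # iff gain is the mediated/unmediated degradation ratio
  ci <- fig1_circuit("iff", alpha_ff = 1)
  expect_equal(ci$k2, 0.5)
  expect_equal(ci$k12 * ci$x_bar, 0.5)
  expect_equal(effective_gain(ci), 1)
  expect_identical(effective_gain(fig1_circuit("iff", alpha_ff = Inf)), Inf)
  # combined gain formula
  expect_equal(effective_gain(
    fig1_circuit("combined", alpha_fb = 1, alpha_ff = 1)), 3)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(make_circuit("fb", "coupled", fig1_input(), l1 = -1, l2 = 1))
  expect_error(fig1_circuit("fb", alpha_ff = 1), "alpha_ff")
  expect_error(fig1_circuit("iff", alpha_fb = 1), "alpha_fb")
  expect_error(make_circuit("fb", "coupled", fig1_input(), 5, 1,
                            alpha_fb = Inf))
  expect_error(static_response_distribution(fig1_circuit(), numeric(0)))
})

test_that("inhibition functions are normalized, monotone, and ramp-limited", {
  g <- inhibition_spec("ramp", alpha = 1, x_anchor = 10)
  expect_equal(inhibition_value(g, 10), 1)
  expect_equal(inhibition_value(g, 20), 0)   # x0 = 2*x_anchor for alpha=1
  expect_equal(inhibition_value(g, 30), 0)
  gh <- inhibition_spec("hill", alpha = 10, x_anchor = 10)
  expect_equal(inhibition_value(gh, 10), 1, tolerance = 1e-12)
  xg <- seq(0.5, 40, by = 0.5)
  expect_true(all(diff(inhibition_value(gh, xg)) < 0))
  # slope matches a central difference
  for (gg in list(g, gh)) {
    num <- (inhibition_value(gg, 12 + 1e-6) -
              inhibition_value(gg, 12 - 1e-6)) / 2e-6
    expect_equal(inhibition_slope(gg, 12), num, tolerance = 1e-5)
  }
})

test_that("deterministic steady state matches the ODE fixed point", {
  circ <- fig1_circuit("fb", alpha_fb = 1)
  expect_equal(steady_state(circ)$y_bar, 50)
  tr <- integrate_ode(circ, 10, seq(0, 5, by = 0.1))
  expect_rel_equal(tr$y[nrow(tr)], 50, 1e-9)
  expect_rel_equal(tr$x[nrow(tr)], 10, 1e-9)
  # convergence from a perturbed initial condition
  tr2 <- integrate_ode(circ, 10, seq(0, 18, by = 0.1),
                       init_state = c(2, 5))
  expect_rel_equal(tr2$y[nrow(tr2)], 50, 1e-5)
  # doubling l1 halves x_bar, leaves y_bar unchanged
  c2 <- make_circuit("fb", "coupled", fig1_input(), l1 = 10, l2 = 1)
  expect_equal(steady_state(c2)$x_bar, 5)
  expect_equal(steady_state(c2)$y_bar, 50)
  # unregulated relaxation is exponential at rates l1, l2
  c0 <- fig1_circuit()
  tr3 <- integrate_ode(c0, 10, seq(0, 1, by = 0.05), init_state = c(0, 0))
  expect_equal(tr3$x, 10 * (1 - exp(-5 * tr3$t)), tolerance = 1e-6)
  expect_equal(tr3$y, 50 * (1 - exp(-1 * tr3$t)), tolerance = 1e-6)
})

test_that("static steady-state curve obeys its closed form and limits", {
  circ <- fig1_circuit("fb", alpha_fb = 100)
  expect_equal(yss_static(circ, 10), 50)
  expect_rel_equal(yss_static(circ, 20), 10100 / 201, 1e-12)
  expect_equal(yss_static(fig1_circuit(), 14), 70)  # alpha=0: f(u)/l2
  # identical curves for fb and iff at matched gain
  u <- c(2, 5, 10, 15, 30)
  expect_equal(yss_static(fig1_circuit("fb", alpha_fb = 7), u),
               yss_static(fig1_circuit("iff", alpha_ff = 7), u),
               tolerance = 1e-12)
  # closed form agrees with the ODE steady state off-nominal
  tr <- integrate_ode(fig1_circuit("fb", alpha_fb = 3), 17,
                      seq(0, 30, by = 0.1))
  expect_rel_equal(tr$y[nrow(tr)], yss_static(fig1_circuit("fb",
                                                           alpha_fb = 3),
                                              17), 1e-7)
  # step response with high gain settles at the near-adapted value
  trs <- integrate_ode(fig1_circuit("fb", alpha_fb = 100), 20,
                       seq(0, 50, by = 0.1))
  expect_rel_equal(trs$y[nrow(trs)], 10100 / 201, 1e-4)
})

test_that("sensitivity equals the finite difference of the steady state", {
  # closed-form examples
  expect_equal(sensitivity_yss(fig1_circuit()), 5)
  expect_equal(sensitivity_yss(fig1_circuit("fb", alpha_fb = 1e12)), 0,
               tolerance = 1e-9)
  expect_equal(sensitivity_yss(fig1_circuit("iff", alpha_ff = Inf)), 0)
  # finite-difference check across motifs, gains and inhibition families
  fd_sens <- function(circ, h = 1e-3) {
    (yss_static(circ, 10 + h) - yss_static(circ, 10 - h)) / (2 * h)
  }
  cases <- list(fig1_circuit("fb", alpha_fb = 2),
                fig1_circuit("iff", alpha_ff = 2),
                fig1_circuit("fb", alpha_fb = 5, g_kind = "hill"))
  for (circ in cases)
    expect_rel_equal(sensitivity_yss(circ), fd_sens(circ), 1e-4)
  # combined circuit matches the combined-gain formula on a gain grid
  for (afb in c(0, 0.5, 1, 2)) for (aff in c(0, 0.5, 1, 2)) {
    circ <- fig1_circuit("combined", alpha_fb = afb, alpha_ff = aff)
    a_comb <- afb + aff + afb * aff
    expect_rel_equal(sensitivity_yss(circ), 5 / (1 + a_comb), 1e-9)
    expect_rel_equal(fd_sens(circ), 5 / (1 + a_comb), 1e-4)
  }
  expect_equal(sensitivity_yss(fig1_circuit("combined", alpha_fb = 1,
                                            alpha_ff = 1)), 1.25)
})

test_that("static response distributions tighten as the gain grows", {
  u <- sample_static_poisson_u(10, 20000, seed = 101)
  d0 <- static_response_distribution(fig1_circuit(), u)
  # alpha=0 is the exact linear map y = 5u
  expect_equal(d0$summary$variance, 25 * stats::var(u), tolerance = 1e-12)
  d100 <- static_response_distribution(fig1_circuit("fb", alpha_fb = 100),
                                       u)
  expect_lt(d100$summary$variance, d0$summary$variance / 100)
  # degenerate input: all outputs at the nominal value
  dd <- static_response_distribution(fig1_circuit("fb", alpha_fb = 2),
                                     rep(10, 5))
  expect_equal(dd$samples$y_ss, rep(50, 5))
  expect_equal(dd$summary$variance, 0)
})

test_that("hill and ramp inhibition give similar static distributions", {
  u <- sample_static_poisson_u(10, 20000, seed = 102)
  v0 <- static_response_distribution(fig1_circuit(), u)$summary$variance
  for (a in c(1, 10, 100)) {
    vr <- static_response_distribution(
      fig1_circuit("fb", alpha_fb = a), u)$summary$variance
    vh <- static_response_distribution(
      fig1_circuit("fb", alpha_fb = a, g_kind = "hill"), u)$summary$variance
    expect_lt(abs(log(vh / vr)), log(2))
    expect_lt(vh, v0 / (1 + a))     # both far below the unregulated spread
    expect_lt(vr, v0 / (1 + a))
  }
})

test_that("circuits round-trip through the YAML config schema", {
  circ <- fig1_circuit("combined", "decoupled", alpha_fb = 2,
                       alpha_ff = 0.5, g_kind = "hill")
  path <- withr::local_tempfile(fileext = ".yaml")
  circuit_to_config(circ, path)
  back <- circuit_from_config(path)
  for (f in c("motif", "coupling", "l1", "l2", "alpha_fb", "alpha_ff",
              "k1", "k2", "k12", "x_bar", "y_bar"))
    expect_equal(back[[f]], circ[[f]], info = f)
  expect_equal(back$g$kind, circ$g$kind)
  # infinite feedforward gain survives the round trip
  ci <- fig1_circuit("iff", alpha_ff = Inf)
  expect_identical(circuit_from_config(circuit_to_config(ci))$alpha_ff, Inf)
})
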