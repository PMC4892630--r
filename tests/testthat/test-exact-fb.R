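test_that("direct autoinhibition has binomial-law moments", {
  m0 <- direct_fb_stationary(50, 1, 0)
  expect_equal(m0$var_y, 50)                      # Poisson limit
  expect_equal(direct_fb_stationary(50, 1, 1e4)$var_y, 50 / 51)
  # y_bar=50, alpha=4: cutoff 62.5 rounds to 62, effective gain 25/6
  m4 <- direct_fb_stationary(50, 1, 4)
  expect_equal(m4$alpha_eff, 50 / 12)
  expect_equal(m4$var_y, 50 / (1 + 50 / 12))
  expect_rel_equal(m4$var_y, 10, 0.05)            # ~ y_bar/(1+alpha) for alpha=4
  # FSP of the same one-species scheme agrees to truncation accuracy
  net <- build_network(make_circuit("direct_fb", "coupled",
                                    input_spec(0, 50, 1), 1, 1,
                                    alpha_fb = 4))
  fsp <- fsp_stationary_moments(net)
  expect_rel_equal(fsp$moments$var_y, m4$var_y, 1e-3)
  expect_rel_equal(fsp$moments$mean_y, 50, 1e-6)
})

test_that("moment-equation solution reproduces the closed-form penalties", {
  for (r in c(0.1, 1, 10)) for (a in c(0.1, 1, 10, 100)) {
    for (cp in c("coupled", "decoupled")) {
      circ <- make_circuit("fb", cp, input_spec(0, 50, 1), l1 = 1 / r,
                           l2 = 1, alpha_fb = a)
      m <- fb_stationary_moments(circ)
      expect_rel_equal(m$var_y,
                       fb_variance_ramp(m$alpha_eff, r, 50, cp), 1e-9)
      expect_equal(m$mean_y, 50, tolerance = 1e-9)
      expect_equal(m$mean_x, 50 * r, tolerance = 1e-9)
      expect_gte(m$p_proxy, -1e-12)
      expect_gte(m$p_decouple, -1e-12)
    }
  }
  # no feedback: Poisson in both couplings, penalties vanish
  m0 <- fb_stationary_moments(flat50_circuit("fb"))
  expect_equal(m0$var_y, 50, tolerance = 1e-9)
  expect_equal(m0$p_proxy, 0, tolerance = 1e-9)
})

test_that("exact feedback variances match FSP at x_bar = y_bar = 50", {
  for (cp in c("coupled", "decoupled")) for (a in c(0, 1, 5, 10)) {
    circ <- flat50_circuit("fb", cp, alpha_fb = a)
    ex <- fb_stationary_moments(circ)
    fs <- fsp_stationary_moments(build_network(circ))
    expect_rel_equal(fs$moments$var_y, ex$var_y, 1e-3)
    expect_rel_equal(fs$moments$mean_y, 50, 1e-3)
  }
})

test_that("penalty terms are monotone and decoupling always hurts", {
  alphas <- c(0.1, 0.5, 1, 2, 5, 20, 100)
  for (r in c(0.1, 1, 10)) {
    pp <- 50 * alphas * (alphas + r) / ((1 + alphas) * (1 + alphas + r))
    pd <- 50 * alphas / (1 + alphas + r)
    expect_true(all(diff(pp) > 0))          # proxy penalty grows with gain
    vc <- fb_variance_ramp(alphas, r, 50, "coupled")
    vd <- fb_variance_ramp(alphas, r, 50, "decoupled")
    expect_true(all(vd > vc))               # decoupled strictly worse
    expect_true(all(vd > 50))               # decoupled worse than no control
  }
  # decoupling penalty decreases with the abundance ratio
  for (a in c(0.5, 2, 10))
    expect_true(all(diff(50 * a / (1 + a + c(0.1, 1, 10))) < 0))
  # coupled, alpha -> infinity: regulation fully wasted (var -> y_bar)
  expect_rel_equal(fb_variance_ramp(1e6, 1, 50, "coupled"), 50, 1e-4)
})

test_that("optimal feedback gain follows sqrt(1+r) and the printed anchors", {
  o0 <- optimal_gain_fb(1e-6, "coupled")
  expect_equal(100 * o0$reduction_fraction, 25, tolerance = 0.1)
  expect_equal(o0$alpha_opt, 1, tolerance = 0.01)
  o1 <- optimal_gain_fb(1, "coupled")
  expect_equal(round(100 * o1$reduction_fraction), 17)
  expect_equal(o1$alpha_opt, sqrt(2), tolerance = 1e-4)
  for (r in c(0.3, 2, 8))                       # analytic minimizer
    expect_rel_equal(optimal_gain_fb(r, "coupled")$alpha_opt, sqrt(1 + r),
                     1e-4)
  expect_lt(optimal_gain_fb(1e6, "coupled")$reduction_fraction, 1e-3)
  od <- optimal_gain_fb(1, "decoupled")
  expect_equal(od$alpha_opt, 0)
  expect_equal(od$reduction_fraction, 0)
})

test_that("mixture variance closed forms and threshold behave as derived", {
  # keep C = a*u_mean = 50 fixed while the input-noise level (u_mean) varies
  circ <- function(cp, a, um = 10)
    make_circuit("fb", cp, input_spec(50 / um, 0, um), l1 = 1, l2 = 1,
                 alpha_fb = a)
  nofb <- static_mixture_variance(circ("coupled", 0), 10, "no_fb")
  expect_equal(nofb$var_y, 300)               # 50 chemical + 250 input
  expect_equal(nofb$chem_component, 50)
  cs <- static_mixture_variance(circ("coupled", 50), 10, "coupled_strong")
  expect_equal(cs$var_y, 49)
  ds <- static_mixture_variance(circ("decoupled", 50), 10,
                                "decoupled_strong")
  expect_equal(ds$var_y, 99)
  # coupled strong feedback beats no feedback for every parameter set
  for (um in c(1, 5, 40, 200)) {
    n <- static_mixture_variance(circ("coupled", 0, um), um, "no_fb")$var_y
    s <- static_mixture_variance(circ("coupled", 50, um), um,
                                 "coupled_strong")$var_y
    expect_lt(s, n)
  }
  # decoupled strong feedback wins only below the input-noise threshold
  thr <- nofb$u_threshold
  expect_equal(thr, 2500 / 49)
  cmp_at <- function(um) {
    d <- static_mixture_variance(circ("decoupled", 50, um), um,
                                 "decoupled_strong")$var_y
    n <- static_mixture_variance(circ("coupled", 0, um), um, "no_fb")$var_y
    d - n
  }
  expect_lt(cmp_at(0.9 * thr), 0)
  expect_gt(cmp_at(1.1 * thr), 0)
  # finite-gain mixture: law of total variance with exact conditionals
  fin0 <- static_mixture_variance(circ("coupled", 0), 10, "finite")
  expect_rel_equal(fin0$var_y, 300, 1e-6)
  fin2 <- static_mixture_variance(circ("coupled", 2), 10, "finite")
  expect_lt(fin2$var_y, 300)
  expect_gt(fin2$var_y, 49)
})

test_that("mixture closed forms agree with stochastic simulation", {
  circ <- function(cp, a) make_circuit("fb", cp, input_spec(5, 0, 10),
                                       l1 = 1, l2 = 1, alpha_fb = a)
  s <- ssa_simulate(build_network(circ("coupled", 50)), n_runs = 4000,
                    seed = 61, input_regime = "static_poisson")
  expect_lt(abs(s$var_y - 49), 4 * s$se_var_y)
  fin <- static_mixture_variance(circ("coupled", 2), 10, "finite")
  s2 <- ssa_simulate(build_network(circ("coupled", 2)), n_runs = 4000,
                     seed = 62, input_regime = "static_poisson")
  expect_lt(abs(s2$var_y - fin$var_y), 4 * s2$se_var_y)
})
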