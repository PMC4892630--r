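test_that("linearization produces the expected drift structure", {
  A0 <- linearize(fig1_circuit())$A
  expect_equal(A0, matrix(c(-5, 0, 0, -1), 2, 2, byrow = TRUE))
  # feedback drift is triangular with eigenvalues -l1(1+a), -l2
  for (a in c(0.5, 3, 50)) {
    A <- linearize(fig1_circuit("fb", alpha_fb = a))$A
    expect_equal(sort(eigen(A, only.values = TRUE)$values),
                 sort(c(-5 * (1 + a), -1)), tolerance = 1e-12)
  }
  # infinite-gain feedforward: A[2,1] = -l2 * y_bar / x_bar
  Ai <- linearize(fig1_circuit("iff", alpha_ff = Inf))$A
  expect_equal(Ai[2, 1], -1 * 50 / 10)
  # noise channels
  m <- linearize(fig1_circuit(), "additive", sigma = 7)
  expect_equal(as.vector(m$B), c(7, 7))
  m2 <- linearize(fig1_circuit(), "input_derivative")
  expect_equal(as.vector(m2$B), c(5, 5))
  expect_error(linearize(make_circuit("direct_fb", "coupled", fig1_input(),
                                      5, 1, alpha_fb = 1)))
})

test_that("the H2 norm matches closed forms, monotonicity and the iff floor", {
  sig <- 1
  h2 <- function(motif, a) {
    circ <- fig1_circuit(motif,
                         alpha_fb = if (motif == "fb") a else 0,
                         alpha_ff = if (motif == "iff") a else 0)
    h2_norm_squared(linearize(circ, "additive", sig))
  }
  expect_equal(h2("fb", 0), sig^2 / 2)        # scalar OU variance sigma^2/(2 l2)
  grid <- 10^seq(-2, 4, length.out = 25)
  hfb <- vapply(grid, function(a) h2("fb", a), numeric(1))
  expect_true(all(diff(hfb) < 0))             # fb: monotone decreasing
  expect_lt(hfb[length(grid)], 1e-2 * h2("fb", 0))
  hiff <- vapply(grid, function(a) h2("iff", a), numeric(1))
  floor_ <- sig^2 / (2 * (5 + 1))
  expect_true(all(hiff >= floor_ - 1e-12))    # iff floor sigma^2/(2(l1+l2))
  expect_lt(min(hiff), floor_ * 1.01)         # and it is approached
  h_inf <- h2_norm_squared(linearize(fig1_circuit("iff", alpha_ff = Inf),
                                     "additive", sig))
  expect_rel_equal(h_inf, floor_, 1e-9)
  # invariance under a state rescaling consistent with the output map
  m <- linearize(fig1_circuit("fb", alpha_fb = 2), "additive", sig)
  T_ <- diag(c(3, 1))
  m2 <- m
  m2$A <- T_ %*% m$A %*% solve(T_); m2$B <- T_ %*% m$B
  m2$C <- m$C %*% solve(T_)
  expect_rel_equal(h2_norm_squared(m2), h2_norm_squared(m), 1e-12)
})

test_that("H2 predictions agree with ensemble SDE variances in the linear regime", {
  # noise scaled into the ramp's active region (halfwidth x_bar/alpha)
  for (a in c(0, 1, 10)) {
    for (motif in c("fb", "iff")) {
      sig <- if (motif == "fb") min(5, 2 * 10 / (1 + a)) else 5
      circ <- fig1_circuit(motif,
                           alpha_fb = if (motif == "fb") a else 0,
                           alpha_ff = if (motif == "iff") a else 0)
      pred <- h2_norm_squared(linearize(circ, "additive", sig))
      ens <- simulate_sde_ensemble(circ, sig, t_final = 20, n_runs = 300,
                                   seed = 31 + a)
      expect_gt(pred, ens$ci[1])
      expect_lt(pred, ens$ci[2])
    }
  }
})

test_that("high-gain feedback beats feedforward under white input noise", {
  efb <- simulate_sde_ensemble(fig1_circuit("fb", alpha_fb = 100), 50,
                               t_final = 20, n_runs = 800, seed = 41)
  eiff <- simulate_sde_ensemble(fig1_circuit("iff", alpha_ff = 100), 50,
                                t_final = 20, n_runs = 800, seed = 42)
  expect_lt(efb$ci[2], eiff$ci[1])   # disjoint CIs, fb strictly smaller
  expect_error(simulate_sde_ensemble(fig1_circuit("fb", alpha_fb = 100),
                                     50, dt = 0.1, n_runs = 100),
               "stability")
})

test_that("trajectory-driven cv reproduces the regulation orderings", {
  expect_equal(cv_dynamic_response(fig1_circuit("fb", alpha_fb = 1), 10,
                                   seq(0, 30, by = 0.1))$cv, 0,
               tolerance = 1e-7)
  traj <- simulate_birth_death_u(10, 1, t_final = 80, seed = 51)
  cvs <- sapply(c(fb0 = 0, fb1 = 1), function(a)
    cv_dynamic_response(fig1_circuit("fb", alpha_fb = a, g_kind = "hill"),
                        traj)$cv)
  expect_lt(cvs["fb1"], cvs["fb0"])  # even low gain reduces the cv
  cv_iff1 <- cv_dynamic_response(fig1_circuit("iff", alpha_ff = 1), traj)$cv
  expect_lt(cv_iff1, cvs["fb0"])
  cv_fb100 <- cv_dynamic_response(
    fig1_circuit("fb", alpha_fb = 100, g_kind = "hill"), traj)$cv
  cv_iff100 <- cv_dynamic_response(
    fig1_circuit("iff", alpha_ff = 100), traj)$cv
  expect_lt(cv_fb100, cv_iff100)     # high-gain fb outperforms iff
})
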