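# shared fixtures: the two parameter sets used throughout
# - "fig1": f(u) = 5u, u_nominal = 10, l1 = 5, l2 = 1  (x_bar 10, y_bar 50)
# - "flat50": constant input f = 50, l1 = l2 = 1        (x_bar = y_bar = 50)

fig1_input <- function() input_spec(5, 0, 10)

fig1_circuit <- function(motif = "fb", coupling = "coupled", alpha_fb = 0,
                         alpha_ff = 0, g_kind = "ramp") {
  make_circuit(motif, coupling, fig1_input(), l1 = 5, l2 = 1,
               alpha_fb = alpha_fb, alpha_ff = alpha_ff, g_kind = g_kind)
}

flat50_circuit <- function(motif = "fb", coupling = "coupled", alpha_fb = 0,
                           alpha_ff = 0, g_kind = "ramp", l1 = 1) {
  make_circuit(motif, coupling, input_spec(0, 50, 1), l1 = l1, l2 = 1,
               alpha_fb = alpha_fb, alpha_ff = alpha_ff, g_kind = g_kind)
}

# iff circuit with prescribed mean populations (l2 = 1 time units)
iff_at <- function(x_bar, y_bar, alpha_ff, coupling = "coupled") {
  make_circuit("iff", coupling, input_spec(0, y_bar, 1), l1 = y_bar / x_bar,
               l2 = 1, alpha_ff = alpha_ff)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol)
}
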