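# Shared fixtures: all inputs are generated in code at test time.

# a random valid set of dimensionless groups in the microtubule-shell range
random_groups <- function(eta = stats::runif(1, 0, 0.25),
                          sK = stats::runif(1, 0, 1e-3)) {
  dimensionless_groups(
    k1 = stats::runif(1, 0.005, 1.5),
    k2 = stats::runif(1, 1e-4, 0.5),
    c2 = stats::runif(1, 1e-4, 0.05),
    mu1 = stats::runif(1, 0, 0.49),
    eta = eta, l = stats::runif(1, 5, 40), sK = sK)
}

# the groups of the illustrative orthotropic microtubule fixture (a short
# inter-crosslink segment, so the critical mode falls inside a modest
# search window), with an overridable nonlocal parameter and foundation
fixture_groups <- function(eta = 0, Ec = 1e3) {
  g <- shell_geometry(L = 112e-9, R = 11.2e-9, h = 2.7e-9, h0 = 1.6e-9)
  m <- orthotropic_material(E1 = 1.5e9, E2 = 3e6, G = 1.5e6, mu1 = 0.3, mu2 = 0.3)
  e <- shell_environment(Ec = Ec, ea0 = eta * 11.2e-9)
  derive_groups(g, m, e)
}

# isotropic wall variant (its stiffness form is positive definite over the
# searched mode grid, so spectral lower bounds apply unconditionally)
isotropic_groups <- function(eta = 0.1, Ec = 1e3) {
  g <- shell_geometry(L = 112e-9, R = 11.2e-9, h = 2.7e-9, h0 = 1.6e-9)
  m <- orthotropic_material(E1 = 1e9, E2 = 1e9, G = 0.385e9, mu1 = 0.3, mu2 = 0.3)
  derive_groups(g, m, shell_environment(Ec = Ec, ea0 = eta * 11.2e-9))
}

# simply supported ansatz of one mode as concrete fields
ss_ansatz_fields <- function(mode, amps = c(1, 1, 1)) {
  list(
    u = trig_field(amps[1], lam = mode$lambda, fx = "cos", n = mode$n, fth = "cos"),
    v = trig_field(amps[2], lam = mode$lambda, fx = "sin", n = mode$n, fth = "sin"),
    w = trig_field(amps[3], lam = mode$lambda, fx = "sin", n = mode$n, fth = "cos"))
}

random_field_set <- function(with_pressure = FALSE) {
  f <- list(u = random_smooth_field(), v = random_smooth_field(),
            w = random_smooth_field())
  if (with_pressure) f$P <- random_smooth_field()
  f
}

empty_field <- function() trig_field(0)

# exact equality of two linear differential expressions (jet algebra)
expect_le_zero <- function(le) {
  expect_true(mtbuckle:::le_is_zero(le),
              label = paste("expression is symbolically zero:",
                            mtbuckle:::.le_format(le)))
}
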