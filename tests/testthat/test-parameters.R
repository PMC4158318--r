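test_that("dimensionless groups follow their defining formulas", {
  g <- shell_geometry(L = 560e-9, R = 11.2e-9, h = 2.7e-9, h0 = 1.6e-9)
  m <- orthotropic_material(E1 = 1e9, E2 = 1e9, G = 0.4e9, mu1 = 0.3, mu2 = 0.3)
  gr <- derive_groups(g, m, shell_environment())

  # equal moduli give a unit modulus ratio
  expect_identical(gr$k1, 1)
  # hand evaluation, independent arithmetic: K = E1*h/(1 - mu1*mu2)
  expect_equal(gr$K, 1e9 * 2.7e-9 / (1 - 0.09), tolerance = 1e-14)
  expect_equal(gr$k2, 0.4e9 * (1 - 0.09) / 1e9, tolerance = 1e-14)
  expect_equal(gr$c2, (1.6e-9)^3 / (12 * (11.2e-9)^2 * 2.7e-9), tolerance = 1e-14)
  expect_equal(gr$l, 50, tolerance = 1e-14)
  expect_gt(gr$K, 0)

  # h0 = h collapses c2 to h^2 / (12 R^2)
  g2 <- shell_geometry(L = 560e-9, R = 11.2e-9, h = 2.7e-9)
  gr2 <- derive_groups(g2, m, shell_environment())
  expect_equal(gr2$c2, (2.7e-9)^2 / (12 * (11.2e-9)^2), tolerance = 1e-14)
})

test_that("foundation constant resolves to 2.7 Ec unless user-set", {
  g <- shell_geometry(L = 1e-6, R = 1e-8, h = 2e-9)
  m <- orthotropic_material(1e9, 1e7, 1e6, 0.3, 0.3)
  gr <- derive_groups(g, m, shell_environment(Ec = 1.0))
  expect_equal(gr$sigma, 2.7)
  gr_user <- derive_groups(g, m, shell_environment(Ec = 1.0, sigma = 5))
  expect_equal(gr_user$sigma, 5)
  expect_equal(gr$sK, 2.7 * 1e-8 / gr$K)
})

test_that("group derivation is invariant under a global length rescale", {
  base <- list(L = 3e-7, R = 1.1e-8, h = 2.5e-9, h0 = 1.5e-9, ea0 = 2e-9)
  m <- orthotropic_material(2e9, 5e6, 2e6, 0.25, 0.35)
  ref <- derive_groups(shell_geometry(base$L, base$R, base$h, base$h0), m,
                       shell_environment(ea0 = base$ea0))
  for (alpha in c(0.1, 3, 1e3)) {
    gr <- derive_groups(
      shell_geometry(alpha * base$L, alpha * base$R, alpha * base$h, alpha * base$h0),
      m, shell_environment(ea0 = alpha * base$ea0))
    for (f in c("k1", "k2", "c2", "l", "eta")) {
      expect_equal(gr[[f]], ref[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("invalid physical inputs are rejected with clear errors", {
  expect_error(orthotropic_material(-1, 1, 1, 0.3, 0.3), "strictly positive")
  expect_error(orthotropic_material(1, 1, 1, 1.2, 0.3), "Poisson")
  expect_error(shell_geometry(1e-6, 1e-8, 2e-8), "smaller than the radius")
  expect_error(shell_geometry(0, 1e-8, 1e-9), "strictly positive")
  expect_warning(shell_geometry(1e-6, 1e-8, 5e-9, h0 = 2e-8), "exceeds")
  expect_error(shell_environment(ea0 = -1), "ea0")
})

test_that("nonlocal harmonic stress attenuates the local Hooke law", {
  m <- orthotropic_material(E1 = 2e9, E2 = 5e6, G = 2e6, mu1 = 0.25, mu2 = 0.35)
  strain <- list(ex = 0.01, eth = -0.004, exth = 0.002)
  om <- 1 - 0.25 * 0.35
  local <- list(sx = (2e9 * 0.01 + 5e6 * 0.35 * -0.004) / om,
                sth = (5e6 * -0.004 + 2e9 * 0.25 * 0.01) / om,
                txth = 2e6 * 0.002)

  # eta = 0: exactly local, for any wavenumbers
  s0 <- nonlocal_harmonic_stress(strain, lambda = 2.3, n = 4, m, groups = 0)
  expect_equal(s0[c("sx", "sth", "txth")], local, tolerance = 1e-14)
  expect_identical(s0$attenuation, 1)

  # uniform strain: the Laplacian of a constant vanishes, local again
  su <- nonlocal_harmonic_stress(strain, lambda = 0, n = 0, m, groups = 0.4)
  expect_equal(su[c("sx", "sth", "txth")], local, tolerance = 1e-14)

  # the derived scalar relation: eta = 0.1, lambda = n = 1 -> 1/1.02
  s1 <- nonlocal_harmonic_stress(strain, lambda = 1, n = 1, m, groups = 0.1)
  expect_equal(s1$attenuation, 1 / 1.02, tolerance = 1e-15)
  expect_equal(s1$sx, local$sx / 1.02, tolerance = 1e-14)

  # attenuation factor is <= 1 on a grid, = 1 iff eta*(lam^2+n^2) = 0
  for (eta in c(0, 0.05, 0.3)) {
    for (lam in c(0, 0.7, 3)) {
      for (n in 0:3) {
        a <- nonlocal_harmonic_stress(strain, lam, n, m, eta)$attenuation
        expect_lte(a, 1)
        if (eta * (lam^2 + n^2) == 0) expect_identical(a, 1) else expect_lt(a, 1)
      }
    }
  }
  expect_error(nonlocal_harmonic_stress(strain, 1, 1.5, m, 0.1), "integer")
})
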