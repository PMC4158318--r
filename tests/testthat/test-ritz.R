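# Rayleigh-Ritz assembly, the Galerkin oracle, and the critical-load search.

test_that("Ritz matrices agree with the Galerkin oracle over random draws", {
  set.seed(17)
  for (i in 1:20) {
    gr <- random_groups()
    md <- trial_mode(sample(1:5, 1), sample(0:8, 1), gr$l)
    rz <- assemble_mode_matrices(gr, md)
    go <- galerkin_oracle(gr, md)
    ks <- max(abs(rz$K))
    expect_lt(max(abs(rz$K - go$K)) / ks, 1e-12)
    expect_equal(go$G, rz$G, tolerance = 1e-15)
    # the raw Galerkin projection is itself symmetric: variational consistency
    expect_lt(go$max_asymmetry / ks, 1e-12)
    expect_lt(max(abs(rz$K - t(rz$K))) / ks, 1e-12)
  }
})

test_that("geometric matrix entries match the hand integral for the u-channel", {
  gr <- random_groups()
  md <- trial_mode(3, 2, gr$l)
  rz <- assemble_mode_matrices(gr, md)
  lam <- md$lambda
  # by-hand integration of the load density for u = A cos(lam x) cos(n th):
  # (lam^2 + eta^2 (lam^4 + lam^2 n^2)) times the trig norm l/2 * pi
  expect_equal(rz$G[1, 1],
               (lam^2 + gr$eta^2 * (lam^4 + lam^2 * md$n^2)) * gr$l / 2 * pi,
               tolerance = 1e-13)
  expect_true(all(eigen(rz$G[rz$active, rz$active], symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("eta = 0 assembly equals the independent local code path", {
  set.seed(23)
  for (i in 1:5) {
    gr <- random_groups(eta = 0)
    md <- trial_mode(sample(1:4, 1), sample(0:6, 1), gr$l)
    rz <- assemble_mode_matrices(gr, md)
    lc <- local_mode_matrices(gr, md)
    expect_lt(max(abs(rz$K - lc$K)) / max(abs(lc$K)), 1e-12)
    expect_lt(max(abs(rz$G - lc$G)) / max(abs(lc$G)), 1e-12)
  }
  # and the resulting critical loads agree to 1e-10 relative
  gr <- fixture_groups(eta = 0)
  res <- critical_load(gr, 1:25, 0:6)
  lc <- local_mode_matrices(gr, res$mode)
  act <- if (res$mode$n == 0) c(1L, 3L) else 1:3
  ev <- mtbuckle:::.pencil_eigen(lc$K[act, act], lc$G[act, act])
  nloc <- min(ev$values[ev$values > 0])
  expect_equal(res$N_cr, nloc, tolerance = 1e-10)
})

test_that("Rayleigh quotient is homogeneous, stationary, and bounded below", {
  set.seed(29)
  # isotropic wall: the stiffness form is positive definite on these modes,
  # so every trial quotient is an upper bound for the buckling load
  gr <- isotropic_groups(eta = 0.1)
  for (mn in list(c(1, 2), c(3, 5), c(2, 0))) {
    md <- trial_mode(mn[1], mn[2], gr$l)
    rz <- assemble_mode_matrices(gr, md)
    act <- rz$active
    ev <- mtbuckle:::.pencil_eigen(rz$K[act, act], rz$G[act, act])
    expect_true(all(abs(Im(ev$values)) == 0))  # real symmetric pencil
    expect_true(all(ev$values > 0))            # positive definite stiffness
    nmin <- min(ev$values)
    qmin <- ev$vectors[, which.min(ev$values)]

    # stationarity: the eigenvector attains its eigenvalue
    expect_equal(rayleigh_quotient(qmin, rz), nmin, tolerance = 1e-12)
    # homogeneity: scaling the amplitudes leaves the quotient unchanged
    for (alpha in c(-3, 0.017, 40)) {
      expect_equal(rayleigh_quotient(alpha * qmin, rz), nmin, tolerance = 1e-12)
    }
    # eigenstructure residual
    resid <- (rz$K[act, act] - nmin * rz$G[act, act]) %*% qmin
    expect_lt(max(abs(resid)), 1e-9 * max(abs(rz$K)))

    # Courant-Fischer bound sampled by brute force: 100 random trial
    # vectors never undercut the smallest positive eigenvalue
    q100 <- matrix(stats::rnorm(100 * length(act)), ncol = length(act))
    quot <- apply(q100, 1, rayleigh_quotient, matrices = rz)
    expect_true(all(quot >= nmin * (1 - 1e-12)))
  }

  # strongly orthotropic wall: the stiffness form is indefinite (the
  # negative branch corresponds to tensile instabilities outside the
  # model); the sampled quotients then respect the signed spectral range
  gro <- fixture_groups(eta = 0.1)
  md <- trial_mode(1, 2, gro$l)
  rzo <- assemble_mode_matrices(gro, md)
  evo <- mtbuckle:::.pencil_eigen(rzo$K, rzo$G)
  q100 <- matrix(stats::rnorm(300), ncol = 3)
  quot <- apply(q100, 1, rayleigh_quotient, matrices = rzo)
  expect_true(all(quot >= min(evo$values) - 1e-9 * max(abs(evo$values))))
  expect_true(all(quot <= max(evo$values) + 1e-9 * max(abs(evo$values))))

  expect_error(rayleigh_quotient(c(0, 0, 0), rzo), "not all vanish")
})

test_that("critical load search honours minima, monotonicity and tie-breaks", {
  gr <- fixture_groups(eta = 0.05)
  res <- critical_load(gr, 1:6, 0:6)
  expect_false(res$no_buckling)
  expect_equal(res$N_cr, min(res$table$N_dimless))
  expect_equal(res$N_cr_dimensional, res$N_cr * gr$K)
  expect_equal(sum(res$table$is_critical), 1L)
  expect_equal(sqrt(sum(res$eigenvector^2)), 1, tolerance = 1e-12)

  # enlarging the search range can only lower (or keep) the minimum
  res_small <- critical_load(gr, 1:3, 0:3)
  expect_gte(res_small$N_cr, res$N_cr)

  # softening with the small-scale parameter: N_cr non-increasing in eta
  etas <- c(0, 0.05, 0.1, 0.2)
  ncr <- vapply(etas, function(e) critical_load(fixture_groups(eta = e),
                                                1:6, 0:6)$N_cr, numeric(1))
  expect_true(all(diff(ncr) <= 1e-12))
  expect_true(any(diff(ncr) < -1e-8 * ncr[1]))

  # stiffening with the foundation: N_cr non-decreasing in sigma
  Ecs <- c(0, 500, 1000, 2000)
  ncr_f <- vapply(Ecs, function(Ec) critical_load(fixture_groups(eta = 0.1, Ec = Ec),
                                                  1:6, 0:6)$N_cr, numeric(1))
  expect_true(all(diff(ncr_f) >= -1e-12))
})

test_that("axisymmetric modes reduce to the (u, w) block", {
  gr <- fixture_groups(eta = 0.08)
  md <- trial_mode(2, 0, gr$l)
  rz <- assemble_mode_matrices(gr, md)
  expect_true(rz$reduced)
  expect_identical(rz$active, c(1L, 3L))
  # the v row/column of both matrices vanishes identically
  expect_equal(rz$K[2, ], c(u = 0, v = 0, w = 0))
  expect_equal(rz$G[2, ], c(u = 0, v = 0, w = 0))
  # solving the reduced block equals striking the v row/column by hand
  ev2 <- mtbuckle:::.pencil_eigen(rz$K[c(1, 3), c(1, 3)], rz$G[c(1, 3), c(1, 3)])
  go <- galerkin_oracle(gr, md)
  ev2o <- mtbuckle:::.pencil_eigen(go$K[c(1, 3), c(1, 3)], go$G[c(1, 3), c(1, 3)])
  expect_equal(ev2$values, ev2o$values, tolerance = 1e-12)
})

test_that("pressure models route correctly through the assembly", {
  gr <- fixture_groups(eta = 0.1)
  md <- trial_mode(2, 3, gr$l)
  base <- assemble_mode_matrices(gr, md)

  # proportional pressure shifts only the w-diagonal, by its Galerkin term
  kappa <- 2e2
  grp <- gr
  grp$pressure <- pressure_proportional(kappa)
  withp <- assemble_mode_matrices(grp, md)
  shift <- -gr$RK * kappa * (1 + gr$eta^2 * (md$lambda^2 + md$n^2)) *
    mtbuckle:::.basis_norm("w", md$lambda, md$n, gr$l)
  # the shift is tiny against K[3,3], so compare at the cancellation floor
  expect_lt(abs((withp$K[3, 3] - base$K[3, 3]) - shift),
            1e-12 * abs(base$K[3, 3]))
  expect_equal(withp$K[-3, -3], base$K[-3, -3])
  # and the oracle sees the same matrices
  expect_equal(galerkin_oracle(grp, md)$K, withp$K, tolerance = 1e-14)

  # constant pressure is rejected for eigenanalysis with a clear message
  grc <- gr
  grc$pressure <- pressure_constant(10)
  expect_error(assemble_mode_matrices(grc, md), "inhomogeneous")
})

test_that("a pencil with no positive eigenvalue reports non-buckling", {
  sp <- mtbuckle:::.smallest_positive(
    mtbuckle:::.pencil_eigen(-diag(2), diag(2)), tol = 1e-12)
  expect_null(sp)
})
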