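# The semi-inverse construction chain and the Euler-Lagrange verification.

test_that("variational derivatives of F reproduce the coupling operators", {
  F <- coupling_density()
  M <- m_operators()
  for (y in c("u", "v", "w")) {
    expect_le_zero(mtbuckle:::le_sub(variational_derivative(F, y)$terms,
                                     M[[y]]$terms))
  }
})

test_that("the Phi construction closes the v- and w-channels", {
  Phi <- phi_density()
  # delta Phi / delta v = k1 w_th - c2 (3 k2 + mu1) w_xxth
  target <- mtbuckle:::le_add(
    mtbuckle:::le_term("w", 0L, 1L, mtbuckle:::pp_mono(1, "k1")),
    mtbuckle:::le_term("w", 2L, 1L, mtbuckle:::pp_add(
      mtbuckle:::pp_mono(-3, c("c2", "k2")), mtbuckle:::pp_mono(-1, c("c2", "mu1")))))
  expect_le_zero(mtbuckle:::le_sub(variational_derivative(Phi, "v")$terms, target))
  # and F = (u-matched part) + Phi exactly
  u_part <- mtbuckle:::qd_scale(phi_density()$terms, -1)
  recomposed <- mtbuckle:::qd_add(coupling_density()$terms, u_part)
  # recomposed now holds only the u-coupled terms; its delta/delta v must be
  # the (k2 + mu1) u_xth membrane term alone
  lhs <- variational_derivative(recomposed, "v")$terms
  rhs <- mtbuckle:::le_term("u", 1L, 1L, mtbuckle:::pp_add(
    mtbuckle:::pp_mono(1, "k2"), mtbuckle:::pp_mono(1, "mu1")))
  expect_le_zero(mtbuckle:::le_sub(lhs, rhs))
})

test_that("coupling density vanishes for axial stretch with uniform inflation", {
  # u = x, v = 0, w = w0: every F term carries a v- or w-derivative except
  # mu1 w_x u, and w_x = 0 for constant w
  fields <- list(u = trig_field(1, p = 1L), v = empty_field(),
                 w = trig_field(0.8))
  params <- mtbuckle:::groups_params(random_groups())
  vals <- mtbuckle:::qd_eval_fields(coupling_density()$terms, fields, params,
                                    x = c(0.2, 1, 3), theta = c(0, 1, 4))
  expect_equal(vals, rep(0, 3))
})

test_that("functional density degenerates correctly in special cases", {
  dens <- functional_density()$terms
  params <- mtbuckle:::groups_params(random_groups())
  x <- seq(0.2, 5, length.out = 7)
  th <- seq(0, 2 * pi, length.out = 7)
  set.seed(21)
  u <- random_smooth_field()

  # v = w = 0: reduces to the V1 integrand alone
  fields_u <- list(u = u, v = empty_field(), w = empty_field())
  v1_only <- mtbuckle:::qd_eval_fields(mtbuckle:::.v1_density(), fields_u,
                                       params, x, th)
  expect_equal(mtbuckle:::qd_eval_fields(dens, fields_u, params, x, th),
               v1_only, tolerance = 1e-14)

  # N = 0, sigma = 0: no load or foundation left, so the density cannot
  # depend on the nonlocal parameter at all
  fields <- random_field_set()
  p0 <- mtbuckle:::groups_params(random_groups(eta = 0, sK = 0))
  p1 <- p0; p1[["eta2"]] <- 0.09
  expect_equal(mtbuckle:::qd_eval_fields(dens, fields, p0, x, th),
               mtbuckle:::qd_eval_fields(dens, fields, p1, x, th),
               tolerance = 1e-14)
})

test_that("Euler-Lagrange equations of the functional recover the governing PDEs", {
  set.seed(101)
  # five random parameter draws; the symbolic check is an exact polynomial
  # identity (parameter-independent), the numeric shadow exercises each draw
  for (i in 1:5) {
    ver <- verify_euler_lagrange(groups = random_groups(), NK = stats::runif(1, 0, 0.5),
                                 n_fields = 2L)
    expect_true(all(ver$symbolic_zero))
    expect_lt(ver$max_rel_numeric, 1e-9)
  }
  # with a prescribed radial pressure field the identity still holds
  ver_p <- verify_euler_lagrange(pressure = "field", n_fields = 3L)
  expect_true(all(ver_p$symbolic_zero))
  expect_lt(ver_p$max_rel_numeric, 1e-9)
})

test_that("a broken coupling coefficient is detected (negative control)", {
  set.seed(5)
  for (term in c("v_x*u_th", "w_x*u", "w_xx*u_x", "w_x*u_thth",
                 "w*v_th", "w_xx*v_th")) {
    ver <- verify_euler_lagrange(n_fields = 1L, drop_coupling = term)
    expect_false(all(ver$symbolic_zero), label = paste("dropping", term))
    expect_gt(ver$max_rel_numeric, 1e-9)
    expect_false(ver$verified)
  }
})

test_that("the governing bilinear form is self-adjoint on admissible fields", {
  # <z, D(y)> = <y, D(z)> for fields in the simply supported periodic
  # family, where all boundary terms vanish
  set.seed(31)
  gr <- random_groups()
  params <- mtbuckle:::groups_params(gr, NK = 0.2)
  ops <- governing_operators()
  gl <- mtbuckle:::.gauss_legendre(16, 0, gr$l)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  grid <- expand.grid(x = gl$x, th = th)
  wts <- rep(gl$w, times = 32) * (2 * pi / 32)
  pairing <- function(flds, tests) {
    tot <- 0
    for (nm in c("u", "v", "w")) {
      dv <- field_eval(mtbuckle:::le_apply_fields(ops[[nm]]$terms, flds, params),
                       grid$x, grid$th)
      tv <- field_eval(tests[[nm]], grid$x, grid$th)
      tot <- tot + sum(dv * tv * wts)
    }
    tot
  }
  for (rep in 1:3) {
    md1 <- trial_mode(sample(1:4, 1), sample(0:4, 1), gr$l)
    md2 <- trial_mode(sample(1:4, 1), sample(0:4, 1), gr$l)
    y <- ss_ansatz_fields(md1, amps = stats::runif(3, -1, 1))
    z <- ss_ansatz_fields(md2, amps = stats::runif(3, -1, 1))
    byz <- pairing(y, z)
    bzy <- pairing(z, y)
    expect_equal(byz, bzy, tolerance = 1e-9)
  }
})

test_that("governing residuals vanish for the trivial solution and reduce correctly", {
  gr <- random_groups()
  z <- empty_field()
  res0 <- governing_residuals(list(u = z, v = z, w = z), gr, N = 0.1 * gr$K)
  for (r in res0) expect_equal(nrow(r), 0L)

  # pure axial field: D1 reduces to u_xx + (N/K)(eta^2 u_xxxx - u_xx)
  u <- trig_field(c(1, -0.3), p = c(2L, 4L))
  res <- governing_residuals(list(u = u, v = z, w = z), gr, N = 0.25 * gr$K)
  x <- c(0.4, 1.3, 2.2)
  NK <- 0.25
  uxx <- field_eval(field_deriv(u, dx = 2), x, 0)
  uxxxx <- field_eval(field_deriv(u, dx = 4), x, 0)
  expect_equal(field_eval(res$u, x, 0),
               uxx + NK * (gr$eta^2 * uxxxx - uxx), tolerance = 1e-12)
  expect_equal(nrow(res$v), 0L)  # no coupling into v from u(x) alone
})
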