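# The exact jet algebra: Euler-Lagrange template, linearity, and agreement
# of the closed-form field derivatives with finite differences.

jk <- mtbuckle:::jet_key
qd1 <- mtbuckle:::qd_term
pm <- mtbuckle:::pp_mono

test_that("variational derivative reproduces textbook Euler-Lagrange terms", {
  # density (1/2) a y_x^2  ->  -a y_xx
  d1 <- qd1(jk("u", 1L, 0L), jk("u", 1L, 0L), pm(0.5, "a"))
  r1 <- variational_derivative(d1, "u")$terms
  expect_le_zero(mtbuckle:::le_sub(r1, mtbuckle:::le_term("u", 2L, 0L, pm(-1, "a"))))

  # density (1/2) a y_xx^2  ->  +a y_xxxx (fourth-order beam term)
  d2 <- qd1(jk("u", 2L, 0L), jk("u", 2L, 0L), pm(0.5, "a"))
  r2 <- variational_derivative(d2, "u")$terms
  expect_le_zero(mtbuckle:::le_sub(r2, mtbuckle:::le_term("u", 4L, 0L, pm(1, "a"))))

  # mixed term (1/2) a y_xth^2 -> +a y_xxthth (even order, plus sign)
  d3 <- qd1(jk("u", 1L, 1L), jk("u", 1L, 1L), pm(0.5, "a"))
  r3 <- variational_derivative(d3, "u")$terms
  expect_le_zero(mtbuckle:::le_sub(r3, mtbuckle:::le_term("u", 2L, 2L, pm(1, "a"))))
})

test_that("variational derivative is linear in the density", {
  set.seed(7)
  rand_density <- function() {
    qd <- mtbuckle:::qd_zero()
    for (i in 1:5) {
      j1 <- jk(sample(c("u", "v", "w"), 1), sample(0:2, 1), sample(0:2, 1))
      j2 <- jk(sample(c("u", "v", "w"), 1), sample(0:2, 1), sample(0:2, 1))
      qd <- mtbuckle:::qd_add(qd, qd1(j1, j2, mtbuckle:::pp_num(stats::runif(1, -2, 2))))
    }
    qd
  }
  for (rep in 1:5) {
    a <- rand_density()
    b <- rand_density()
    ab <- mtbuckle:::qd_add(a, b)
    for (y in c("u", "v", "w")) {
      lhs <- variational_derivative(ab, y)$terms
      rhs <- mtbuckle:::le_add(variational_derivative(a, y)$terms,
                               variational_derivative(b, y)$terms)
      expect_le_zero(mtbuckle:::le_sub(lhs, rhs))
    }
  }
})

test_that("parameter polynomial arithmetic is exact", {
  a <- mtbuckle:::pp_add(pm(0.5, c("k2", "c2")), pm(1, "mu1"))
  b <- mtbuckle:::pp_add(pm(-0.5, c("c2", "k2")), pm(-1, "mu1"))
  expect_true(mtbuckle:::pp_is_zero(mtbuckle:::pp_add(a, b)))
  prod <- mtbuckle:::pp_mul(pm(2, "k2"), pm(3, c("k2", "c2")))
  expect_equal(mtbuckle:::pp_eval(prod, c(k2 = 0.5, c2 = 0.1)), 6 * 0.25 * 0.1)
  sp <- mtbuckle:::pp_split(mtbuckle:::pp_add(pm(1, "k1"), pm(2, c("NK", "eta2"))), "NK")
  expect_equal(mtbuckle:::pp_eval(sp$free, c(k1 = 3)), 3)
  expect_equal(mtbuckle:::pp_eval(sp$lin, c(eta2 = 0.25)), 0.5)
  expect_error(mtbuckle:::pp_split(mtbuckle:::pp_mul(pm(1, "NK"), pm(1, "NK")), "NK"),
               "degree")
})

test_that("field derivatives match finite differences", {
  set.seed(11)
  f <- random_smooth_field()
  h <- 1e-5
  x <- c(0.3, 1.7, 2.9)
  th <- c(0.5, 2.1, 5.0)
  fx_num <- (field_eval(f, x + h, th) - field_eval(f, x - h, th)) / (2 * h)
  expect_equal(field_eval(field_deriv(f, dx = 1), x, th), fx_num, tolerance = 1e-6)
  fth_num <- (field_eval(f, x, th + h) - field_eval(f, x, th - h)) / (2 * h)
  expect_equal(field_eval(field_deriv(f, dth = 1), x, th), fth_num, tolerance = 1e-6)
  # trigonometric x-part too (the ansatz family)
  g <- trig_field(1.3, lam = 0.8, fx = "sin", n = 2, fth = "cos")
  gx_num <- (field_eval(g, x + h, th) - field_eval(g, x - h, th)) / (2 * h)
  expect_equal(field_eval(field_deriv(g, dx = 1), x, th), gx_num, tolerance = 1e-6)
})

test_that("the nonlocal operator L acts as eta^2 Laplacian minus identity", {
  # constant field: derivatives vanish, L(c) = -c
  cst <- trig_field(2.5)
  expect_equal(field_eval(apply_nonlocal_L(cst, 0.3), 1.1, 0.7), -2.5)
  # eta = 0: L(f) = -f for any field
  set.seed(3)
  f <- random_smooth_field()
  x <- seq(0.1, 3, length.out = 5)
  th <- seq(0, 2 * pi, length.out = 5)
  expect_equal(field_eval(apply_nonlocal_L(f, 0), x, th),
               -field_eval(f, x, th), tolerance = 1e-14)
  # single harmonic: multiplication by -(1 + eta^2 (lam^2 + n^2))
  lam <- 0.9; n <- 2; eta <- 0.2
  hmn <- trig_field(1, lam = lam, fx = "cos", n = n, fth = "cos")
  expect_equal(field_eval(apply_nonlocal_L(hmn, eta), x, th),
               -(1 + eta^2 * (lam^2 + n^2)) * field_eval(hmn, x, th),
               tolerance = 1e-14)
})
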