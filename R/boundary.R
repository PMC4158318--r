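# Natural and geometric boundary conditions at the shell ends x = 0 and
# x = l, and the boundary terms of the first variation.
#
# Integrating the first variation of the trial functional by parts (using
# 2*pi-periodicity in theta, so only x-boundary terms survive) leaves edge
# integrals pairing five boundary expressions with the variations
# (du, du_x, dv, dv_x, dw, dw_x).  Setting each coefficient to zero, or
# prescribing the conjugate displacement quantity, yields six
# natural-or-geometric alternatives per edge.  With eta > 0 the natural
# expressions in the u and w channels carry load-dependent terms
# NK * eta^2 * (...): the nonlocal formulation couples the boundary
# conditions to the load.

# The six natural-condition expressions (left-hand sides, "= 0"), as linear
# differential expressions, paired with their geometric alternatives.
# The w-shear expression (fifth alternative) is assembled in one place so a
# transcription correction is a one-line change.
.bc_w_shear <- function() {
  Reduce(le_add, list(
    le_term("w", 3L, 0L, .pps(.pm(1, "c2"), .pm(-1, c("NK", "eta2")))),
    le_term("w", 1L, 2L, .pps(.pm(4, c("c2", "k2")), .pm(2, c("c2", "mu1")),
                              .pm(-1, c("NK", "eta2")))),
    le_term("w", 1L, 0L, .pps(.pm(-1, c("sK", "eta2")), .pm(1, "NK"))),
    le_term("u", 0L, 0L, .pm(1, "mu1")),
    le_term("u", 0L, 2L, .pm(1, c("c2", "k2"))),
    le_term("u", 2L, 0L, .pm(-1, "c2")),
    le_term("v", 1L, 1L, .pps(.pm(-3, c("c2", "k2")), .pm(-1, c("c2", "mu1"))))))
}

#' Boundary-condition expressions of the variational formulation
#'
#' Returns the six conjugate pairs of end conditions: for each pair, the
#' natural (force-like) expression whose vanishing is demanded when the
#' conjugate displacement quantity is left free, and the geometric
#' alternative.  Pairs, in order: axial force vs `u`; `u_xx` vs `u_x`;
#' circumferential force vs `v`; `v_xx` vs `v_x`; effective radial shear vs
#' `w`; bending moment vs `w_x`.
#'
#' @return a named list of pairs; each pair holds `natural` (an
#'   `mt_operator`) and `geometric` (the jet of the prescribed quantity).
#' @export
bc_expressions <- function() {
  nat_u <- Reduce(le_add, list(
    le_term("u", 1L, 0L, .pps(pp_num(1), .pm(-1, "NK"))),
    le_term("u", 3L, 0L, .pm(1, c("NK", "eta2"))),
    le_term("u", 1L, 2L, .pm(1, c("NK", "eta2"))),
    le_term("w", 2L, 0L, .pm(-1, "c2"))))
  # The circumferential force condition carries no radial-deflection term:
  # the coupling-density term c2*(3*k2+mu1)*w_xx*v_th reaches delta_v only
  # through a theta integration by parts, which leaves no axial boundary
  # trace, so the first variation pairs delta_v with membrane and load
  # terms alone (cf. the first-variation edge integrals; the numeric
  # balance identity in boundary_term_balance() pins this down).
  nat_v <- Reduce(le_add, list(
    le_term("u", 0L, 1L, .pps(.pm(1, "k2"), .pm(1, "mu1"))),
    le_term("v", 1L, 0L, .pps(.pm(1, "k2"), .pm(3, c("k2", "c2")), .pm(-1, "NK"))),
    le_term("v", 3L, 0L, .pm(1, c("NK", "eta2"))),
    le_term("v", 1L, 2L, .pm(1, c("NK", "eta2")))))
  nat_wx <- Reduce(le_add, list(
    le_term("w", 2L, 0L, .pps(.pm(-1, "c2"), .pm(1, c("NK", "eta2")))),
    le_term("v", 0L, 1L, .pps(.pm(3, c("c2", "k2")), .pm(1, c("c2", "mu1")))),
    le_term("u", 1L, 0L, .pm(1, "c2"))))
  op <- function(le) structure(list(terms = le), class = "mt_operator")
  list(
    u_force = list(natural = op(nat_u), geometric = "u"),
    u_curvature = list(natural = op(le_term("u", 2L, 0L, pp_num(1))),
                       geometric = "u_x"),
    v_force = list(natural = op(nat_v), geometric = "v"),
    v_curvature = list(natural = op(le_term("v", 2L, 0L, pp_num(1))),
                       geometric = "v_x"),
    w_shear = list(natural = op(.bc_w_shear()), geometric = "w"),
    w_moment = list(natural = op(nat_wx), geometric = "w_x")
  )
}

#' Edge condition set
#'
#' Marks, for one edge, which member of each of the six conjugate pairs is
#' enforced.  Exactly one member per pair.
#'
#' @param edge `"x0"` or `"xl"`.
#' @param enforced character vector of length 6 over
#'   `c("natural", "geometric")`, in the pair order of [bc_expressions()].
#'   The default is the simply supported pattern of the Ritz family:
#'   natural axial force, geometric `u_x`... i.e.
#'   `c("natural", "geometric", "geometric", "natural", "geometric", "natural")`.
#' @return an object of class `mt_edge_set`.
#' @export
edge_condition_set <- function(edge = c("x0", "xl"),
                               enforced = c("natural", "geometric", "geometric",
                                            "natural", "geometric", "natural")) {
  edge <- match.arg(edge)
  enforced <- match.arg(enforced, c("natural", "geometric"), several.ok = TRUE)
  if (length(enforced) != 6L) stop("exactly one member of each of the 6 pairs")
  names(enforced) <- names(bc_expressions())
  structure(list(edge = edge, enforced = enforced), class = "mt_edge_set")
}

.edge_x <- function(edge, l) if (edge == "x0") 0 else l

# geometric quantities as jets
.geo_jets <- c(u = "u.0.0", u_x = "u.1.0", v = "v.0.0", v_x = "v.1.0",
               w = "w.0.0", w_x = "w.1.0")

#' Boundary-condition residuals at one edge
#'
#' Evaluates, at the requested edge, the expressions of all six conjugate
#' pairs on the given displacement fields: the natural expressions of
#' [bc_expressions()] and the geometric quantities.  Each residual is
#' reported pointwise on a sampled theta grid and theta-integrated (root
#' mean square over the circumference, the weak measure used for
#' acceptance, since the underlying statement is an edge integral).  The
#' "satisfied" tolerance is scale-free: `1e-9` times the largest magnitude
#' of any single term in the expression.
#'
#' @param fields named list of [trig_field()]s `u`, `v`, `w`.
#' @param groups an `mt_groups` object.
#' @param N axial load (same units as `K`, N/m).
#' @param edge_set an [edge_condition_set()] (or an edge name).
#' @param n_theta number of theta sample points.
#' @return an object of class `mt_bc_report`: per-pair list with `kind`
#'   (which member is enforced), `weak` (RMS residual), `pointwise_max`,
#'   `scale`, and `satisfied`; plus a `max_rel` summary over the enforced
#'   conditions.
#' @export
natural_bc_residuals <- function(fields, groups, N = 0, edge_set = "x0",
                                 n_theta = 64L) {
  stopifnot(inherits(groups, "mt_groups"))
  if (!inherits(edge_set, "mt_edge_set")) edge_set <- edge_condition_set(edge_set)
  params <- groups_params(groups, NK = N / groups$K)
  xe <- .edge_x(edge_set$edge, groups$l)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  pairs <- bc_expressions()
  out <- list()
  for (nm in names(pairs)) {
    kind <- edge_set$enforced[[nm]]
    # the scale reference samples interior sections too, so an expression
    # whose every term vanishes at the edge (e.g. the ansatz natural
    # conditions, all proportional to sin(m*pi)) is judged against the
    # term magnitudes the mode actually carries
    xs <- c(xe, groups$l * c(0.25, 0.5, 0.75))
    if (kind == "natural") {
      le <- pairs[[nm]]$natural$terms
      vals <- field_eval(le_apply_fields(le, fields, params), xe, th)
      scale <- 0
      for (k in names(le)) {
        j <- .jet_parse(k)
        df <- field_deriv(fields[[j$f]], j$a, j$b)
        for (xr in xs) {
          tv <- pp_eval(le[[k]], params) * field_eval(df, xr, th)
          scale <- max(scale, abs(tv))
        }
      }
    } else {
      j <- .jet_parse(.geo_jets[[pairs[[nm]]$geometric]])
      vals <- field_eval(field_deriv(fields[[j$f]], j$a, j$b), xe, th)
      scale <- max(abs(field_eval(fields[[j$f]], rep(xs, each = length(th)),
                                  rep(th, times = length(xs)))), 1)
    }
    weak <- sqrt(mean(vals^2))
    out[[nm]] <- list(kind = kind, weak = weak, pointwise_max = max(abs(vals), 0),
                      scale = scale,
                      satisfied = weak <= 1e-9 * max(scale, 1e-300))
  }
  rel <- vapply(out, function(p) p$weak / max(p$scale, 1e-300), numeric(1))
  structure(list(edge = edge_set$edge, pairs = out, max_rel = max(rel)),
            class = "mt_bc_report")
}

#' @export
print.mt_bc_report <- function(x, ...) {
  cat(sprintf("Boundary residuals at edge %s\n", x$edge))
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    cat(sprintf("  %-12s [%-9s] weak %.3e  pointwise %.3e  scale %.3e  %s\n",
                nm, p$kind, p$weak, p$pointwise_max, p$scale,
                if (p$satisfied) "ok" else "VIOLATED"))
  }
  invisible(x)
}

#' Check circumferential periodicity of fields
#'
#' Verifies that `u`, `v`, `w` agree at `theta = 0` and `theta = 2*pi` for
#' sampled `x` in `[0, l]`.
#'
#' @param fields named list of [trig_field()]s.
#' @param l dimensionless length (or an `mt_groups`).
#' @param n_x number of axial sample points.
#' @param tol absolute tolerance relative to the field magnitude.
#' @return a named logical vector (one entry per field) with attribute
#'   `"max_gap"` holding the worst mismatch.
#' @export
check_periodicity <- function(fields, l = 2 * pi, n_x = 9L, tol = 1e-9) {
  if (inherits(l, "mt_groups")) l <- l$l
  xg <- seq(0, l, length.out = n_x)
  # compare theta against theta + 2*pi around the whole circumference, so a
  # half-integer harmonic (zero at both endpoints but not periodic) is caught
  thg <- seq(0, 2 * pi, length.out = 8L)[-8L]
  pts <- expand.grid(x = xg, th = thg)
  ok <- logical(length(fields))
  names(ok) <- names(fields)
  gap <- 0
  for (nm in names(fields)) {
    v0 <- field_eval(fields[[nm]], pts$x, pts$th)
    v1 <- field_eval(fields[[nm]], pts$x, pts$th + 2 * pi)
    scale <- max(abs(v0), abs(v1), 1)
    g <- max(abs(v0 - v1)) / scale
    gap <- max(gap, g)
    ok[nm] <- g <= tol
  }
  attr(ok, "max_gap") <- gap
  ok
}

## ---- quadrature and the weak-form balance ---------------------------------

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch); the integrands met
# here are polynomial-times-trigonometric with modest polynomial degree, so
# a small rule is exact to machine precision.
.gauss_legendre <- function(n, a = 0, b = 1) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (b - a) / 2 * e$values + (a + b) / 2, w = (b - a) / 2 * 2 * e$vectors[1L, ]^2)
}

# integral over [0, l] x [0, 2*pi) of a quadratic density on concrete fields
.integrate_density <- function(qd, fields, params, l, nx = 12L, nth = 32L) {
  gl <- .gauss_legendre(nx, 0, l)
  th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  grid <- expand.grid(x = gl$x, th = th)
  vals <- qd_eval_fields(qd, fields, params, grid$x, grid$th)
  wts <- rep(gl$w, times = nth) * (2 * pi / nth)
  sum(vals * wts)
}

#' Weak-form boundary-term balance
#'
#' The integration-by-parts identity behind the boundary conditions: for
#' any smooth 2*pi-periodic fields and variations,
#' `delta V = integral of (D1 du + D2 dv + D3 dw) + sum of the edge terms
#' b1..b5` evaluated at `x = l` minus `x = 0`.  The left side is the exact
#' Gateaux derivative of the quadrature of the functional density; the
#' right side combines the governing residual fields with the boundary
#' pairings of [bc_expressions()].  Agreement on random fields validates
#' the whole chain of transcriptions (functional, operators, edge terms)
#' at once.
#'
#' @param fields,variations named lists of [trig_field()]s `u`, `v`, `w`
#'   (plus `P` when `pressure = "field"`).
#' @param groups an `mt_groups` object.
#' @param N axial load (N/m).
#' @param pressure `"zero"` or `"field"`.
#' @return a list with `delta_V`, `interior`, `boundary`, and the relative
#'   imbalance `rel_err`.
#' @export
boundary_term_balance <- function(fields, variations, groups, N = 0,
                                  pressure = c("zero", "field")) {
  pressure <- match.arg(pressure)
  stopifnot(inherits(groups, "mt_groups"))
  NK <- N / groups$K
  params <- groups_params(groups, NK = NK)
  l <- groups$l
  dens <- functional_density(pressure)$terms

  # Gateaux derivative of the quadratic functional: exact central difference
  plus <- fields
  minus <- fields
  for (nm in c("u", "v", "w")) {
    plus[[nm]] <- .field_join(fields[[nm]], variations[[nm]])
    minus[[nm]] <- .field_join(fields[[nm]], field_scale(variations[[nm]], -1))
  }
  delta_V <- (.integrate_density(dens, plus, params, l) -
                .integrate_density(dens, minus, params, l)) / 2

  # interior part: governing residual fields paired with the variations
  ops <- governing_operators(pressure)
  gl <- .gauss_legendre(12L, 0, l)
  th <- seq(0, 2 * pi, length.out = 33L)[-33L]
  grid <- expand.grid(x = gl$x, th = th)
  wts <- rep(gl$w, times = 32L) * (2 * pi / 32)
  interior <- 0
  for (nm in c("u", "v", "w")) {
    dvals <- field_eval(le_apply_fields(ops[[nm]]$terms, fields, params),
                        grid$x, grid$th)
    vvals <- field_eval(variations[[nm]], grid$x, grid$th)
    interior <- interior + sum(dvals * vvals * wts)
  }

  # edge terms b1..b5: coefficient expressions paired with the variations
  pairs <- bc_expressions()
  terms <- list(
    list(coef = le_scale(pairs$u_force$natural$terms, -1), var = "u", d = 0L),
    list(coef = le_term("u", 2L, 0L, .pm(1, c("NK", "eta2"))), var = "u", d = 1L),
    list(coef = le_scale(pairs$v_force$natural$terms, -1), var = "v", d = 0L),
    list(coef = le_term("v", 2L, 0L, .pm(1, c("NK", "eta2"))), var = "v", d = 1L),
    list(coef = pairs$w_shear$natural$terms, var = "w", d = 0L),
    list(coef = pairs$w_moment$natural$terms, var = "w", d = 1L))
  boundary <- 0
  for (tm in terms) {
    cf <- le_apply_fields(tm$coef, fields, params)
    vf <- field_deriv(variations[[tm$var]], dx = tm$d)
    for (edge in c(1, -1)) {
      xe <- if (edge == 1) l else 0
      boundary <- boundary +
        edge * sum(field_eval(cf, xe, th) * field_eval(vf, xe, th)) * (2 * pi / 32)
    }
  }

  scale <- max(abs(delta_V), abs(interior), abs(boundary), 1e-300)
  list(delta_V = delta_V, interior = interior, boundary = boundary,
       rel_err = abs(delta_V - (interior + boundary)) / scale)
}
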