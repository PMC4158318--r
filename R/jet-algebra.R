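# Exact jet-space algebra underlying the symbolic verification engine.
#
# The governing operators of the shell model are linear, and the trial
# functional is quadratic, in the displacement fields and their partial
# derivatives.  Everything symbolic in this package is therefore represented
# over "jet variables" y_{(a,b)} = d^{a+b} y / dx^a dtheta^b for
# y in {u, v, w, P}:
#
#   * a parameter polynomial ("pp") is a sparse multivariate polynomial in
#     the dimensionless groups (k1, k2, c2, mu1, eta2 = eta^2, NK = N/K,
#     sK = sigma*R/K, RK = R/K, pK = R*kappa_p/K) with numeric coefficients;
#   * a linear expression ("linexpr") maps jet variables to parameter
#     polynomials (a linear differential operator applied to the fields);
#   * a quadratic density ("qdensity") maps unordered pairs of jet variables
#     to parameter polynomials (the integrand of a functional).
#
# All structural coefficients arising from the shell equations are dyadic
# rationals (integers and halves), so double arithmetic is exact and a
# vanishing residual cancels to a polynomial with no terms at all --
# "symbolic zero" here means an exact polynomial identity valid for every
# admissible parameter value, not a numeric tolerance.

## ---- parameter polynomials ------------------------------------------------

.mono_parse <- function(key) {
  if (key == "1") return(integer(0))
  parts <- strsplit(key, "*", fixed = TRUE)[[1L]]
  vars <- character(length(parts))
  exps <- integer(length(parts))
  for (i in seq_along(parts)) {
    bits <- strsplit(parts[i], "^", fixed = TRUE)[[1L]]
    vars[i] <- bits[1L]
    exps[i] <- if (length(bits) > 1L) as.integer(bits[2L]) else 1L
  }
  stats::setNames(exps, vars)
}

.mono_key <- function(ex) {
  ex <- ex[ex != 0L]
  if (!length(ex)) return("1")
  ex <- ex[order(names(ex))]
  paste(ifelse(ex == 1L, names(ex), paste0(names(ex), "^", ex)), collapse = "*")
}

.mono_mul <- function(k1, k2) {
  ea <- .mono_parse(k1)
  eb <- .mono_parse(k2)
  vars <- union(names(ea), names(eb))
  ex <- stats::setNames(integer(length(vars)), vars)
  ex[names(ea)] <- ea
  ex[names(eb)] <- ex[names(eb)] + eb
  .mono_key(ex)
}

pp_zero <- function() numeric(0)

pp_num <- function(x) if (x == 0) pp_zero() else c("1" = x)

# coef * prod(vars); `vars` is a character vector with repetitions,
# e.g. pp_mono(-2, c("c2", "k2")) is -2*c2*k2.
pp_mono <- function(coef, vars = character(0)) {
  if (coef == 0) return(pp_zero())
  if (!length(vars)) return(c("1" = coef))
  tab <- table(vars)
  key <- .mono_key(stats::setNames(as.integer(tab), names(tab)))
  stats::setNames(coef, key)
}

pp_add <- function(a, b) {
  keys <- union(names(a), names(b))
  r <- stats::setNames(numeric(length(keys)), keys)
  r[names(a)] <- a
  r[names(b)] <- r[names(b)] + b
  r[r != 0]
}

pp_scale <- function(a, s) {
  if (s == 0) return(pp_zero())
  a * s
}

pp_mul <- function(a, b) {
  if (!length(a) || !length(b)) return(pp_zero())
  r <- pp_zero()
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      r <- pp_add(r, stats::setNames(a[[i]] * b[[j]],
                                     .mono_mul(names(a)[i], names(b)[j])))
    }
  }
  r
}

pp_is_zero <- function(a) length(a) == 0L

pp_eval <- function(a, vals) {
  if (!length(a)) return(0)
  tot <- 0
  for (i in seq_along(a)) {
    ex <- .mono_parse(names(a)[i])
    term <- a[[i]]
    if (length(ex)) {
      miss <- setdiff(names(ex), names(vals))
      if (length(miss)) {
        stop("no value supplied for parameter(s): ", paste(miss, collapse = ", "))
      }
      term <- term * prod(vals[names(ex)]^ex)
    }
    tot <- tot + term
  }
  tot
}

# Split a polynomial that is at most linear in `var` into the part free of
# `var` and the coefficient of `var` (with `var` removed).  Used to separate
# the load-proportional part of an operator from its stiffness part.
pp_split <- function(a, var) {
  free <- pp_zero()
  lin <- pp_zero()
  for (i in seq_along(a)) {
    ex <- .mono_parse(names(a)[i])
    d <- if (var %in% names(ex)) ex[[var]] else 0L
    if (d == 0L) {
      free <- pp_add(free, a[i])
    } else if (d == 1L) {
      ex[var] <- 0L
      lin <- pp_add(lin, stats::setNames(a[[i]], .mono_key(ex)))
    } else {
      stop("polynomial has degree > 1 in '", var, "'")
    }
  }
  list(free = free, lin = lin)
}

.pp_format <- function(a) {
  if (!length(a)) return("0")
  paste(vapply(seq_along(a), function(i) {
    key <- names(a)[i]
    co <- a[[i]]
    if (key == "1") format(co) else if (co == 1) key
    else if (co == -1) paste0("-", key) else paste0(format(co), "*", key)
  }, character(1)), collapse = " + ")
}

## ---- jet variables and linear expressions ---------------------------------

jet_key <- function(f, a, b) paste(f, a, b, sep = ".")

.jet_parse <- function(key) {
  p <- strsplit(key, ".", fixed = TRUE)[[1L]]
  list(f = p[1L], a = as.integer(p[2L]), b = as.integer(p[3L]))
}

.jet_label <- function(key) {
  j <- .jet_parse(key)
  if (j$a + j$b == 0L) return(j$f)
  paste0(j$f, "_", strrep("x", j$a), strrep("th", j$b))
}

le_zero <- function() list()

le_term <- function(f, a, b, pp) {
  if (pp_is_zero(pp)) return(le_zero())
  stats::setNames(list(pp), jet_key(f, a, b))
}

le_add <- function(a, b) {
  for (k in names(b)) {
    a[[k]] <- if (is.null(a[[k]])) b[[k]] else pp_add(a[[k]], b[[k]])
    if (pp_is_zero(a[[k]])) a[[k]] <- NULL
  }
  a
}

le_scale <- function(le, s) {
  # s: a number or a parameter polynomial
  pp <- if (is.numeric(s) && is.null(names(s))) pp_num(s) else s
  out <- le_zero()
  for (k in names(le)) {
    r <- pp_mul(le[[k]], pp)
    if (!pp_is_zero(r)) out[[k]] <- r
  }
  out
}

le_sub <- function(a, b) le_add(a, le_scale(b, -1))

# Total derivative d^dx/dx^dx d^dth/dtheta^dth of a linear expression.  The
# coefficients are parameter polynomials, constant in (x, theta), so the
# derivative just shifts every jet variable.
le_deriv <- function(le, dx = 0L, dth = 0L) {
  if (!length(le)) return(le)
  out <- le_zero()
  for (k in names(le)) {
    j <- .jet_parse(k)
    out[[jet_key(j$f, j$a + dx, j$b + dth)]] <- le[[k]]
  }
  out
}

le_is_zero <- function(le) length(le) == 0L

le_max_order <- function(le) {
  if (!length(le)) return(0L)
  max(vapply(names(le), function(k) {
    j <- .jet_parse(k)
    j$a + j$b
  }, integer(1)))
}

.le_format <- function(le) {
  if (!length(le)) return("0")
  keys <- names(le)[order(names(le))]
  paste(vapply(keys, function(k) {
    paste0("(", .pp_format(le[[k]]), ")*", .jet_label(k))
  }, character(1)), collapse = " + ")
}

## ---- quadratic densities --------------------------------------------------

pair_key <- function(j1, j2) paste(sort(c(j1, j2)), collapse = " ")

qd_zero <- function() list()

# Adds coef * J1 * J2 to the density (the full coefficient of the product;
# a diagonal pair qd_term(j, j, c) means c * j^2).
qd_term <- function(j1, j2, pp) {
  if (pp_is_zero(pp)) return(qd_zero())
  stats::setNames(list(pp), pair_key(j1, j2))
}

qd_add <- function(a, b) {
  for (k in names(b)) {
    a[[k]] <- if (is.null(a[[k]])) b[[k]] else pp_add(a[[k]], b[[k]])
    if (pp_is_zero(a[[k]])) a[[k]] <- NULL
  }
  a
}

qd_scale <- function(qd, s) {
  pp <- if (is.numeric(s) && is.null(names(s))) pp_num(s) else s
  out <- qd_zero()
  for (k in names(qd)) {
    r <- pp_mul(qd[[k]], pp)
    if (!pp_is_zero(r)) out[[k]] <- r
  }
  out
}

# Partial derivative of the density with respect to one jet variable:
# d/dJ (c * J1 * J2) = c*J2 [J1 == J] + c*J1 [J2 == J]  (so 2c*J on the
# diagonal), yielding a linear expression.
qd_partial <- function(qd, jet) {
  out <- le_zero()
  for (k in names(qd)) {
    js <- strsplit(k, " ", fixed = TRUE)[[1L]]
    if (js[1L] == jet) {
      j <- .jet_parse(js[2L])
      out <- le_add(out, le_term(j$f, j$a, j$b, qd[[k]]))
    }
    if (js[2L] == jet) {
      j <- .jet_parse(js[1L])
      out <- le_add(out, le_term(j$f, j$a, j$b, qd[[k]]))
    }
  }
  out
}

qd_jets_of <- function(qd, field) {
  jets <- unique(unlist(strsplit(names(qd), " ", fixed = TRUE), use.names = FALSE))
  if (is.null(jets)) return(character(0))
  jets[vapply(jets, function(k) .jet_parse(k)$f == field, logical(1))]
}

# Substitute a numeric value for one parameter throughout a density (e.g.
# NK = 0 to strip the load terms).
qd_sub_param <- function(qd, var, value) {
  out <- qd_zero()
  for (k in names(qd)) {
    sp <- pp_split(qd[[k]], var)
    r <- pp_add(sp$free, pp_scale(sp$lin, value))
    if (!pp_is_zero(r)) out[[k]] <- r
  }
  out
}

# Extract the coefficient density of one parameter (degree <= 1 assumed),
# e.g. the geometric (load) part of the total functional density.
qd_coeff_of <- function(qd, var) {
  out <- qd_zero()
  for (k in names(qd)) {
    sp <- pp_split(qd[[k]], var)
    if (!pp_is_zero(sp$lin)) out[[k]] <- sp$lin
  }
  out
}

## ---- Euler-Lagrange / variational derivative ------------------------------

#' Variational derivative of a quadratic functional density
#'
#' Applies the higher-order Euler-Lagrange template to a functional density
#' \eqn{F(y, y_x, y_\theta, y_{xx}, \dots)}: the variational derivative with
#' respect to a field \eqn{y} is
#' \deqn{\frac{\delta F}{\delta y} = \sum_{(a,b)} (-1)^{a+b}
#'       \frac{\partial^{a+b}}{\partial x^a \partial \theta^b}
#'       \frac{\partial F}{\partial y_{(a,b)}},}
#' one term per derivative order actually present in the density, with the
#' sign alternating by the parity of the total derivative order.  The
#' template extends to arbitrary finite order, so no truncation can occur;
#' densities are stored exactly, and the result is a linear differential
#' operator with exact polynomial coefficients in the dimensionless groups.
#'
#' @param density a functional density as returned by
#'   [functional_density()], [coupling_density()] or [phi_density()].
#' @param target which field to vary: `"u"`, `"v"` or `"w"`.
#' @return an object of class `mt_operator`: the linear differential
#'   operator \eqn{\delta F/\delta y} acting on the fields.
#' @examples
#' # delta/delta v of the coupling density F recovers the M2 operator terms
#' variational_derivative(coupling_density(), "v")
#' @export
variational_derivative <- function(density, target = c("u", "v", "w")) {
  target <- match.arg(target)
  qd <- if (inherits(density, "mt_density")) density$terms else density
  out <- le_zero()
  for (J in qd_jets_of(qd, target)) {
    j <- .jet_parse(J)
    part <- qd_partial(qd, J)
    sgn <- if ((j$a + j$b) %% 2L == 0L) 1 else -1
    out <- le_add(out, le_scale(le_deriv(part, j$a, j$b), sgn))
  }
  structure(list(terms = out), class = "mt_operator")
}

#' @export
print.mt_operator <- function(x, ...) {
  cat(.le_format(x$terms), "\n")
  invisible(x)
}

#' @export
print.mt_density <- function(x, ...) {
  qd <- x$terms
  if (!is.null(x$label)) cat(x$label, "\n")
  if (!length(qd)) {
    cat("0\n")
    return(invisible(x))
  }
  for (k in names(qd)[order(names(qd))]) {
    js <- strsplit(k, " ", fixed = TRUE)[[1L]]
    cat(sprintf("  (%s) * %s * %s\n", .pp_format(qd[[k]]),
                .jet_label(js[1L]), .jet_label(js[2L])))
  }
  invisible(x)
}
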