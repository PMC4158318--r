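# Concrete displacement fields for numeric checks.
#
# Fields are finite sums of separable terms
#     coef * x^p * {1, cos(lam*x), sin(lam*x)} * {cos(n*theta), sin(n*theta)}
# which are closed under partial differentiation, so every jet derivative
# appearing in the operators and densities is available in closed form.
# These cover both the simply supported Ritz ansatz (pure trigonometric in
# x) and the random polynomial-times-Fourier test fields used by the
# numeric shadow of the symbolic verification.

#' Build a separable trial field
#'
#' @param coef numeric vector of term coefficients.
#' @param p integer vector of powers of the axial coordinate `x`.
#' @param lam axial wavenumbers (used when `fx` is `"cos"` or `"sin"`).
#' @param fx axial trigonometric part per term: `"one"`, `"cos"` or `"sin"`.
#' @param n circumferential wavenumbers (integer for 2*pi-periodic fields).
#' @param fth circumferential part per term: `"cos"` or `"sin"`.
#' @return an object of class `mt_field`, a term table.
#' @examples
#' w <- trig_field(1, lam = pi / 10, fx = "sin", n = 2, fth = "cos")
#' field_eval(w, x = 5, theta = 0)
#' @export
trig_field <- function(coef, p = 0L, lam = 0, fx = "one", n = 0, fth = "cos") {
  d <- data.frame(coef = coef, p = as.integer(p), lam = lam, fx = fx,
                  n = n, fth = fth, stringsAsFactors = FALSE)
  stopifnot(all(d$fx %in% c("one", "cos", "sin")),
            all(d$fth %in% c("cos", "sin")),
            all(d$p >= 0L))
  d <- d[d$coef != 0, , drop = FALSE]
  structure(d, class = c("mt_field", "data.frame"))
}

field_zero <- function() {
  trig_field(numeric(0), p = integer(0), lam = numeric(0), fx = character(0),
             n = numeric(0), fth = character(0))
}

.field_join <- function(...) {
  d <- do.call(rbind, lapply(list(...), as.data.frame))
  structure(d, class = c("mt_field", "data.frame"))
}

field_scale <- function(f, s) {
  f$coef <- f$coef * s
  f[f$coef != 0, , drop = FALSE]
}

.field_dx1 <- function(f) {
  out <- list()
  # power rule part
  pw <- f[f$p > 0L, , drop = FALSE]
  if (nrow(pw)) {
    pw$coef <- pw$coef * pw$p
    pw$p <- pw$p - 1L
    out <- c(out, list(pw))
  }
  # axial trig part
  tr <- f[f$fx != "one" & f$lam != 0, , drop = FALSE]
  if (nrow(tr)) {
    iscos <- tr$fx == "cos"
    tr$coef <- ifelse(iscos, -tr$coef * tr$lam, tr$coef * tr$lam)
    tr$fx <- ifelse(iscos, "sin", "cos")
    out <- c(out, list(tr))
  }
  if (!length(out)) return(field_zero())
  do.call(.field_join, out)
}

.field_dth1 <- function(f) {
  iscos <- f$fth == "cos"
  f$coef <- ifelse(iscos, -f$coef * f$n, f$coef * f$n)
  f$fth <- ifelse(iscos, "sin", "cos")
  f[f$coef != 0, , drop = FALSE]
}

#' Partial derivative of a trial field
#'
#' @param f an [trig_field()] object.
#' @param dx,dth number of derivatives in `x` and `theta`.
#' @return the derivative field, again an `mt_field`.
#' @export
field_deriv <- function(f, dx = 0L, dth = 0L) {
  for (i in seq_len(dx)) f <- .field_dx1(f)
  for (i in seq_len(dth)) f <- .field_dth1(f)
  f
}

#' Evaluate a trial field on points
#'
#' @param f an [trig_field()] object.
#' @param x,theta coordinate vectors (recycled against each other).
#' @return numeric vector of field values.
#' @export
field_eval <- function(f, x, theta) {
  k <- max(length(x), length(theta))
  x <- rep_len(x, k)
  theta <- rep_len(theta, k)
  val <- numeric(k)
  for (i in seq_len(nrow(f))) {
    fx <- switch(f$fx[i], one = 1, cos = cos(f$lam[i] * x), sin = sin(f$lam[i] * x))
    fth <- switch(f$fth[i], cos = cos(f$n[i] * theta), sin = sin(f$n[i] * theta))
    val <- val + f$coef[i] * x^f$p[i] * fx * fth
  }
  val
}

#' Random smooth periodic test field
#'
#' Draws a truncated Fourier series in `theta` (harmonics up to `n_max`)
#' with low-order polynomial coefficients in `x`, the field family used by
#' the numeric shadow of the symbolic verification: smooth, 2*pi-periodic,
#' and exercising every derivative order present in the operators.
#'
#' @param n_max highest circumferential harmonic (default 3).
#' @param p_max highest polynomial power in `x` (default 4).
#' @return an `mt_field`.
#' @export
random_smooth_field <- function(n_max = 3L, p_max = 4L) {
  rows <- list()
  for (n in 0:n_max) {
    for (fth in if (n == 0L) "cos" else c("cos", "sin")) {
      rows[[length(rows) + 1L]] <- data.frame(
        coef = stats::runif(1, -1, 1), p = sample(0:p_max, 1L), lam = 0,
        fx = "one", n = n, fth = fth, stringsAsFactors = FALSE)
    }
  }
  do.call(.field_join, rows)
}

# Evaluate a linear differential expression (a linexpr) on concrete fields:
# returns the resulting field.  `fields` is a named list (u, v, w, P, ...)
# of mt_field objects; `params` a named vector of parameter values.
le_apply_fields <- function(le, fields, params) {
  out <- field_zero()
  for (k in names(le)) {
    j <- .jet_parse(k)
    if (is.null(fields[[j$f]])) {
      stop("expression involves field '", j$f, "' but no such field was supplied")
    }
    co <- pp_eval(le[[k]], params)
    if (co == 0) next
    out <- .field_join(out, field_scale(field_deriv(fields[[j$f]], j$a, j$b), co))
  }
  out
}

# Evaluate a quadratic density on concrete fields at points.
qd_eval_fields <- function(qd, fields, params, x, theta) {
  k <- max(length(x), length(theta))
  val <- numeric(k)
  cache <- new.env(parent = emptyenv())
  jet_val <- function(key) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    j <- .jet_parse(key)
    if (is.null(fields[[j$f]])) {
      stop("density involves field '", j$f, "' but no such field was supplied")
    }
    v <- field_eval(field_deriv(fields[[j$f]], j$a, j$b), x, theta)
    cache[[key]] <- v
    v
  }
  for (pk in names(qd)) {
    co <- pp_eval(qd[[pk]], params)
    if (co == 0) next
    js <- strsplit(pk, " ", fixed = TRUE)[[1L]]
    val <- val + co * jet_val(js[1L]) * jet_val(js[2L])
  }
  val
}

#' Apply the nonlocal operator L to a field
#'
#' The nonlocal operator of the shell model is
#' \eqn{L(f) = \eta^2 (f_{xx} + f_{\theta\theta}) - f}, with
#' \eqn{\eta = e a_0 / R} the dimensionless small-scale parameter.  At
#' \eqn{\eta = 0} it reduces to \eqn{-f} (the classical, local limit), and on
#' a single harmonic \eqn{\cos(\lambda x)\cos(n\theta)} it multiplies the
#' field by \eqn{-(1 + \eta^2(\lambda^2 + n^2))}.
#'
#' @param f an [trig_field()] object.
#' @param groups a [dimensionless_groups()] object, or a single numeric
#'   `eta` value.
#' @return the field \eqn{L(f)} as an `mt_field`.
#' @export
apply_nonlocal_L <- function(f, groups) {
  eta <- if (inherits(groups, "mt_groups")) groups$eta else as.numeric(groups)
  stopifnot(is.finite(eta), eta >= 0)
  lap <- .field_join(field_deriv(f, dx = 2L), field_deriv(f, dth = 2L))
  .field_join(field_scale(lap, eta^2), field_scale(f, -1))
}
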