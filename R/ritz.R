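# Rayleigh-Ritz solution of the buckling eigenproblem.
#
# For the simply supported trigonometric family
#     u = A cos(lam*x) cos(n*theta),
#     v = B sin(lam*x) sin(n*theta),
#     w = C sin(lam*x) cos(n*theta),      lam = m*pi/l,
# the quadratic forms of the functional reduce, by trigonometric
# orthogonality, to exact 3x3 matrices in the amplitudes (A, B, C):
# a stiffness form Kmat from R1 + R2 + R3 - V4 and a geometric (load) form
# Gmat from the S-densities, and the buckling loads are the generalized
# eigenvalues of Kmat q = (N/K) Gmat q.  The family satisfies theta
# periodicity and the geometric end conditions v = 0, w = 0 (with u free,
# whose conjugate natural conditions it satisfies identically), so single
# harmonics decouple exactly and no numerical quadrature enters the
# assembly.
#
# Phase bookkeeping: every x-part is cos(lam*x + jx*pi/2) and every
# theta-part cos(n*theta + jt*pi/2); differentiation multiplies by lam (or
# n) and advances the phase by one.  With lam = m*pi/l,
#   int_0^l cos(lam x + j1 pi/2) cos(lam x + j2 pi/2) dx = (l/2) cospi((j1-j2)/2)
# and for n >= 1 the theta integral is pi*cospi((j1-j2)/2); for n = 0 the
# factors are constants cospi(j/2) and the integral is their product
# times 2*pi.

.ansatz_phase_x <- c(u = 0L, v = -1L, w = -1L)   # cos / sin / sin
.ansatz_phase_th <- c(u = 0L, v = -1L, w = 0L)   # cos / sin / cos

.int_x <- function(j1, j2, l) (l / 2) * cospi((j1 - j2) / 2)

.int_th <- function(j1, j2, n) {
  if (n == 0) 2 * pi * cospi(j1 / 2) * cospi(j2 / 2)
  else pi * cospi((j1 - j2) / 2)
}

# factor and phases of the (a,b) jet of the basis function of field f
.ansatz_jet <- function(f, a, b, lam, n) {
  list(fac = lam^a * n^b,
       jx = .ansatz_phase_x[[f]] + a,
       jt = .ansatz_phase_th[[f]] + b)
}

.basis_norm <- function(f, lam, n, l) {
  jx <- .ansatz_phase_x[[f]]
  jt <- .ansatz_phase_th[[f]]
  .int_x(jx, jx, l) * .int_th(jt, jt, n)
}

#' Simply supported trial mode
#'
#' One member of the admissible trigonometric family: `m` axial half-waves
#' (`lambda = m*pi/l`) and `n` circumferential waves.
#'
#' @param m axial half-wave number, integer `>= 1`.
#' @param n circumferential wave number, integer `>= 0`.
#' @param l dimensionless length `L/R` (or an `mt_groups` object).
#' @return an object of class `mt_mode`.
#' @export
trial_mode <- function(m, n, l) {
  if (inherits(l, "mt_groups")) l <- l$l
  stopifnot(m >= 1, m == round(m), n >= 0, n == round(n), l > 0)
  structure(list(m = as.integer(m), n = as.integer(n), l = l,
                 lambda = m * pi / l, basis = "simply_supported_trig"),
            class = "mt_mode")
}

# Hessian of the integrated quadratic density restricted to the ansatz
# amplitudes (A, B, C).
.assemble_density <- function(qd, params, lam, n, l) {
  idx <- c(u = 1L, v = 2L, w = 3L)
  M <- matrix(0, 3L, 3L, dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
  for (pk in names(qd)) {
    co <- pp_eval(qd[[pk]], params)
    if (co == 0) next
    js <- strsplit(pk, " ", fixed = TRUE)[[1L]]
    j1 <- .jet_parse(js[1L])
    j2 <- .jet_parse(js[2L])
    if (j1$f == "P" || j2$f == "P") {
      stop("prescribed pressure fields cannot enter the eigenproblem assembly")
    }
    a1 <- .ansatz_jet(j1$f, j1$a, j1$b, lam, n)
    a2 <- .ansatz_jet(j2$f, j2$a, j2$b, lam, n)
    val <- co * a1$fac * a2$fac * .int_x(a1$jx, a2$jx, l) * .int_th(a1$jt, a2$jt, n)
    if (val == 0) next
    i <- idx[[j1$f]]
    j <- idx[[j2$f]]
    if (i == j) {
      M[i, i] <- M[i, i] + 2 * val
    } else {
      M[i, j] <- M[i, j] + val
      M[j, i] <- M[j, i] + val
    }
  }
  M
}

.check_pressure_eigen <- function(groups) {
  p <- groups$pressure
  if (p$model == "constant") {
    stop("constant radial pressure makes the buckling problem inhomogeneous; ",
         "it is accepted for functional evaluation only, not eigenanalysis")
  }
  if (p$model == "proportional") groups$RK * p$kappa else 0
}

#' Assemble the Ritz matrices of one mode from the trial functional
#'
#' Restricts the stiffness quadratic form `R1 + R2 + R3 - V4` and the
#' geometric (load) form built from the `S`-densities to the simply
#' supported ansatz of [trial_mode()], integrating in closed form by
#' trigonometric orthogonality.  The proportional radial-pressure model
#' adds its Galerkin contribution `-pK * L` on the `w`-harmonic to the
#' stiffness matrix (it is not substituted into the functional, which would
#' double-count the linear term's variation).
#'
#' For `n = 0` the circumferential basis of `v` vanishes identically: the
#' returned matrices carry a zero `v` row/column and `reduced = TRUE`, and
#' the eigenproblem is solved on the `(u, w)` block.
#'
#' The load eigenvalue of the pencil `Kmat q = NK * Gmat q` is the
#' dimensionless axial load `NK = N/K`.
#'
#' @param groups an `mt_groups` object.
#' @param mode an `mt_mode`.
#' @return an object of class `mt_ritz`: list with `K`, `G` (3x3 symmetric),
#'   `mode`, `reduced`, and the active amplitude indices.
#' @export
assemble_mode_matrices <- function(groups, mode) {
  stopifnot(inherits(groups, "mt_groups"), inherits(mode, "mt_mode"))
  if (mode$lambda <= 0) stop("no load path for this mode (lambda = 0)")
  pK <- .check_pressure_eigen(groups)
  params <- groups_params(groups)
  dens <- functional_density("zero")$terms
  stiff_qd <- qd_scale(qd_sub_param(dens, "NK", 0), -1)   # R1 + R2 + R3 - V4
  geo_qd <- qd_coeff_of(dens, "NK")                       # K * (S_u + S_v + S_w)
  lam <- mode$lambda
  n <- mode$n
  K <- .assemble_density(stiff_qd, params, lam, n, groups$l)
  G <- .assemble_density(geo_qd, params, lam, n, groups$l)
  if (pK != 0) {
    # Galerkin contribution of P = -kappa_p * w: D3 gains -pK * L(w), i.e.
    # +pK * (1 + eta^2(lam^2 + n^2)) on the w-harmonic; stiffness-side sign
    # is the negative of the operator coefficient.
    K[3L, 3L] <- K[3L, 3L] -
      pK * (1 + groups$eta^2 * (lam^2 + n^2)) * .basis_norm("w", lam, n, groups$l)
  }
  K <- (K + t(K)) / 2
  G <- (G + t(G)) / 2
  reduced <- n == 0L
  structure(list(K = K, G = G, mode = mode, reduced = reduced,
                 active = if (reduced) c(1L, 3L) else 1:3),
            class = "mt_ritz")
}

#' Galerkin projection of the governing equations (independent oracle)
#'
#' Substitutes the same simply supported ansatz into the governing
#' operators `D1`, `D2`, `D3` (the PDE route, transcribed independently of
#' the functional), projects each onto its own basis function, and splits
#' off the load-proportional terms: row `y` of the projection is
#' `A q + NK * B q` with `Kmat_oracle = -A` and `Gmat_oracle = B`.
#' Variational consistency demands that the symmetrized `Kmat_oracle` equal
#' the Ritz stiffness matrix entrywise and `Gmat_oracle` equal the
#' geometric matrix exactly; this is the module's core cross-check.
#'
#' @inheritParams assemble_mode_matrices
#' @return a list with `K` (symmetrized), `G`, `K_raw` (unsymmetrized
#'   projection) and `max_asymmetry` (largest absolute asymmetry of
#'   `K_raw`, itself a diagnostic of variational consistency).
#' @export
galerkin_oracle <- function(groups, mode) {
  stopifnot(inherits(groups, "mt_groups"), inherits(mode, "mt_mode"))
  if (mode$lambda <= 0) stop("no load path for this mode (lambda = 0)")
  pK <- .check_pressure_eigen(groups)
  pressure <- if (pK != 0) "proportional" else "zero"
  ops <- governing_operators(pressure)
  params <- groups_params(groups, pK = pK)
  lam <- mode$lambda
  n <- mode$n
  l <- groups$l
  idx <- c(u = 1L, v = 2L, w = 3L)
  A <- matrix(0, 3L, 3L, dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
  B <- A
  for (y in c("u", "v", "w")) {
    jy <- list(jx = .ansatz_phase_x[[y]], jt = .ansatz_phase_th[[y]])
    for (k in names(ops[[y]]$terms)) {
      j <- .jet_parse(k)
      sp <- pp_split(ops[[y]]$terms[[k]], "NK")
      aj <- .ansatz_jet(j$f, j$a, j$b, lam, n)
      proj <- aj$fac * .int_x(aj$jx, jy$jx, l) * .int_th(aj$jt, jy$jt, n)
      if (proj == 0) next
      A[idx[[y]], idx[[j$f]]] <- A[idx[[y]], idx[[j$f]]] + pp_eval(sp$free, params) * proj
      B[idx[[y]], idx[[j$f]]] <- B[idx[[y]], idx[[j$f]]] + pp_eval(sp$lin, params) * proj
    }
  }
  K_raw <- -A
  list(K = (K_raw + t(K_raw)) / 2, G = B, K_raw = K_raw,
       max_asymmetry = max(abs(K_raw - t(K_raw))))
}

#' Independent local-theory assembly (eta = 0 reference path)
#'
#' A third code path for the classical (local) orthotropic shell: the mode
#' matrices are written out as explicit closed-form entries obtained by
#' substituting the ansatz into the local operators by hand, with every
#' nonlocal term deleted at source (not by setting `eta = 0` in shared
#' code).  Used to pin the `eta = 0` limit of the nonlocal assembly.
#'
#' @inheritParams assemble_mode_matrices
#' @return a list with 3x3 `K` and `G`.
#' @export
local_mode_matrices <- function(groups, mode) {
  stopifnot(inherits(groups, "mt_groups"), inherits(mode, "mt_mode"))
  pK <- .check_pressure_eigen(groups)
  k1 <- groups$k1; k2 <- groups$k2; c2 <- groups$c2; mu1 <- groups$mu1
  sK <- groups$sK; l <- groups$l
  lam <- mode$lambda
  n <- mode$n
  # operator coefficients on the harmonic (local limit, L(.) = -1)
  a_uu <- -(k2 * (1 + c2) * n^2 + lam^2)
  a_uv <- (k2 + mu1) * lam * n
  a_uw <- mu1 * lam + c2 * lam^3 - c2 * k2 * lam * n^2
  a_vv <- -(k2 * (1 + 3 * c2) * lam^2 + k1 * n^2)
  a_vw <- -k1 * n - c2 * (3 * k2 + mu1) * lam^2 * n
  a_ww <- -(1 + c2 * k1) + 2 * c2 * k1 * n^2 -
    c2 * (lam^4 + k1 * n^4 + (4 * k2 + 2 * mu1) * lam^2 * n^2) - sK + pK
  nu <- .basis_norm("u", lam, n, l)
  nv <- .basis_norm("v", lam, n, l)
  nw <- .basis_norm("w", lam, n, l)
  A <- matrix(c(a_uu * nu, a_uv * nu, a_uw * nu,
                a_uv * nv, a_vv * nv, a_vw * nv,
                a_uw * nw, a_vw * nw, a_ww * nw),
              3L, 3L, byrow = TRUE,
              dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
  G <- diag(lam^2 * c(nu, nv, nw))
  dimnames(G) <- dimnames(A)
  list(K = -A, G = G)
}

#' Rayleigh quotient of a trial amplitude vector
#'
#' `N/K = (q' Kmat q) / (q' Gmat q)`: homogeneous of degree zero in `q`,
#' stationary exactly at the eigenvectors of the pencil, and bounded below
#' by the smallest positive eigenvalue on the cone where the quotient is
#' positive.
#'
#' @param q amplitude vector (length 3, or the active length of a reduced
#'   system).
#' @param matrices an `mt_ritz` object from [assemble_mode_matrices()].
#' @return the dimensionless load estimate `N/K`.
#' @export
rayleigh_quotient <- function(q, matrices) {
  stopifnot(inherits(matrices, "mt_ritz"))
  act <- matrices$active
  if (length(q) == 3L) q <- q[act]
  stopifnot(length(q) == length(act))
  if (all(q == 0)) stop("trial amplitudes must not all vanish")
  den <- drop(t(q) %*% matrices$G[act, act] %*% q)
  if (den <= 0) stop("trial function carries no geometric energy")
  drop(t(q) %*% matrices$K[act, act] %*% q) / den
}

# smallest positive generalized eigenvalue of the symmetric pencil
# K q = N G q with G positive definite on the active block
.pencil_eigen <- function(K, G) {
  U <- chol(G)
  Ui <- backsolve(U, diag(nrow(U)))
  S <- t(Ui) %*% K %*% Ui
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  q <- Ui %*% e$vectors
  # polish each eigenvalue with the Rayleigh quotient of its eigenvector:
  # stationarity makes this first-order insensitive to the vector error,
  # recovering the digits lost in the Cholesky reduction
  vals <- vapply(seq_len(ncol(q)), function(j) {
    drop(t(q[, j]) %*% K %*% q[, j]) / drop(t(q[, j]) %*% G %*% q[, j])
  }, numeric(1))
  list(values = vals, vectors = q)
}

.smallest_positive <- function(ev, tol) {
  pos <- which(ev$values > tol)
  if (!length(pos)) return(NULL)
  i <- pos[which.min(ev$values[pos])]
  list(value = ev$values[i], vector = ev$vectors[, i])
}

#' Critical buckling load over a mode range
#'
#' Solves the generalized eigenproblem of every mode `(m, n)` in the search
#' range, records the smallest positive load eigenvalue per mode (negative
#' eigenvalues correspond to tensile instabilities outside the model and
#' modes without a positive eigenvalue are recorded as non-buckling), and
#' takes the critical load as the minimum over the searched table, with the
#' deterministic tie-break "smaller n, then smaller m".
#'
#' @param groups an `mt_groups` object.
#' @param m_range,n_range integer vectors of axial half-wave and
#'   circumferential wave numbers to search.
#' @return an object of class `mt_buckling`: per-mode table (columns `m`,
#'   `n`, `lambda`, `N_dimless`, `N_dimensional`, `is_critical`), `N_cr`
#'   (dimensionless `N/K`), `N_cr_dimensional` (N/m), critical `mode`,
#'   normalized amplitude vector, and the search ranges.  When no searched
#'   mode buckles, `N_cr` is `NA` and `no_buckling` is `TRUE` (an explicit
#'   result, not an error).
#' @examples
#' gr <- dimensionless_groups(k1 = 0.002, k2 = 0.001, c2 = 1e-3, mu1 = 0.3,
#'                            eta = 0.1, l = 20)
#' critical_load(gr, m_range = 1:3, n_range = 0:4)
#' @export
critical_load <- function(groups, m_range = 1:5, n_range = 0:8) {
  stopifnot(inherits(groups, "mt_groups"),
            length(m_range) >= 1, length(n_range) >= 1)
  rows <- list()
  best <- NULL
  for (n in sort(unique(as.integer(n_range)))) {
    for (m in sort(unique(as.integer(m_range)))) {
      mode <- trial_mode(m, n, groups$l)
      mat <- assemble_mode_matrices(groups, mode)
      act <- mat$active
      ev <- .pencil_eigen(mat$K[act, act, drop = FALSE],
                          mat$G[act, act, drop = FALSE])
      tol <- 1e-12 * max(abs(mat$K[act, act]))
      sp <- .smallest_positive(ev, tol)
      if (is.null(sp)) next
      q <- numeric(3L)
      q[act] <- sp$vector
      q <- q / sqrt(sum(q^2))
      rows[[length(rows) + 1L]] <- data.frame(
        m = m, n = n, lambda = mode$lambda, N_dimless = sp$value,
        N_dimensional = sp$value * groups$K)
      if (is.null(best) || sp$value < best$N) {
        best <- list(N = sp$value, m = m, n = n, mode = mode, q = q)
      }
    }
  }
  if (!length(rows)) {
    return(structure(list(table = data.frame(), N_cr = NA_real_,
                          N_cr_dimensional = NA_real_, mode = NULL,
                          eigenvector = NULL, no_buckling = TRUE,
                          m_range = m_range, n_range = n_range,
                          eta = groups$eta),
                     class = "mt_buckling"))
  }
  tab <- do.call(rbind, rows)
  tab$is_critical <- tab$m == best$m & tab$n == best$n
  tab <- tab[order(tab$n, tab$m), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, N_cr = best$N,
                 N_cr_dimensional = best$N * groups$K,
                 mode = best$mode, eigenvector = best$q, no_buckling = FALSE,
                 m_range = m_range, n_range = n_range, eta = groups$eta),
            class = "mt_buckling")
}

#' @export
print.mt_buckling <- function(x, digits = 6, ...) {
  cat("Critical buckling load (simply supported Rayleigh-Ritz)\n")
  if (isTRUE(x$no_buckling)) {
    cat("  no buckling in searched range\n")
    return(invisible(x))
  }
  cat(sprintf("  N_cr/K = %.*g   N_cr = %.*g N/m   mode (m, n) = (%d, %d)   eta = %g\n",
              digits, x$N_cr, digits, x$N_cr_dimensional,
              x$mode$m, x$mode$n, x$eta))
  cat(sprintf("  amplitudes (A, B, C) = (%.4f, %.4f, %.4f)   %d buckling modes in table\n",
              x$eigenvector[1], x$eigenvector[2], x$eigenvector[3],
              nrow(x$table)))
  invisible(x)
}
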