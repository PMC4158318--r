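# Physical description of one microtubule shell problem and the
# dimensionless groups consumed by the operators and functionals.

#' Shell geometry
#'
#' Geometry of the cylindrical shell representing one microtubule.  All
#' lengths are in metres (SI); the configuration reader accepts annotated
#' units such as `"11.2 nm"` and converts at parse time.
#'
#' @param L shell length (m).
#' @param R mid-surface radius (m).
#' @param h wall thickness (m); must satisfy `h < R`.
#' @param h0 effective thickness for bending (m); defaults to `h`.  Values
#'   above `R` are accepted with a warning only, as a sanity bound.
#' @return an object of class `mt_geometry`.
#' @export
shell_geometry <- function(L, R, h, h0 = h) {
  vals <- c(L = L, R = R, h = h, h0 = h0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("geometry values must be strictly positive and finite")
  }
  if (h >= R) stop("wall thickness h must be smaller than the radius R")
  if (h0 > R) warning("effective bending thickness h0 exceeds the radius R")
  structure(as.list(vals), class = "mt_geometry")
}

#' Orthotropic shell material
#'
#' Elastic constants of the orthotropic shell wall: Young's moduli along the
#' axial (`E1`) and circumferential (`E2`) directions, the shear modulus
#' `G`, and the two Poisson ratios.  The product `mu1 * mu2` must stay
#' below 1 for the membrane stiffness `K = E1*h/(1 - mu1*mu2)` to be finite
#' and positive.
#'
#' @param E1,E2 axial and circumferential Young's moduli (Pa).
#' @param G shear modulus (Pa).
#' @param mu1,mu2 Poisson ratios (dimensionless, in `[0, 1)`).
#' @return an object of class `mt_material`.
#' @export
orthotropic_material <- function(E1, E2, G, mu1, mu2) {
  if (any(!is.finite(c(E1, E2, G, mu1, mu2)))) stop("material values must be finite")
  if (E1 <= 0 || E2 <= 0 || G <= 0) {
    stop("validation error: moduli E1, E2, G must be strictly positive")
  }
  if (mu1 < 0 || mu2 < 0 || mu1 >= 1 || mu2 >= 1) {
    stop("validation error: Poisson ratios must lie in [0, 1)")
  }
  if (mu1 * mu2 >= 1) stop("non-physical Poisson product: mu1*mu2 >= 1")
  structure(list(E1 = E1, E2 = E2, G = G, mu1 = mu1, mu2 = mu2),
            class = "mt_material")
}

#' Surrounding medium and small-scale parameters
#'
#' The filament network surrounding the microtubule acts as a Winkler-type
#' elastic foundation with constant `sigma`; when not set explicitly it is
#' derived from the elastic modulus of the surrounding medium as
#' `sigma = 2.7 * Ec`.  `ea0` is the Eringen small-scale length (m); the
#' dimensionless nonlocal parameter is `eta = ea0 / R`.  The radial cytosol
#' pressure enters only through a user-chosen model: `pressure_zero()`
#' (default, static eigenproblem), `pressure_proportional(kappa)` with
#' `P_YY = -kappa * w`, or `pressure_constant(value)` (accepted for
#' functional evaluation only, not for eigenanalysis).
#'
#' @param Ec elastic modulus of the surrounding medium (Pa).
#' @param sigma foundation constant (Pa); overrides the `2.7 * Ec` default
#'   when supplied.
#' @param ea0 nonlocal length scale (m), `>= 0`.
#' @param pressure a pressure model; see Details.
#' @return an object of class `mt_environment`.
#' @export
shell_environment <- function(Ec = 0, sigma = NULL, ea0 = 0,
                              pressure = pressure_zero()) {
  if (!is.finite(Ec) || Ec < 0) stop("Ec must be finite and >= 0")
  if (!is.finite(ea0) || ea0 < 0) stop("ea0 must be finite and >= 0")
  sigma_user <- !is.null(sigma)
  if (!sigma_user) sigma <- 2.7 * Ec
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be finite and >= 0")
  if (!inherits(pressure, "mt_pressure")) stop("pressure must be a pressure model")
  structure(list(Ec = Ec, sigma = sigma, sigma_user = sigma_user,
                 ea0 = ea0, pressure = pressure),
            class = "mt_environment")
}

#' @rdname shell_environment
#' @export
pressure_zero <- function() structure(list(model = "zero"), class = "mt_pressure")

#' @rdname shell_environment
#' @param kappa proportionality constant of the radial pressure model
#'   `P_YY = -kappa * w` (Pa per unit dimensionless radial displacement).
#' @export
pressure_proportional <- function(kappa) {
  stopifnot(is.finite(kappa))
  structure(list(model = "proportional", kappa = kappa), class = "mt_pressure")
}

#' @rdname shell_environment
#' @param value constant radial pressure (Pa).
#' @export
pressure_constant <- function(value) {
  stopifnot(is.finite(value))
  structure(list(model = "constant", value = value), class = "mt_pressure")
}

#' One complete shell problem
#'
#' @param geometry a [shell_geometry()].
#' @param material an [orthotropic_material()].
#' @param environment a [shell_environment()].
#' @return an object of class `mt_problem`.
#' @export
shell_problem <- function(geometry, material, environment = shell_environment()) {
  stopifnot(inherits(geometry, "mt_geometry"),
            inherits(material, "mt_material"),
            inherits(environment, "mt_environment"))
  structure(list(geometry = geometry, material = material,
                 environment = environment), class = "mt_problem")
}

#' Dimensionless groups of the shell model
#'
#' Computes the groups the governing operators and functionals consume:
#' \deqn{k_1 = E_2/E_1,\quad k_2 = G(1-\mu_1\mu_2)/E_1,\quad
#'       c_2 = h_0^3/(12 R^2 h),\quad K = E_1 h/(1-\mu_1\mu_2),}
#' together with \eqn{\eta = e a_0 / R}, \eqn{l = L/R}, the foundation group
#' \eqn{sK = \sigma R / K} and the pressure group \eqn{RK = R/K}.
#'
#' The direction of the modulus ratio deserves a flag: `k1` is defined as
#' the *circumferential-to-axial* ratio `E2/E1`.  This is forced by the
#' structure of the governing operators, where the hoop-stiffness terms
#' (`k1*v_thth`, `k1*w_th`, `c2*k1*w_thththth`) must carry the
#' circumferential modulus after division by `K = E1*h/(1-mu1*mu2)`.  Should
#' a different convention ever be needed, this is the single place to flip
#' it.
#'
#' @param geometry a [shell_geometry()] (or an `mt_problem`, in which case
#'   the remaining arguments are taken from it).
#' @param material an [orthotropic_material()].
#' @param environment a [shell_environment()].
#' @return an object of class `mt_groups` with fields `k1`, `k2`, `c2`, `K`,
#'   `eta`, `l`, `sK`, `RK`, the resolved `sigma`, and the pressure model.
#' @examples
#' g <- shell_geometry(L = 560e-9, R = 11.2e-9, h = 2.7e-9, h0 = 1.6e-9)
#' m <- orthotropic_material(E1 = 1.5e9, E2 = 3e6, G = 1.5e6, mu1 = 0.3, mu2 = 0.3)
#' derive_groups(g, m, shell_environment(Ec = 1e3, ea0 = 1.12e-9))
#' @export
derive_groups <- function(geometry, material = NULL, environment = NULL) {
  if (inherits(geometry, "mt_problem")) {
    material <- geometry$material
    environment <- geometry$environment
    geometry <- geometry$geometry
  }
  if (is.null(environment)) environment <- shell_environment()
  stopifnot(inherits(geometry, "mt_geometry"),
            inherits(material, "mt_material"),
            inherits(environment, "mt_environment"))
  om <- 1 - material$mu1 * material$mu2
  K <- material$E1 * geometry$h / om
  groups <- list(
    k1 = material$E2 / material$E1,
    k2 = material$G * om / material$E1,
    c2 = geometry$h0^3 / (12 * geometry$R^2 * geometry$h),
    K = K,
    mu1 = material$mu1,
    eta = environment$ea0 / geometry$R,
    l = geometry$L / geometry$R,
    sigma = environment$sigma,
    sK = environment$sigma * geometry$R / K,
    RK = geometry$R / K,
    pressure = environment$pressure
  )
  structure(groups, class = "mt_groups")
}

#' Direct construction of dimensionless groups
#'
#' Builds an `mt_groups` object from the dimensionless values themselves,
#' bypassing the physical parameterisation.  Used for randomized property
#' checks and anywhere the groups are the natural input.
#'
#' @param k1,k2,c2 stiffness ratios (dimensionless, `> 0`).
#' @param mu1 Poisson ratio entering the coupling terms.
#' @param eta nonlocal parameter `ea0/R` (`>= 0`).
#' @param l slenderness `L/R` (`> 0`).
#' @param sK foundation group `sigma*R/K` (`>= 0`).
#' @param K membrane stiffness (N/m), used only to redimensionalise loads.
#' @param RK pressure group `R/K`.
#' @param pressure a pressure model.
#' @return an object of class `mt_groups`.
#' @export
dimensionless_groups <- function(k1, k2, c2, mu1 = 0.3, eta = 0, l = 20,
                                 sK = 0, K = 1, RK = 1,
                                 pressure = pressure_zero()) {
  vals <- c(k1 = k1, k2 = k2, c2 = c2, l = l, K = K)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("k1, k2, c2, l, K must be strictly positive")
  }
  stopifnot(eta >= 0, sK >= 0, mu1 >= 0, mu1 < 1)
  structure(list(k1 = k1, k2 = k2, c2 = c2, K = K, mu1 = mu1, eta = eta,
                 l = l, sigma = NA_real_, sK = sK, RK = RK,
                 pressure = pressure),
            class = "mt_groups")
}

#' @export
print.mt_groups <- function(x, digits = 6, ...) {
  cat("Dimensionless shell groups\n")
  cat(sprintf("  k1 = %.*g  k2 = %.*g  c2 = %.*g  mu1 = %.*g\n",
              digits, x$k1, digits, x$k2, digits, x$c2, digits, x$mu1))
  cat(sprintf("  eta = %.*g  l = %.*g  sK = %.*g  K = %.*g N/m\n",
              digits, x$eta, digits, x$l, digits, x$sK, digits, x$K))
  cat(sprintf("  pressure model: %s\n", x$pressure$model))
  invisible(x)
}

# Named parameter vector used to evaluate parameter polynomials; NK (the
# dimensionless load N/K) and pK (the proportional-pressure group) are set
# by the caller.
groups_params <- function(groups, NK = 0, pK = 0) {
  c(k1 = groups$k1, k2 = groups$k2, c2 = groups$c2, mu1 = groups$mu1,
    eta2 = groups$eta^2, sK = groups$sK, RK = groups$RK, NK = NK, pK = pK)
}

#' Nonlocal stress amplitudes for a single strain harmonic
#'
#' For a strain state that is a single Fourier harmonic proportional to
#' \eqn{\cos(\lambda x)\cos(n\theta)}, the nonlocal constitutive relations
#' become algebraic: the Laplacian multiplies the harmonic by
#' \eqn{-(\lambda^2 + n^2)}, so every stress amplitude equals the local
#' orthotropic Hooke's-law amplitude divided by the attenuation denominator
#' \eqn{1 + \eta^2(\lambda^2 + n^2)}.  At \eqn{\eta = 0}, or for a uniform
#' strain (\eqn{\lambda = n = 0}), the local law is recovered exactly.
#'
#' @param strain named list or vector with strain amplitudes `ex`, `eth`,
#'   `exth` (dimensionless).
#' @param lambda axial wavenumber of the harmonic (dimensionless).
#' @param n circumferential wavenumber (integer `>= 0`).
#' @param material an [orthotropic_material()].
#' @param groups an `mt_groups` object (for `eta`), or a numeric `eta`.
#' @return a list with stress amplitudes `sx`, `sth`, `txth` (Pa) and the
#'   scalar `attenuation` factor applied to the local law.
#' @export
nonlocal_harmonic_stress <- function(strain, lambda, n, material, groups) {
  stopifnot(inherits(material, "mt_material"))
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer")
  eta <- if (inherits(groups, "mt_groups")) groups$eta else as.numeric(groups)
  s <- as.list(strain)
  stopifnot(all(c("ex", "eth", "exth") %in% names(s)))
  om <- 1 - material$mu1 * material$mu2
  att <- 1 / (1 + eta^2 * (lambda^2 + n^2))
  list(
    sx = att * (material$E1 * s$ex + material$E2 * material$mu2 * s$eth) / om,
    sth = att * (material$E2 * s$eth + material$E1 * material$mu1 * s$ex) / om,
    txth = att * material$G * s$exth,
    attenuation = att
  )
}
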