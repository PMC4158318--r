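---
title: "Methods: the variational shell model behind mtbuckle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the variational shell model behind mtbuckle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbuckle)
```

## The model and its assumptions

A microtubule is represented as a thin circular cylindrical shell of
mid-surface radius $R$, wall thickness $h$, effective bending thickness
$h_0$ and length $L$, with orthotropic wall elasticity: Young's moduli
$E_1$ (axial) and $E_2$ (circumferential), shear modulus $G$ and Poisson
ratios $\mu_1, \mu_2$. Coordinates are the dimensionless axial position
$x = X/R \in [0, l]$, $l = L/R$, and the circumferential angle $\theta$;
displacements are $u$ (axial), $v$ (circumferential) and $w$ (radial),
all functions of $(x, \theta)$ and $2\pi$-periodic in $\theta$.

Three environmental effects enter:

* **Nonlocality.** Stress at a point depends on strain in a
  neighbourhood: $(1 - \eta^2 \nabla^2)\,\sigma = C \varepsilon$ with
  $\eta = e a_0 / R$ the small-scale parameter. On a single harmonic
  $\propto \cos\lambda x \cos n\theta$ this reduces to dividing every local
  stress amplitude by $1 + \eta^2(\lambda^2 + n^2)$
  (`nonlocal_harmonic_stress()`); $\eta = 0$ recovers classical
  elasticity. $e a_0$ must come from experiment; we treat it as an input.
* **Foundation.** The filament network acts as a Winkler foundation of
  constant $\sigma = 2.7\,E_c$ unless the user sets $\sigma$ directly (an
  explicit value always wins and both are echoed).
* **Radial cytosol pressure** $P_{YY}$, entering the radial equation only
  through the slot $(R/K)\,L(P_{YY})$, where $L(\cdot) = \eta^2\nabla^2 - 1$.
  No constitutive formula for $P_{YY}$ is implemented — deriving it from
  cytosol flow is out of scope — so the user chooses a model: `zero`
  (default; a static eigenproblem), `proportional` ($P_{YY} = -\kappa_p w$),
  or `constant` (accepted for functional evaluation, rejected for
  eigenanalysis because it makes the problem inhomogeneous).

The governing equations divide through by the membrane stiffness
$K = E_1 h / (1 - \mu_1\mu_2)$, leaving the dimensionless groups

$$k_1 = E_2/E_1, \quad k_2 = G(1-\mu_1\mu_2)/E_1, \quad
  c_2 = h_0^3/(12 R^2 h), \quad \eta = e a_0/R, \quad l = L/R,$$

plus $\sigma R/K$ (foundation) and $R/K$ (pressure scale). **Direction of
$k_1$:** the ratio is defined circumferential-to-axial, $k_1 = E_2/E_1$.
This is forced by the operator structure: after division by $K$ the hoop
terms $k_1 v_{\theta\theta}$, $k_1 w_\theta$ and
$c_2 k_1 w_{\theta\theta\theta\theta}$ must carry the circumferential
modulus. The definition lives in one line of `derive_groups()` should a
different convention ever be wanted.

## Exact symbolic verification of the variational principle

The governing operators are linear and the trial functional quadratic in
the fields and their partial derivatives, so the whole symbolic layer
works over *jet variables* $y_{(a,b)} = \partial^{a+b} y / \partial x^a
\partial\theta^b$: operators are maps from jet variables to coefficient
polynomials in the dimensionless groups, densities are maps from
*pairs* of jet variables to such polynomials. All structural coefficients
are integers and halves — dyadic rationals, exact in double precision —
so sums and cancellations are exact, and a residual that cancels leaves a
polynomial with literally no terms. A "symbolic zero" from
`verify_euler_lagrange()` is therefore an exact polynomial identity valid
for **every** admissible parameter value at once, which is stronger than a
computer-algebra simplification at sampled parameters.

The trial functional is $V = V_1(u) + V_2(v) + V_3(w) + \iint F$, where
the $V_i$ are single-field quadratic integrands (membrane, bending,
foundation, nonlocal load and pressure terms, each with its $1/2$
prefactor) and the coupling density

$$F = -(k_2+\mu_1)\,v_x u_\theta + \mu_1 w_x u + c_2 w_{xx} u_x
    + c_2 k_2\, w_x u_{\theta\theta} - k_1 w v_\theta
    + c_2(3k_2+\mu_1)\, w_{xx} v_\theta$$

is the outcome of the semi-inverse construction: an unknown $F$ is
postulated, the $u$-channel match determines its $u$-coupled part, and the
remainder $\Phi(v,w) = -k_1 w v_\theta + c_2(3k_2+\mu_1) w_{xx} v_\theta$
is fixed by the $v$-channel. The package re-verifies this chain step by
step (`coupling_density()`, `phi_density()`, `m_operators()`) and then the
main claim: for each field $y$,

$$\frac{\delta V}{\delta y} = D_y \quad\text{(the governing operator)},$$

using the higher-order Euler–Lagrange template
$\delta F/\delta y = \sum_{(a,b)} (-1)^{a+b} D_x^a D_\theta^b\,
\partial F/\partial y_{(a,b)}$, with the sign alternating by the parity of
the total derivative order. The template is implemented for arbitrary
finite order, so no truncation is possible. Dropping any single coupling
term (the `drop_coupling` hook) breaks the identity and is detected — the
package's negative control.

A numeric shadow always runs alongside the exact check: residual
operators are evaluated on random test fields (truncated Fourier series in
$\theta$ up to harmonic 3 with polynomial coefficients in $x$ up to degree
4 — smooth, periodic, and exercising every derivative order present) and
compared to the magnitude of the governing terms; the default report uses
10 fields and the acceptance checks demand a relative residual below
$10^{-9}$ (observed: $\sim 10^{-15}$).

## Rayleigh–Ritz solution

The functional decomposes as $V = -(R_1 + R_2 + R_3 - V_4) + N\,(S_u + S_v
+ S_w)$, giving the Rayleigh quotient $N = \min (R_1+R_2+R_3-V_4)/(S_u +
S_v + S_w)$. The admissible family implemented is the simply supported
trigonometric ansatz

$$u = A\cos\lambda x \cos n\theta,\quad v = B\sin\lambda x \sin n\theta,
  \quad w = C\sin\lambda x \cos n\theta,\qquad \lambda = m\pi/l,$$

chosen because it satisfies $\theta$-periodicity and, at both ends, the
geometric conditions $v = 0$, $w = 0$ and $u_x = 0$ together with the
conjugate natural conditions *identically* (every natural expression is
proportional to $\sin m\pi$). The minimisation over the admissible space
is stated without boundary conditions attached; we fix this family as the
v1 interpretation — other end conditions would change $N_{cr}$ and are out
of scope.

Per mode $(m, n)$, trigonometric orthogonality reduces the quadratic forms
to exact $3\times 3$ matrices in $(A, B, C)$: a stiffness form
$K_{\mathrm{mat}}$ (Hessian of $R_1+R_2+R_3-V_4$) and a geometric form
$G_{\mathrm{mat}}$ (Hessian of $K(S_u+S_v+S_w)$, so the pencil eigenvalue
is the dimensionless load $N/K$). Assembly is closed-form — phase
bookkeeping over $\cos(\lambda x + j\pi/2)$ factors, integrals $l/2$ or
$\pi$ times $\cos$ of phase differences — with no quadrature anywhere in
the solve path; quadrature appears only in cross-check tests. Cross-mode
coupling vanishes exactly for this operator family, which is why a single
harmonic per $(m,n)$ suffices and multi-term Ritz expansions are not
needed.

Numerical choices and degenerate cases:

* **Eigen solve.** $G_{\mathrm{mat}}$ is positive definite for
  $\lambda > 0$; the symmetric-definite pencil is reduced by Cholesky and
  each eigenvalue is polished with the Rayleigh quotient of its computed
  eigenvector (stationarity makes the quotient first-order insensitive to
  eigenvector error, recovering the digits the reduction loses).
* **Sign of $N$.** The buckling load is the *smallest positive*
  eigenvalue (tolerance $10^{-12}\,\lVert K_{\mathrm{mat}}\rVert$);
  negative eigenvalues correspond to tensile instabilities outside the
  model. For strongly orthotropic walls ($k_1 \ll 1$) the stiffness form
  is genuinely indefinite, so trial quotients can undercut the smallest
  positive eigenvalue; the sampled Courant–Fischer bound therefore holds
  unconditionally only where the stiffness form is positive definite
  (e.g. the isotropic fixture, verified eigenvalue-by-eigenvalue), and the
  indefinite case is bounded by the signed spectral range instead.
* **Axisymmetric modes.** At $n = 0$ the $v$ basis function vanishes
  identically; the matrices carry a zero $v$ row/column, are flagged
  `reduced`, and the $(u, w)$ block is solved. A mode with $\lambda = 0$
  has no load path and is rejected.
* **Symmetrisation.** The assembled Hessians are symmetric by
  construction; $K_{\mathrm{mat}}$ is nevertheless passed through
  $\tfrac12(M + M^\top)$, and the *unsymmetrised* Galerkin projection is
  reported with its asymmetry as a diagnostic — variational consistency
  makes it vanish, and the tests assert this at $10^{-12}$ relative.
* **Ties.** Exact ties in the mode search resolve to smaller $n$, then
  smaller $m$.
* **Proportional pressure.** $P_{YY} = -\kappa_p w$ is *not* substituted
  into the functional: the pressure enters $V_3$ linearly, and varying a
  substituted linear term would double its contribution. It is added on
  the Galerkin side instead, as $-p_K L$ applied to the $w$-harmonic
  ($p_K = R\kappa_p/K$), shifting only the $w$-diagonal of
  $K_{\mathrm{mat}}$ by $-p_K(1+\eta^2(\lambda^2+n^2))$ per unit basis
  norm. Under this sign convention a positive $\kappa_p$ *reduces* the
  effective radial stiffness; users wanting a restoring pressure should
  pass the opposite sign.

Two independent implementations guard the assembly: the Galerkin
projection of the governing operators (transcribed from the PDE side, not
derived from the functional) must match the Ritz matrices entrywise, and a
third, hand-coded local assembly with every nonlocal term deleted at
source pins the $\eta = 0$ limit.

## Boundary conditions

Integrating the first variation by parts leaves edge integrals pairing
five expressions with $(\delta u, \delta u_x, \delta v, \delta v_x,
\delta w, \delta w_x)$ at $x = 0, l$; each pair yields a natural
(force-like) or geometric alternative. With $\eta > 0$ the axial-force,
radial-shear and bending-moment expressions carry load-proportional
nonlocal terms $N/K\,\eta^2(\cdots)$ — the boundary conditions couple to
the load, a distinctive feature of the nonlocal formulation.

One transcription subtlety deserves a flag. Statements of this boundary
set sometimes carry a $c_2(3k_2+\mu_1)\,w_{x\theta}$ term in the
circumferential (*$v$-channel*) natural force condition. The
first-variation computation shows it cannot be there: the coupling-density
term $c_2(3k_2+\mu_1)\,w_{xx} v_\theta$ reaches $\delta v$ only through a
$\theta$ integration by parts, which leaves no axial boundary trace. The
package therefore reports the variationally consistent form, and
`boundary_term_balance()` — the numeric identity
$\delta V = \iint (D_1\delta u + D_2\delta v + D_3\delta w) +
\sum_i b_i$ on random fields — confirms it to $\sim 10^{-15}$ relative
(the spurious term would show up at $\sim 10^{-4}$). The radial-shear
expression, whose printed groupings vary across sources, is isolated in a
single helper so any correction is a one-line change.

Residuals are reported both pointwise on a $\theta$ grid and as an RMS
over the circumference (the weak measure used for acceptance, since the
underlying statement is an edge integral), with a scale-free tolerance of
$10^{-9}$ times the largest single-term magnitude — sampled at interior
sections as well, so an expression that vanishes identically at an edge is
judged against the magnitudes the mode actually carries. Periodicity is
checked by comparing $\theta$ against $\theta + 2\pi$ around the whole
circle, which catches half-integer harmonics that happen to vanish at the
endpoints.

## Fixtures: what they emulate and what they do not

The illustrative parameter sets (`mt_fixtures()`) use values typical of
the microtubule shell-model literature — $R = 11.2$ nm, $h = 2.7$ nm,
$h_0 = 1.6$ nm, GPa-scale axial versus MPa-scale circumferential moduli,
kPa-scale cytoplasm — but they are *not* measurements of any specific
experiment, and $e a_0$ for microtubules is unknown; fixtures span
$\eta \in [0, 0.2]$ as a plausible range. The default segment length is
112 nm ($l = 10$), read as a stretch between lateral crosslinks; for the
strongly orthotropic wall the axisymmetric minimiser then falls near
$m \approx 17$ ($\lambda^* \approx ((1-\mu_1^2)/c_2)^{1/4}$), safely
interior to the default search window $m \le 25$, $n \le 8$ (225 modes,
solved in a couple of seconds). At the largest $\eta$ in the sweep the
minimiser migrates to the window edge: nonlocal softening strengthens
with wavenumber, and ever-shorter wavelengths keep lowering the load — a
known feature of nonlocal shell models, worth remembering when reading
$N_{cr}$ at large $\eta$ as anything more than a window minimum.

Passing tests on these fixtures demonstrate the mathematical structure —
the variational identity, oracle agreement, monotone trends — on a
continuum idealisation. They do not validate the continuum model against
real microtubules: protofilament discreteness, length-dependent apparent
stiffness, viscoelasticity of the cytosol (only a static pressure slot is
kept), post-buckling behaviour and imperfection sensitivity are all
outside the model.

## Known limitations

* Single-harmonic Ritz per mode is exact for the simply supported family
  only; other edge conditions (clamped, free) would need multi-term
  expansions and are not solved in v1 (the boundary module *verifies*
  conditions, it does not solve non-SS boundary-value problems).
* The trial functional is not unique; the verified one is the standard
  semi-inverse choice. Different functionals differing by null
  Lagrangians would shift individual boundary terms while leaving the
  field equations unchanged.
* Dimensional results scale with $K = E_1 h/(1-\mu_1\mu_2)$; uncertainty
  in the effective wall thickness propagates linearly into $N_{cr}$.
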