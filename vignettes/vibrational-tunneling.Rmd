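---
title: "Vibrational tunneling spectra from instanton couplings and VCI local states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrational tunneling spectra from instanton couplings and VCI local states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vibtun)
```

## The problem

Molecules and model systems with several potential wells separated by high
barriers show tunneling structure in their vibrational spectra: states that
would be degenerate (or accidentally near-degenerate) localize in single
wells and interact only through the classically forbidden region.  Exact
variational treatments need basis sets that resolve two or more wells at
once and become prohibitively expensive exactly where tunneling splittings
are small.  `vibtun` implements the opposite decomposition: accurate
*single-well* anharmonic states provide the diagonal of a small effective
Hamiltonian (the tunneling matrix), and semiclassical instanton
wavefunctions provide the inter-well couplings, at the cost of one
minimum-action-path optimization plus Hessians along it.

The tunneling matrix over localized states $\{\phi_i^{(L)},\phi_j^{(R)}\}$
has diagonal blocks $E_i^{(L/R)}\,\delta_{ij}$ (intra-well off-diagonal
couplings are neglected; the VSCF/VCI basis is chosen to make them small)
and an off-diagonal block $h_{ij}$.  Its eigenvalues are the vibrational
levels; differences of paired levels are tunneling splittings, and
eigenvector well-weights give mixing angles.

## Semiclassical couplings

The coupling block is evaluated by a generalized Herring surface integral
over a dividing plane inside the barrier,
$$h_{ij} = \tfrac12 \oint_D \big[\phi_j^{(R)}\partial_n \phi_i^{(L)}
 - \phi_i^{(L)}\partial_n \phi_j^{(R)}\big]\, d\Sigma ,$$
derived by integrating the two localized Schrödinger equations over the
left half-space, extending intra-well overlaps to the full domain, and
dropping products of tails (exact at this order away from pathological
overlaps; the connection-point scan below estimates the neglected terms).

Inside the barrier the local wavefunctions are Jacobi-field instanton (JFI)
forms built on the minimum action path (MAP), the geodesic of the metric
$\sqrt{2(V-V_{min})}\,dS$ in mass-scaled coordinates:

* momentum $p_0(S)=\sqrt{2(V-V_{min})}$ and action $W_0(S)=\int p_0\,dS$;
* Gaussian width matrices from the matrix Riccati transport
  $p_0\,dA/dS = H(S) - A^2$ with the harmonic initial value
  $A(\epsilon)=H_0^{1/2}$ a short jump $\epsilon$ away from the minimum
  (the equation is singular at $p_0 = 0$; below $\epsilon$ the wavefunction
  *is* the harmonic-oscillator form, which is what the matching condition
  states);
* an amplitude exponent $W_1$ with
  $dW_1/d\tau = \tfrac12\left[dp_0/dS + \mathrm{tr}(PAP) -
  \mathrm{tr}A_0\right]$ ($P$ projects out the tangent), which reduces to
  the familiar $p_0^{-1/2}$ WKB amplitude in one dimension and vanishes
  identically on a quadratic surface;
* for excited states, a prefactor $\prod_m (F_m + U_m^T\Delta x)^{\nu_m}$
  per excited mode, transported by
  $p_0\,dF/dS=\omega_e F$ and
  $p_0\,dU/dS = (\omega_e - PAP)\,U - 2\omega_e F\,\kappa(S)$
  with the path curvature $\kappa = d\hat t/dS$, matched at $\epsilon$ by
  $F(\epsilon)=U_0^T(x(\epsilon)-x_{min})$ and the transverse part of the
  excited normal mode $U_0$.  These transport equations were derived for
  this package by inserting $\phi_\nu = \Phi\,\phi_0$ into the Euclidean
  Schrödinger equation and collecting orders in the transverse displacement;
  the one-dimensional and separable limits they must reproduce (harmonic
  $F(S)=S$; transverse $F\equiv 0$, $U$ constant) are tested.  Note that for
  $\nu>1$ the prefactor is a power, not a Hermite polynomial: the
  semiclassical form only matches the oscillator's dominant tail, with the
  normalization $(2\omega_e)^{\nu/2}/\sqrt{\nu!}$.

At the dividing plane (through the connection point, normal along the
path tangent, the average of its one-sided limits when the path is kinked)
the flux integral is Gaussian with polynomial prefactors.  Two independent
evaluation routes are provided: closed-form Gaussian moments
(`tm_element_fundamental`, excitations up to one quantum per mode) and
Gauss–Hermite quadrature in the eigenbasis of the combined width matrix
(`tm_element_numeric`, arbitrary excitation products, default order 20 per
transverse dimension).  **Flux truncation:** only the classical-action
exponent $W_0$ is differentiated in $\partial_n$; derivatives of the
amplitude factors ($W_1$, $A(S)$, $F$, $U$) are one order higher in
$\hbar$ and are dropped.  Keeping them is inconsistent asymptotics and
measurably degrades accuracy (on the symmetric benchmark the ground-state
splitting moves from 0.2% to 15% error against the exact grid solution).

For wells of different depth ($d\neq 0$) the MAP is optimized on the
modified surface $\tilde V = V - \Theta(S-S_{cp})\,d$ with the connection
point fixed a priori at the middle bead; the coupling then depends weakly
on the choice of $S_{cp}$ unless the two states are resonant, and
`tm_sensitivity` reports the spread over a scan of the central region as
the error estimate.

## Local states

Within each well the potential is expanded to the two-mode level of the
$n$-mode hierarchy around the minimum: one-mode cuts along every normal
mode sampled at Gauss–Hermite DVR points scaled by the harmonic length
$1/\sqrt{\omega_i}$ (8 points per mode for the benchmark, 11 suggested for
molecules), fitted to order-8 polynomials without a constant term;
pair corrections on the rectangular point grid, defined as grid energy
minus both *sampled* one-mode values, fitted to tensor monomials
$q_i^p q_j^q$ with $p,q\ge 1$ so they vanish on the axes identically.
With 8 points and order 8 both fits interpolate; with more points they are
genuine least squares and the residuals are reported.

The VSCF basis frequency per mode is not the harmonic $\omega_i$ but the
fundamental of the fitted one-mode potential computed in a 100-function
sine-DVR (box: twice the sampled range, shrunk automatically if the
polynomial tail turns over).  This keeps the number of harmonic-oscillator
basis functions small (7 per mode for the benchmark, 16 suggested for
molecules).  All polynomial integrals use Gauss–Hermite quadrature of
sufficient exact degree.  VCISD diagonalizes the full 1+2-mode Hamiltonian
over VSCF modal products with at most two modes excited and at most 6
quanta per mode; states are labeled by the dominant configuration, and a
leading coefficient within 10% of the runner-up raises an ambiguity flag —
the method presumes cleanly assignable local states, and densely mixed
spectra are outside its domain.  A larger basis should not be used blindly:
high modals probe the unphysical tails of the fitted polynomials and can
introduce intruder states; the meaningful check is a plateau of the target
energies against basis size on the scale of the tunneling-matrix elements
(tested).

## The benchmark double well

The fully specified 2D test system is built from two harmonic wells
$V_{L/R}=\tfrac12 (x-x^{(L/R)})^T H^{(L/R)} (x-x^{(L/R)})$,
$H^{(L/R)} = R(\pm\theta)\,\mathrm{diag}(\alpha_1,\alpha_2)\,R(\pm\theta)^T$,
minima at $(\mp\beta,0)$, combined as
$$V = \frac{V_L\,(V_R + d\,\gamma_1)}{\gamma_1 V_L + \gamma_2 V_R},\qquad
\gamma_1 = 1 - d\,\gamma_2 / V_L(x^{(R)}),\quad
\gamma_2 = 1 + d\,\gamma_1 / V_R(x^{(L)}) .$$
The linear system for $(\gamma_1,\gamma_2)$ is the unique choice in this
family for which both minima are *exactly* harmonic with eigenvalues
$(\alpha_1,\alpha_2)$, the right minimum sits exactly at $d$, and each
parameter can be varied without touching the others — the defining
properties of the construction.  A self-check at surface construction
verifies the harmonic limits.  Defaults: $\alpha_{1,L}=1.6$,
$\alpha_{2,L}=4.0$, $\beta=2$, $\theta=\pi/12$ (which balances the $F$- and
$U$-type contributions to the couplings), $m=3.5$ in both dimensions, all
in the model's atomic-like units; sweeps vary $\alpha_{1,R}\in[1.6,36]$,
$\alpha_{2,R}\in[4,49]$ or $d\in[0,1.1]$.

What the benchmark does and does not exercise: it is two-dimensional, has a
single tunneling channel and no rigid-body nullspace, so passing tests show
correctness of the path, transport, Herring and VCI machinery — not the
trans/rot projection or bead-orientation aspects of molecular
applications, for which only unit-level tests (nullspace construction,
idempotence) exist here.

## Numerical choices

* **String optimizer.**  The MAP is found by cycles of L-BFGS minimization
  of the discretized Jacobi action over *perpendicular bead offsets*
  relative to the current chain (the tangential directions of the free
  problem are flat and poison convergence), interleaved with equal-arc-length
  reparameterization through a natural-spline fit of the chain.
  Steepest-descent displacement along the perpendicular action gradient —
  the textbook string update — needs steps bounded by the squared bead
  spacing here and was too slow to reach tight tolerances.  Convergence is
  declared on the textbook criterion regardless: the largest perpendicular
  component of the action gradient, default $10^{-6}$ au, measured on the
  optimized chain before the final resampling.  Defaults: 301 beads (model),
  adaptive step via the line search, straight-line initial guess
  (multi-channel systems need seeded guesses).
* **Arc length** is measured on a refined sampling of the spline curve, not
  the bead polyline, consistently with the spline-interpolated fields
  $V(S)$, $H(S)$, $x(S)$ (natural cubic splines, Hessians stored per bead).
* **Transport integration.**  Fixed-step fourth-order Runge–Kutta, step =
  one tenth of the bead spacing (halving the step changes the widths at the
  connection point by $<10^{-7}$, tested); the width matrix is symmetrized
  after every step, and a negative eigenvalue of the *tangent-projected*
  widths aborts with a location (the unprojected matrix legitimately
  develops a small negative near-tangent eigenvalue past the barrier top,
  tracking $dp_0/dS$).
* **Jump distance** $\epsilon = 0.1$ au (model) and 0.25 au (molecular
  default), configurable.
* **det$'$ thresholds.**  Zero modes in width determinants and in the
  combined plane Gaussian are detected at $10^{-8}\times$ the largest
  eigenvalue and excluded (pseudoinverse / pseudodeterminant).
* **Signs.**  Local wavefunctions are taken positive at their minima; mode
  signs follow a fixed deterministic convention, and the reported spectra
  are invariant to flips (tested via the induced similarity transform).
* **Reference solver.**  Sinc-DVR (uniform grid, unit mass in mass-scaled
  coordinates) with lowest eigenpairs from implicitly restarted Lanczos and
  a separable kinetic matvec.  The box is chosen from classical turning
  points at 1.5$\times$ the barrier plus a generous pad (tails at the walls
  must be negligible — a tight box is the one way this solver converges
  slowly), and a refinement gate ($<10^{-6}$ change on 1.5$\times$ denser
  grids) certifies convergence.  96 points per axis satisfies the gate for
  every benchmark configuration used.

## Problem sizes used in the shipped runs

The test-suite and the acceptance script run the benchmark protocol end to
end: 301-bead paths at $10^{-6}$ au, 96-point DVR grids, VCISD with 8 DVR
points / order-8 fits / 7 basis functions / 6 quanta, crossing searches on
a 9-point bracket grid refined by golden-section search (about 15 extra
evaluations per curve).  These are the configurations all reported numbers
refer to.

## Known limitations

* Rotational motion is neglected throughout; couplings between states whose
  assignment mixes normal modes strongly (flagged by the labeling
  ambiguity check) are outside the method's assumptions.
* The analytic coupling route is restricted to at most one quantum per
  mode; higher excitations go through the quadrature route, whose cost grows
  exponentially with the number of transverse dimensions.
* The semiclassical coupling overestimates splittings when the effective
  barrier is small — on the benchmark, the longitudinally excited doublet
  (effective barrier 0.545 vs 1.221 for the ground state) is overestimated
  by roughly 12%, the known failure mode of the approximation, while
  ground-state and transversally excited splittings are accurate to a few
  percent.
* Molecular surfaces are consumed through the plug-in contract
  (energy/gradient/Hessian callables plus geometry and masses); no
  electronic-structure interface or bundled molecular PES is included.
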