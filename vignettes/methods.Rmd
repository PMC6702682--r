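---
title: "Methods: reparametrized surfaces in sum-of-products form"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reparametrized surfaces in sum-of-products form}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sopes)
```

## The problem

Grid-based quantum dynamics needs the potential energy surface (PES) as a
tensor on a direct-product grid, but a 6-dimensional molecule at 10--30
points per coordinate means $10^7$--$10^9$ grid points --- far too many for
direct electronic-structure evaluation, and far too many to store inside a
wavefunction propagation. `sopes` implements the two-part answer this
package is built around:

1. **Reparametrization.** A fast parametrized energy backend (in the field,
   a semiempirical Hamiltonian; here, any `surface_backend`) is refitted so
   that its parameters $\zeta \in \mathbb{R}^D$ reproduce a small set of
   high-quality reference energies and harmonic frequencies. $D$ depends on
   the backend family, not on the system size, so the approach does not
   inherit the curse of dimensionality through its parameter count.
2. **Tensor decomposition.** The refitted surface is compressed into Tucker
   (sum-of-products) form,
   $V_{i_1 \dots i_f} \approx \sum_{j_1 \dots j_f} C_{j_1 \dots j_f}
   \prod_\kappa v^{(\kappa)}_{i_\kappa j_\kappa}$,
   either exactly from a full-grid tensor (POTFIT) or --- the point of the
   multigrid algorithm --- from coarse and partial grids only, never
   touching the full primitive grid.

## Objective functions and weighting

The fit minimizes a weighted mean-square objective. The two-term form
(`chi0`) keeps energies and frequencies in separate means,

$$\chi_0(\zeta) = \frac{1}{n}\sum_i \omega_E(E_i^{\mathrm{ref}})
\left[E_i^{\mathrm{ref}} - E_i(\zeta)\right]^2
+ \frac{1}{m}\sum_j \omega_F(\Delta F_j)
\left[F_j^{\mathrm{ref}} - F_j(\zeta)\right]^2,$$

while the simpler concatenated form (`chi1`, the default) takes a single
mean over the joined residual vector of length $n+m$. The weights are
exponential step functions, $\omega(x) = 1$ for $x \le \alpha$ and
$e^{\beta(x-\alpha)}$ beyond, continuous at the shoulder. Defaults:
$\alpha_E$ is a barrier-height estimate (falling back to the largest
reference energy), $\beta_E = -10^{-3}$ per cm$^{-1}$, $\alpha_F = 100$
cm$^{-1}$, $\beta_F = -10^{-2}$ --- negative $\beta$ down-weights
high-energy points and large frequency deviations, keeping the fit focused
on the chemically relevant region. The objectives as implemented carry no
square root; the *reported* fit quality (`fit_rmse`) is the square root of
the unweighted mean-square relative-energy residual, which is a different
number and deliberately so.

Two conventions matter in practice:

* **Energy reference.** Both sides of the residual are relative energies.
  The reference geometry defaults to the lowest-energy dataset entry, but
  when a dataset does not contain its own energy zero (displacement grids
  exclude their pivot) the minimum geometry must be passed explicitly ---
  a mismatched zero biases the objective by a constant and demonstrably
  shifts the recovered parameters by several percent.
* **Frequencies.** At each trial $\zeta$ the stationary points are
  re-refined on the trial surface and frequencies compared mode-by-mode
  after ascending sort; no mode tracking across parameter sets is
  attempted. A failed refinement returns a large finite penalty
  ($10^6$, flagged) so derivative-free searches continue.

## Optimization protocol

Stage 1 runs a global multistart search with single-linkage clustering:
seeded uniform starts in the parameter box are ranked by objective value;
walking down the ranking, a start within the (shrinking) critical linkage
distance of an already-explored better point is absorbed into that
cluster, while cluster-distinct starts seed local descents. Local descents
use BOBYQA (bound-constrained quadratic trust-region, via `nloptr`).
Every later stage is local-only, warm-started from the previous stage's
best parameters, on a cumulatively growing dataset.

One numerical choice proved decisive: BOBYQA is run in **box-normalized
coordinates** ($[0,1]^D$). The family's parameters span eight orders of
magnitude (well curvatures $\sim 10^6$, coupling amplitudes $\sim 10^{-1}$),
and a single trust-region radius in raw units stalls far from the optimum;
after normalization the toy recovery experiment converges to machine
precision. Parameters with degenerate bounds (lower equal to upper) are
held fixed rather than passed to the optimizer.

## Reference datasets

Datasets are built from the stationary points outward, in the staged
pattern core $\rightarrow$ +1D $\rightarrow$ +2D $\rightarrow$ +random
full-D $\rightarrow$ +interpolated path $\rightarrow$ +path cloud:

* **Displacement grids** move one coordinate (order 1) or a coordinate
  pair (order 2) off a pivot, levels alternating outward in multiples of a
  per-coordinate step, the pivot itself never duplicated.
* **Interpolated paths** (`liic`) connect stationary points linearly in
  internal coordinates, 50 points per path by default; periodic
  coordinates follow the shorter arc. The path ordinate is normalized to
  $X_i = i/(n-1) \in [0,1]$ so that the endpoint blending of the
  distortion cloud is exact at both ends (the blend
  $(1-X_i)\,Q_\mathrm{init} + X_i\,Q_\mathrm{fin}$ then uses purely the
  initial modes at one end and purely the final modes at the other).
* **Distortion clouds** displace each path point along the blended
  endpoint normal modes with independent uniform factors in
  $(-s, +s)$, default $s = 0.1$; the mode along the path (the torsion-like
  reaction coordinate) is excluded.
* **Energy filtering** is inclusive at the cutoff.

Stage composition and sizes are fully configurable; the six-stage
composition shipped in `stage_template()` is a template, never enforced,
because published per-class counts are not reconstructible from first
principles.

## DVR grids and the multigrid decomposition

Two DVR families are provided. The harmonic (Hermite) DVR diagonalizes the
position operator in the lowest-$N$ oscillator basis and linearly rescales
the nodes so the outermost coincide with the requested range; the kinetic
matrix is the conjugated $P^2$ matrix, exact in that basis. The cosine DVR
uses the even particle-in-a-box basis with equidistant midpoint nodes
(DCT-II transform), suited to a torsion over $[0, \pi]$. Grid indices are
1-based with closed ranges throughout, including in the SOP file format.

Exact POTFIT forms, per degree of freedom, the potential density matrix
$\rho^{(\kappa)}_{kk'} = \sum_{I^\kappa} V_{I^\kappa k} V_{I^\kappa k'}$
(the Gram matrix over all other coordinates) and keeps its leading
eigenvectors as natural potentials. Truncation error over the grid equals
the sum of discarded eigenvalues for single-mode truncation and is bounded
by the total discarded weight in general --- both used as test oracles.

The multigrid route never evaluates the full grid. With coarse index sets
(every $k$-th fine point, from the first; an endpoint-including policy is
also available) it evaluates the backend on the coarse product grid (the
core tensor $V$) and on each per-DOF partial grid (fine along one
coordinate, coarse along the rest), then forms
$\tilde\gamma^{(\kappa)} = \rho^{(\kappa)\prime}\,\rho^{(\kappa)-1}$
from the mixed fine-by-coarse and coarse density matrices, and assembles
$\tilde V = V \times_1 \tilde\gamma^{(1)T} \cdots \times_f
\tilde\gamma^{(f)T}$. The inverse is an eigenvalue-thresholded
pseudo-inverse with a relative threshold of $10^{-12}$ of the largest
eigenvalue (the reconstruction is exactly interpolatory on the coarse
points up to this tolerance). Backend calls are cached by grid index and
evaluated in lexicographic order, so call counts are exactly
$|{\rm coarse}| + \sum_\kappa (|{\rm partial}_\kappa| - |{\rm coarse}|)$
and logs are reproducible. All degrees of freedom are treated
symmetrically; no separately contracted mode is implemented.

Published coarse-grid point counts for the 6D benchmark system are *not*
reproduced by any straightforward stride rule applied to the published
grid table; coarse counts here are therefore always configuration-derived
and reported, never hard-coded or asserted.

## The toy surface family

The built-in fixture generator is a torsion-coupled chain,

$$V = \sum_\kappa \tfrac{1}{2} a_\kappa (q_\kappa - r_\kappa(\phi))^2
+ \sum_{\kappa<\lambda} b_{\kappa\lambda}(q_\kappa - r_\kappa)(q_\lambda -
r_\lambda) + c_1(1 - \cos\phi) + c_2(1 - \cos 2\phi),
\qquad r_\kappa(\phi) = q0_\kappa + d_\kappa \cos\phi .$$

With $c_1 = 0$ it is a symmetric double well in the torsion (a cis/trans
surrogate) with barrier exactly $2 c_2$ at $\phi = \pi/2$ on the relaxed
chain, and analytic minima and saddle --- every test oracle about
stationary points is closed-form. The reference instance draws, per seed:
chain curvatures $a_\kappa \in [3 \times 10^5, 2 \times 10^6]$ (harmonic
wavenumbers of roughly 550--1400 cm$^{-1}$ at unit mass), barrier
$2c_2 \in [3000, 5000]$ cm$^{-1}$ (torsional wavenumber
$\sqrt{4c_2} \approx 80$--100 cm$^{-1}$), torsional well shifts
$d_\kappa \in [0.04, 0.12]$ length units, and bilinear couplings up to 10%
of the geometric-mean curvature. These magnitudes were chosen once to
mirror a small covalent molecule with a hindered internal rotation and are
not tuned thereafter. Parameter-recovery experiments use $\pm 50\%$ boxes
around the reference parameters and multiplicative 20% perturbed starts.

The quadratic family is a *polynomial* in each coordinate and in
$\cos\phi$, hence exactly low-rank in Tucker form --- decomposition error
at any sensible coarse grid is roundoff, which makes it useless for
studying error versus coarse-grid density. The `morse = TRUE` variant
replaces each chain well by a Morse well of identical bottom curvature
($D_\kappa(1 - e^{-\beta_\kappa u})^2$, $D_\kappa = a_\kappa /
2\beta_\kappa^2$, $\beta_\kappa \in [2, 4]$), which preserves every
stationary-point oracle while giving genuine Tucker rank growth; the
stride-dependence studies use this variant.

What the toy emulates: a multi-well torsional landscape, mode coupling
through both bilinear terms and torsion-dependent well positions,
realistic energy scales, and (in the Morse variant) anharmonicity. What it
does not emulate: real electronic structure (no electronic failure modes,
no SCF noise), curvilinear kinetic couplings, permutational symmetry, or
dissociation channels. Passing recovery tests on the toy shows the
machinery is correct and well-conditioned, not that a particular
semiempirical family can reach chemical accuracy for a given molecule.

## Validation layers

* **Harmonic analysis.** Hessians by central differences (step $10^{-3}$
  in native units, Richardson-extrapolated variant available),
  symmetrized; frequencies as
  $\mathrm{sign}(\lambda)\sqrt{|\lambda|}$ of the mass-weighted Hessian
  eigenvalues, imaginary modes printed as negative reals (a transition
  state shows exactly one). In the package's natural-unit convention
  ($\hbar = 1$, energies in cm$^{-1}$, unit masses) this is already a
  wavenumber; conversion constants for hartree/bohr/amu Hessians are
  tabulated in `unit_constants` at full CODATA precision.
* **Classical trajectories.** Microcanonical normal-mode sampling
  distributes the requested energy over modes by a seeded uniform simplex
  draw with random phases (the exact distribution of the historical
  sampling option is unspecified in the sources this package follows;
  this scheme is the documented stand-in). The harmonic partition is
  exact; the anharmonic residual is logged. Velocity-Verlet propagation
  converts femtoseconds into the natural time unit
  ($1\,\mathrm{fs} = 2\pi c \times 10^{-15}$ inverse-wavenumbers,
  so a 1000 cm$^{-1}$ mode has a 33 fs period). Trajectories store every
  frame including $t = 0$ (a 1 ps run at 5 fs is 201 frames) and report
  two conservation numbers: the bounded energy *fluctuation*
  ($\approx (\omega\,\Delta t)^2/4$ relative for a harmonic mode --- an
  irreducible property of the integrator, about $10^{-3}$ at
  $\Delta t = T/100$) and the secular *drift* (final vs initial energy,
  $\sim 10^{-7}$ over ten periods), which is the quantity a symplectic
  integrator keeps small and the one asserted in tests.
* **Vibrational eigensolutions.** For up to three degrees of freedom, a
  dense direct-product Hamiltonian
  $H = \sum_\kappa T^{(\kappa)}/2m_\kappa \otimes I + \mathrm{diag}(V)$ is
  diagonalized outright; this replaces multiconfiguration relaxation
  machinery, which is out of scope, and the kinetic operator is
  diagonal-mass Cartesian-like (no curvilinear terms). Level-ladder
  comparisons (`eigen_rmse`) include the zero ground-state row, which is
  the convention that reproduces the published benchmark RMSE values
  (360.2 / 58.4 / 24.5 cm$^{-1}$ for the shipped HONO tables); the
  accompanying `mad` is the mean absolute deviation --- the published MAD
  row for those tables matches no convention we could identify and is not
  asserted anywhere. Spectra are computed as windowed Fourier transforms
  of the autocorrelation of a spectrally propagated state; peaks are local
  maxima above 5% of the spectrum maximum, i.e. above the Hann-window
  sidelobe level (2.7%).

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
instances sized for a single CPU: 3-DOF toys, full grids up to $22^3$,
multigrid decompositions on $15 \times 15 \times 16$ grids at strides 5,
3, 1, dense eigenproblems up to dimension $\approx 2300$, ten-seed
recovery experiments with $\sim 2000$-evaluation global and
1500-evaluation local budgets, and an 80-trajectory census at 200 steps
each. These sizes are the package's own defaults for its validation
studies; every one of them is a configuration knob.

## Known limitations

* The dense eigensolver stops at three degrees of freedom; for the full
  6D pipeline the deliverable is the decomposed SOP file.
* The external-program adapter shells out one process per geometry;
  it caches by (geometry, parameters) but does not batch.
* MLSL here is the documented multistart-plus-single-linkage scheme, not
  a drop-in replica of any particular library implementation; its cluster
  report is part of the returned object.
* Only direct-product grids and two DVR families (harmonic, cosine) are
  supported; no FFT/exponential, sine or Legendre DVRs, and no
  non-direct-product or mode-combined grids.
* The interpolated reaction path is linear in internal coordinates; no
  intrinsic-reaction-coordinate integration on the surface is attempted.
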