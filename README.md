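# sopes — sum-of-products potential energy surfaces

`sopes` is an R toolkit for building grid-based molecular potential energy
surfaces (PES) in Tucker / sum-of-products (SOP) form — the representation
grid-based quantum dynamics methods require — from a cheap *parametrized*
energy backend, for people who work on vibrational dynamics of small
molecules (multi-well torsional systems, isomerization problems) and need a
full-dimensional surface without millions of electronic-structure calls.

It implements, end to end:

1. **Backend reparametrization.** The backend's parameters
   ζ ∈ ℝᴰ (D independent of system size) are refitted against reference
   energies and harmonic frequencies by minimizing a weighted mean-square
   objective

   χ(ζ) = (1/n) Σᵢ ω_E(Eᵢ) [Eᵢ − Eᵢ(ζ)]² + (1/m) Σⱼ ω_F(ΔFⱼ) [Fⱼ − Fⱼ(ζ)]²

   with exponential step weights ω(x) = 1 for x ≤ α, e^{β(x−α)} beyond,
   using a multistart single-linkage global stage followed by
   warm-started BOBYQA local stages on cumulatively growing datasets.
2. **Staged reference sets.** Displacement grids (1D/2D) around stationary
   points, seeded random full-dimensional points, linear interpolation
   paths in internal coordinates between minima and saddle (with
   shorter-arc handling of periodic coordinates), normal-mode distortion
   clouds around the path, and inclusive energy filtering.
3. **Tensor decomposition.** Exact POTFIT (eigenvectors of potential
   density matrices ρ^(κ) = Σ_{I^κ} V_{I^κ k} V_{I^κ k'}) and the
   multigrid variant, which evaluates the backend only on a coarse
   direct-product grid and per-coordinate partial grids and extends the
   coarse core tensor with γ̃^(κ) = ρ^(κ)′ ρ^(κ)⁻¹ — never touching the
   full primitive grid.
4. **Validation.** Numerical Hessians and harmonic frequencies, Newton
   refinement of stationary points, microcanonical normal-mode sampling
   with velocity-Verlet trajectories, and a dense DVR eigensolver (≤ 3
   degrees of freedom) with level-ladder RMSE metrics and autocorrelation
   spectra.

A documented plain-text SOP file format, an analytic torsion-coupled toy
surface family (with closed-form minima, saddle and barrier, and an
optional Morse-anharmonic variant), and an adapter for external energy
programs round out the package. See `vignettes/methods.Rmd` for the
science and every numerical convention.

## Worked example

Decompose an anharmonic 3-DOF toy surface on a 15×15×16 DVR grid using
only coarse and partial grids (stride 3), then solve a 2D vibrational cut:

```r
library(sopes)

s <- toy_reference(seed = 0, f = 3, morse = TRUE)
s
#> toy torsion surface: 3 DOFs (2 chain + torsion), barrier 2*c2 = 4889.4 cm-1

toy_stationary_points(s)$ts
#> stationary point (ts), E = 4889.3505 cm-1
#>   frequencies (cm-1): -98.3 864.8 1357.7

grids <- default_toy_grids(s, n_chain = 15, n_phi = 16)
mg <- make_multigrid(grids, stride = 3)
mg
#> multigrid: 3 DOFs, stride 3 (from_first)
#>   primitive sizes: 15 x 15 x 16
#>   coarse sizes:    5 x 5 x 6  (150 points)

dec <- mgpf_decompose(s, mg, rmse_sample = 300, rmse_seed = 1)
dec
#> MGPF decomposition: 1000 backend calls, ranks 5x5x6
#>   sampled RMSE 0.0262 (n = 300)

write_sop(dec$potential, "pes.sop")
```

1000 backend calls instead of the 3600 full-grid points, and the
decomposed surface reproduces the backend to 0.03 cm⁻¹ (RMSE over 300
random grid points) on a surface whose barrier is ~4900 cm⁻¹. The single
negative frequency (−98.3 cm⁻¹) is the transition-state signature; the
printed barrier is exactly `2 * c2` of the family.

A 2D cut through the (stretch, torsion) plane, diagonalized on the grid:

```r
cut <- function(q) surface_energy(s, c(q[1], s$q0[2] + s$d[2] * cos(q[2]), q[2]))
H <- build_hamiltonian(grids[c(1, 3)], s$masses[c(1, 3)], cut)
lowest_eigenpairs(H, 6)
#> eigenreport: ZPE = 737.2881 cm-1, 6 levels
#> [1]    0.00    0.72  388.55  389.61 1063.96 1064.71
```

The near-degenerate pairs (splittings 0.7–1 cm⁻¹) are the tunneling
doublets of the symmetric torsional double well.

The whole pipeline — reference-set generation, staged refit from a
perturbed start, decomposition, eigensolution, reports — runs from one
configuration via `run_pipeline()`; `report(run_dir)` prints the stage
ledger, level comparison, cumulative-RMSE curve and parameter-deviation
table.

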