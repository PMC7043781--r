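# critnet

Folded proteins are strange elastic objects: a perturbation at one
residue is felt by residues on the far side of the molecule, no matter
how large the protein is. `critnet` is an R package for testing whether
that long-range correlation is encoded purely in the *native contact
topology*, by putting proteins on a common footing with the two systems
that bracket them — ordered lattices and disordered ideal polymers — and
comparing how their dynamical and topological descriptors scale with
size.

It is aimed at structural bioinformaticians and biophysicists who work
with elastic network models and want reproducible, tested finite-size
scaling analyses rather than one-off scripts.

## What it computes

A structure (Cα trace of a PDB chain, or a generated reference system)
becomes a contact network with Kirchhoff (graph Laplacian) matrix
Γ: Γᵢⱼ = −1 for residue pairs with rᵢⱼ ≤ r_C, Γᵢᵢ = degree. From it:

* **Slow modes** — the spectrum of the symmetric normalized Laplacian
  L = D^(−1/2) Γ D^(−1/2); the smallest nonzero eigenvalue λ₁ is the
  slowest collective mode, and its size dependence λ₁ ∼ N^(−ζ)
  discriminates lattices (ζ ≈ 0.73), proteins (ζ ≈ 1), and ideal
  polymers (ζ ≈ 1.7).
* **Correlations** — the GNM covariance C ∝ Γ⁺ (pseudoinverse), the
  cross-correlation φᵢⱼ = Cᵢⱼ/√(Cᵢᵢ Cⱼⱼ), the distance-binned
  correlation function φ(r), its first zero crossing ξ (the correlation
  length), and the finite-size susceptibility
  χ = (s/N) Σᵢ<ⱼ φᵢⱼ θ(ξ − rᵢⱼ).
* **Topology** — the average shortest-path length ⟨l⟩ ∼ N^α and the
  Louvain-maximized modularity, which follows the lattice law
  Q = 1 − K·N^(−η) with η = 1/(d+1), so an effective fractal dimension
  d_eff = 1/η − 1 can be read off a size ladder.
* **Geometry** — radius of gyration and the inertia-ellipsoid shape
  factor s = N a³/(L₁L₂L₃), a = 3.8 Å.

Generators for near-spherical fcc clusters (springs to 1st + 2nd
neighbor shells), cubic lattices, and freely-jointed ideal chains supply
the reference systems, and `fit_power_law()` / `fit_modularity_scaling()`
extract exponents by log-log regression. The methods vignette
(`vignettes/critnet-methods.Rmd`) documents every model, convention and
numerical tolerance.

## Worked example

Analyze one generated fcc cluster end to end, then a small size ladder:

```r
library(critnet)

fcc <- generate_fcc_cluster(500)
cfg <- analysis_config(max_n = 5000, springs = "shells", seed = 2)
run_structure(fcc, cfg)
#>   source_id   N       rg mean_path    lambda1        s      chi         q
#> 1  fcc_n500 500 12.92374  4.776577 0.05668046 5.908158 25.59616 0.5870826
#>   n_communities       xi censored_xi r_cut_corr r_cut_topo reason
#> 1             8 14.05522       FALSE   5.977902   5.977902

run_dataset(lapply(c(64, 128, 256, 512, 1024), generate_fcc_cluster),
            analysis_config(max_n = 5000, springs = "shells"))
#> <dataset_report> 5 structure(s), 0 skipped
#>   zeta         exponent 0.6837 +/- 0.0059 (R^2 = 1.000, n = 5)
#>   alpha        exponent 0.3351 +/- 0.0015 (R^2 = 1.000, n = 5)
#>   eta          exponent 0.1994 +/- 0.0070 (R^2 = 0.996, n = 5)
#>   chi_exponent exponent 0.8162 +/- 0.0231 (R^2 = 0.998, n = 5)
#>   xi_vs_rg     exponent 1.0492 +/- 0.0356 (R^2 = 0.997, n = 5)
```

Reading the row: the 500-site cluster has radius of gyration 12.9 Å,
slowest nonzero normalized-Laplacian mode λ₁ ≈ 0.057, shape factor 5.9
(densely packed, as a compact crystal should be), correlation length
14.1 Å — slightly above Rg, the scale-free signature — and Louvain
modularity 0.59. The ladder fits then show the lattice fingerprints:
⟨l⟩ grows as N^(1/3) and λ₁ decays with ζ close to the 2/3 expected
from maximum-wavelength arguments, while ξ tracks Rg with slope ≈ 1.

Protein input works the same way: `run_structure("file.pdb", cfg)` parses
the first protein chain's Cα trace (`parse_structure()` exposes
`chain_id` and `model_index`, resolves altlocs by occupancy, ignores
HETATM) and applies the 30 ≤ N ≤ 1200 chain-length filter.

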