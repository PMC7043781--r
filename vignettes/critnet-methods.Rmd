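---
title: "Models and methods behind critnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind critnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critnet)
```

`critnet` asks a structural question with a statistical-physics answer: why
can a local perturbation at one residue of a folded protein be felt at
residues far across the molecule? The package's working hypothesis is that
these long-range correlations are encoded in the *native contact topology*
alone. Everything in the package serves one workflow: turn a coordinate
set (a protein Cα trace, or a generated reference system) into an elastic
network, extract dynamical and topological descriptors from that network,
and compare how the descriptors scale with system size across ordered
(lattice), disordered (ideal polymer) and protein-like systems.

## The elastic network model

A structure of $N$ residues is reduced to its Cα positions. In the
Gaussian network model (GNM), every residue pair within a cutoff distance
$r_C$ is joined by a harmonic spring of uniform strength, giving the
potential

$$V = \frac{\kappa}{2}\sum_{i,j}\Delta\vec r_i\,\Gamma_{ij}\,\Delta\vec r_j,$$

where $\Gamma$ is the Kirchhoff matrix — the graph Laplacian of the
contact network: $\Gamma_{ij} = -1$ for contacts, $0$ otherwise, and
$\Gamma_{ii}$ equal to the contact degree. `build_kirchhoff()` constructs
it; the spectrum is positive semi-definite with one zero mode per
connected component.

Two cutoff conventions are carried side by side, following common
practice for the two descriptor families: **9 Å** for the
correlation/spectrum family and **8 Å** for the topology family. Both are
plain arguments of `analysis_config()`, and 6–15 Å sweeps are supported;
the scaling *exponents* studied here are insensitive to the choice, while
absolute descriptor values are not.

A parameter-free variant (`model = "pf_gnm"`) connects *all* pairs with
spring constants $r_{ij}^{-2}$. It is included deliberately as a negative
control: it runs through the whole pipeline, but it is known not to
reproduce the scaling relations that the cutoff GNM produces, so no test
asserts agreement for it.

### Mode spectra and the normalized Laplacian

Comparing spectra across sizes requires a degree normalization,

$$L = D^{-1/2}\,\Gamma\,D^{-1/2},$$

whose eigenvalues lie in $[0, 2]$ (`normalized_laplacian()`). All scaling
analyses in the package use $\lambda_1$, the smallest *nonzero* eigenvalue
of $L$ — the slowest collective mode. The raw-$\Gamma$ spectrum remains
available (`lambda1(net, normalized = FALSE)`), since the normalization
choice for reported eigenvalues is a convention, not a theorem.

Numerical choices worth knowing:

* zero modes are detected with a *relative* tolerance
  $10^{-9}\lambda_{\max}$ (with $\lambda_{\max}$ bounded by Gershgorin's
  theorem), so the detection is stable from $N = 3$ to $N = 5000$;
* partial spectra on large sparse systems use a Lanczos iteration on the
  shifted operator $bI - L$ ($b$ the Gershgorin bound), whose *largest*
  eigenpairs are the smallest eigenpairs of $L$. The suite checks the
  sparse and dense solvers agree on $\lambda_1$ to $10^{-8}$; on failure
  to converge the code silently falls back to the dense path;
* eigenvector orthonormality is asserted at $10^{-8}$.

### Covariance, correlations, susceptibility

The GNM covariance is the Moore–Penrose pseudoinverse of $\Gamma$, with
the physical prefactor $3k_BT/\kappa$ set to one — every downstream
quantity is scale-free in it. For a connected network the pseudoinverse
is computed exactly as $(\Gamma + J/N)^{-1} - J/N$ ($J$ the all-ones
matrix); the tests verify the pseudoinverse identities and an independent
spectral-sum oracle. Disconnected networks are an error by design: a
pseudoinverse across components mixes fluctuations that share no springs.

Cross-correlations are $\phi_{ij} = C_{ij}/\sqrt{C_{ii}C_{jj}}$. The
distance-dependent correlation function $\phi(r)$ averages $\phi_{ij}$
over unordered pairs in half-open distance bins $[kw, (k+1)w)$ with
$w = 1$ Å by default (the published curves are smooth at ångström
resolution; $w$ is a config knob). A pair exactly on an edge belongs to
the upper bin.

The correlation length $\xi$ is the first zero crossing of $\phi(r)$,
located by linear interpolation between the last positive and first
non-positive occupied bins — interpolation de-noises small systems
relative to taking the first negative bin. Profiles that never cross zero
return the largest occupied bin center flagged `censored`; censored
values are excluded from scaling fits rather than treated as measurements.

The finite-size susceptibility is

$$\chi = \frac{s}{N}\sum_{i<j}\phi_{ij}\,\theta(\xi - r_{ij}),$$

with a *strict* Heaviside step (pairs at exactly $r_{ij} = \xi$ are
excluded; at 1 Å binning the choice is immaterial beyond ties, but it is
fixed and documented). Each structure uses its own $\xi$.

### Shape factor

The shape factor measures residue packing density inside the inertia
ellipsoid: $s = N a^3 / (L_1 L_2 L_3)$ with $a = 3.8$ Å the residue size.
The axis lengths are taken as $L_i = \sqrt{5\mu_i}$ from the
gyration-tensor eigenvalues $\mu_1 \ge \mu_2 \ge \mu_3$ — the semi-axes
of the uniform solid ellipsoid with the same gyration tensor. This is a
genuine convention choice (full axes instead of semi-axes would divide
$s$ by 8); the semi-axis convention is adopted because it reproduces the
published per-protein shape factors for single-structure worked examples,
and because it makes $s \to N a^3 / R^3$ exact for points filling a ball
of radius $R$, which the test suite verifies by Monte Carlo. Degenerate
(collinear or coplanar) inputs raise an error rather than returning an
infinite density.

## Topology descriptors

Both descriptors act on the *binary* contact graph, whatever the spring
model, because they characterize contact topology rather than energetics.

* `average_path_length()` is the exact BFS mean over ordered pairs up to
  $N = 2000$; above that it averages BFS trees from 1000 fixed-seed
  sampled sources, an estimator that is unbiased over sources. Sampled
  results carry a `sampled` attribute.
* `modularity_q()` implements the Newman modularity
  $Q = \sum_c [m_c/M - (K_c/2M)^2]$ on unit-weight edges; the two-module
  spin form is its special case, and the suite cross-checks it against
  both a direct adjacency-matrix oracle and an independent library
  implementation.
* `best_partition()` maximizes $Q$ with the Louvain multilevel heuristic,
  best of 10 restarts with derived sub-seeds (restart count and
  tie-handling are not standardized anywhere; max-of-10 with
  first-restart tie-break is this package's fixed policy, and results are
  deterministic given the seed). On graphs small enough to enumerate,
  the tests require the Louvain optimum to match exhaustive search over
  set partitions.

## Reference systems

The generators define the study conditions; they are first-class, tested
code.

* **fcc clusters** (`generate_fcc_cluster()`): the $N$ fcc sites nearest
  the origin — a near-spherical carve, chosen over cubes of unit cells
  because cluster shape affects scaling prefactors but not exponents.
  Springs connect the 1st and 2nd neighbor shells
  (`build_lattice_springs()`, shell radii found by distance ranking, not
  hard-coded, so any spacing works). Interior coordination is 12 + 6.
* **cubic lattices** (`generate_cubic_lattice()`): full open-boundary
  grids.
* **ideal chains** (`generate_ideal_chain()`): freely-jointed
  fixed-bond random walks, bond $b = 3.8$ Å, no excluded volume —
  "ideal" is read literally, which pins $\langle R^2\rangle = (n-1)b^2$
  (tested against the closed form). The 3.8 Å bond matches the Cα
  virtual-bond scale so protein cutoffs transfer unchanged.

Default spacing 3.8 Å everywhere; the suite confirms the exponents are
invariant to coordinate rescaling, as they must be.

## Scaling analysis

All exponents come from unweighted ordinary least squares on
$(\log_{10} x, \log_{10} y)$ (`fit_power_law()`), matching the field's
straight-line-on-log-log practice; standard errors are reported so
tolerance checks are principled, and maximum-likelihood tail fitting is
deliberately out of scope. Modularity uses the lattice finite-size law
$Q = 1 - K N^{-\eta}$ (`fit_modularity_scaling()`), and
`effective_dimension()` inverts $\eta = 1/(d+1)$ into
$d_{\mathrm{eff}} = 1/\eta - 1$. When an ensemble has several
realizations per size, fits run on per-size means; per-realization rows
are retained by `run_dataset()`.

### Problem sizes and what the checks show

The reproduction suite runs entirely on generated systems, at sizes the
package chose as its desk-scale ladders: fcc $N \in \{64,\dots,4096\}$
for the slow mode and path length, $\{100,\dots,5000\}$ for modularity;
open cubic grids $4^3$–$12^3$; freely-jointed chains
$N \in \{64,\dots,2048\}$ with 20 seeds per size. The slow-mode
exponents, the path-length exponents, and the fcc/polymer modularity
exponents are checked against their published values at stated
tolerances; `scripts/acceptance.R` recomputes the same quantities from
scratch.

Two systematic finite-size effects deserve honesty:

* **Open-boundary modularity.** The law $\eta = 1/(d+1)$ is an
  asymptotic statement for optimal partitions. On open-boundary grids at
  desk scale, boundary modules lose fewer edges than interior ones, which
  raises $Q$ at small $N$ and flattens the fitted slope below the
  asymptotic $1/4$ — an effect visible no matter how good the optimizer
  is. The cubic-lattice check therefore sits below its theoretical
  target in this implementation, and is reported as such rather than
  patched.
* **Polymer ensembles are heavy-tailed.** $\langle l\rangle$ and
  $\lambda_1$ of a random-walk contact network vary enormously between
  conformations (compact walks are small worlds, extended walks are
  chains). With 20 seeds per size, fitted polymer exponents move by
  $\pm 0.1$ between independent ensembles; the published polymer values
  were obtained with an unpublished generation protocol, and the
  freely-jointed default recorded above is this package's stated
  assumption.

## What the generators do not emulate

Lattices and ideal chains bracket proteins from the ordered and
disordered sides; neither has secondary structure, side-chain packing
heterogeneity, missing residues, or crystallographic artifacts (altloc
records, multiple chains) — the parsing layer handles those for real
PDB input, but passing the generator-based tests says nothing about
force-field realism beyond contact topology. Anisotropic ($3N \times 3N$)
elastic models, B-factor fitting, and NMR-ensemble correlation analysis
are out of scope.

## A compact example

```{r example, eval = FALSE}
fcc <- generate_fcc_cluster(500)
cfg <- analysis_config(max_n = 5000, springs = "shells", seed = 2)
run_structure(fcc, cfg)

report <- run_dataset(lapply(c(64, 128, 256, 512), generate_fcc_cluster),
                      analysis_config(max_n = 5000, springs = "shells"))
report$fits$zeta
```
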