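---
title: "Continuous structural connectivity: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous structural connectivity: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surfconn)
```

## The model

Tractography represents white-matter fibers as streamlines; `surfconn`
uses only their two endpoints, which lie on (or near) the white surface of
each hemisphere. The scientific object is a symmetric probability density
$p(x, y)$ on $\Omega \times \Omega$, where $\Omega = \Omega_L \cup
\Omega_R$ is the pair of hemisphere surfaces, each treated as a compact
2-manifold without boundary. Treating the hemispheres as closed surfaces
is a deliberate simplification: each has a physical boundary at the medial
wall, but closed-manifold numerics are far better behaved, and the medial
wall is excluded afterwards by masking the estimated matrix
(`apply_medial_mask()`, applied post-estimation and without
renormalization — the normalization invariants below therefore refer to
the pre-mask estimate).

Given $N$ endpoint pairs $(s_{1j}, s_{2j})$, the symmetrized kernel
density estimator is

$$\hat p(x, y) = \frac{1}{2N} \sum_{j=1}^{N}
  \left[ k(x, s_{1j})\,k(y, s_{2j}) + k(x, s_{2j})\,k(y, s_{1j}) \right].$$

Because a Gaussian in geodesic distance is not positive definite on
nontrivial compact manifolds, kernels are instead built spectrally from
the Laplace–Beltrami operator (LBO): with eigenpairs $-\Delta f_m =
\lambda_m f_m$ the kernel matrix on the mesh vertices is
$K = F\,\Phi(\Lambda)\,F^\top$, where $\Phi$ is the family's spectral
weight:

* diffusion (heat): $\Phi(\lambda) = \exp(-\kappa^2 \lambda / 2)$,
* Matérn in dimension 2: $\Phi(\lambda) = (2\nu/\kappa^2 +
  \lambda)^{-\nu - 1}$.

As $\nu \to \infty$ the normalized Matérn weights converge to the
diffusion weights (`matern_limit_check()` quantifies the rate). The
spherical heat kernel (SHK) — the heat kernel of the *unit sphere*,
evaluated through a truncated Legendre series — is provided as the
baseline used by spherical-mapping approaches. Points on different
hemispheres get kernel value zero, so the full kernel is block diagonal
(`block_kernel()`).

On a mesh with $M$ vertices, with $A$ the sparse matrix of streamline
counts between snapped endpoint vertices, the whole estimator is

$$P = \frac{1}{2N}\, K A K^\top,$$

algebraically identical to the double loop above but three matrix products
instead of $O(M^2 N)$ kernel evaluations. `smooth_exact()` implements the
loop as a reference oracle; the identity is asserted to $10^{-12}$ in the
tests.

## Parameters

| Parameter | Meaning | Units | Default / grid |
|---|---|---|---|
| `kappa` | diffusion/Matérn bandwidth (spatial correlation length) | mesh length units | grid of 10 log-spaced values, 0.6252–18.9204 (cortical mm scale) |
| `sigma` | SHK bandwidth | unitless (unit sphere) | grid of 10 values, 0.0001–0.05 |
| `nu` | Matérn smoothness | — | user-set; no default |
| `M_T` | spectral truncation | — | all computed eigenpairs; conventionally the coarse vertex count (2562 on an ico4 mesh) |
| `tol` | SHK series threshold | — | 0.001, giving `J = 368` at `sigma = 1e-4` and `J = 14` at `sigma = 0.05` |

Bandwidth endpoints follow the convention that the two families' influence
radii on a sphere are comparable; on the unit sphere the correspondence is
exact, $\sigma = \kappa^2/2$. Whether the $\sigma$ grid should be log- or
linearly spaced is genuinely open; log spacing is the default (matching
the $\kappa$ grid and the multiplicative role of a bandwidth), linear is
available via `bandwidth_grid(spacing = "linear")`.

**Normalization.** The spectral representation leaves a free constant. We
define `unit_mass` normalization $\tilde\Phi = \Phi/\Phi(0)$, which makes
every kernel integrate to exactly 1 over its hemisphere against the
lumped vertex areas — precisely what a KDE kernel must do, and the source
of the testable invariants: mass-weighted row sums of $K$ equal 1, and the
mass-weighted double sum of $P$ equals 1 before masking. `raw` exposes the
unnormalized sum. Truncated spectral sums can dip slightly negative far
from the diagonal; those entries are *kept* (clamping would silently break
the integrals); the minimum entry is shown by `print()`.

## Discretization and eigensolvers

The LBO is discretized with the cotangent stiffness matrix and, by
default, the lumped (barycentric) vertex-area mass. Lumping makes the mass
diagonal, which gives an exactly constant first eigenvector and the exact
quadrature identities used throughout. The full linear-FEM (consistent)
mass is available as `mass_type = "consistent"` for eigenvalue studies:
the two discretizations err in opposite directions at the top of the
spectrum (lumped underestimates, consistent overestimates), which matters
when reading log-log eigenvalue plots. On a closed 2-manifold, Weyl's law
gives $\lambda_m \sim (4\pi/\mathrm{area})\, m$, i.e. slope 1 in
$\log\lambda$ vs $\log m$; `weyl_slope()` is the corresponding
diagnostic. Mid-spectrum slopes near 1 certify the discretization; ranges
reaching a coarse mesh's resolution limit show visible distortion
(inflated slope under consistent mass), which is why eigenvectors are best
computed on a fine mesh and carried to the analysis mesh by the nested
vertex correspondence (`downsample_basis()`). Downsampled eigenvectors are
used as-is by default — restriction to a subset of vertices only
approximately preserves mass-orthonormality, and both conventions are
defensible — with `reorthonormalize = TRUE` opting into an exact
Gram-correction.

Two eigensolver paths exist. Small meshes and near-full spectra use a
dense LAPACK solver with index-range extraction. Large meshes with
truncated spectra use shift-invert: the shifted operator is factored once
(sparse Cholesky) and a block-Krylov basis of its inverse fourth power is
built with full two-pass reorthogonalization, followed by Rayleigh–Ritz on
the stiffness form and explicit residual verification. The block size (8)
exceeds the largest exact eigenvalue multiplicity of icosahedrally
symmetric meshes (5), so degenerate clusters are resolved. The default
relative-residual tolerance is $10^{-7}$: the scheme's practical floor
sits near $10^{-8}$ at eigenvalue-cluster boundaries (normalizing tiny
novel Krylov directions amplifies projection rounding), and since
eigenvalue error scales as the squared residual, $10^{-7}$ leaves solver
error orders of magnitude below the FEM discretization error (about 1% at
the spectral depths used here). The two paths agree to $10^{-13}$ on
shared problems in the test suite. The iterative path's starting block is
drawn from an explicit seed; all returned spectra are deterministic given
that seed, and the Weyl slope reported by `scripts/acceptance.R` is stable
across seeds.

Further numerical conventions: $\lambda_0$ is clamped to exactly 0 when
below $10^{-8}$ (the analytic nullspace); the constant mode's sign is
fixed positive (all downstream kernels are quadratic in the eigenvectors,
hence sign-invariant — tested by random sign flips); endpoint snapping
uses Euclidean (chordal) nearest-vertex distance with exact ties broken by
the lowest vertex index; vertex indices are 0-based everywhere, with file
readers converting as needed; no distance cutoff rejects far-off
endpoints.

## The synthetic-data generator

`two_bundle_scenario()` defines the packaged ground truth: on a unit
icosphere (subdivision 3, 642 vertices), two equal-weight "bundles", each
connecting a pair of base-icosahedron vertices, with spatial spread given
by a diffusion kernel of bandwidth 0.3 (about 17 degrees of arc — a
bundle footprint in the range of a major association tract rendered on a
unit sphere). Bundle profiles are unit-mass diffusion-kernel columns, so
the truth is band-limited, exactly representable on the mesh, and
renormalized to exact unit mass. `sample_endpoints()` draws unordered
vertex pairs from the discrete distribution $\pi(i,j) \propto p(i,j)\,
m_i m_j$ — unordered because the estimator is symmetrized.
`make_scan_collection()` adds subject structure: per-subject log-normal
perturbation of bundle weights and Gaussian jitter of bundle centers
(snapped back to the mesh), then independent endpoint samples per scan.
Every stochastic routine takes an explicit seed; there is no hidden RNG
state.

What the generator emulates: endpoint clustering into bundles, sampling
noise at realistic streamline counts, controlled intra- vs inter-subject
variation, and traits tied to connectivity parameters. What it does not:
cortical folding geometry (the fixture is a sphere), spherical-registration
distortion, tractography biases (gyral bias, false-positive bundles), or
spatially correlated scanner noise. Two consequences matter when reading
the tests. First, on a sphere the SHK *is* the diffusion kernel (the
addition theorem turns the spectral sum into the Legendre series), so
SHK-vs-diffusion contrasts here only measure discretization error — the
substantive family contrast that survives on the sphere is
diffusion vs Matérn, and the packaged small-sample comparison tunes each
family's bandwidth on a shared grid before comparing (a fixed $\kappa$ is
not a fixed amount of smoothing across families). Second, passing tests
certify the estimator and its calibration under the generator's
assumptions, not performance on cortical data.

## Reliability, inference, prediction

`dicc()` implements the distance-based intraclass correlation
$1 - \widehat{MSD}_w / \widehat{MSD}_b$ with both mean squared distances
estimated by averages over all within- and between-subject scan pairs,
Frobenius distance by default over the full matrix (an upper-triangle
option exists). A value below 0.4 is conventionally annotated as poor
reliability; the annotation is surfaced, never computed with.
`reliability_identifiability()` reports $\mu_{intra}$, $\mu_{inter}$
(means of row-wise-Pearson similarities over within- and between-subject
pairs; zero-variance rows are dropped from the row mean rather than
propagating NaN) and identifiability $|\mu_{intra} - \mu_{inter}|/s$. The
pooled standard deviation $s$ is the two-sample pooled estimate over the
two similarity samples — the cited construction names no formula, and the
two-sample pooled variance is the standard reading.

Local inference projects each subject's $P$ onto rank-one tensors
$\xi_k \otimes \xi_k$ of a mass-orthonormal, locally supported basis:
$S_k = \xi_k^\top \mathrm{diag}(m)\, P\, \mathrm{diag}(m)\, \xi_k$. The
diagonal reading of the reduced-rank expansion is implemented (the fuller
tensor form is not spelled out by its originators); a practical corollary
is that planted effects are detectable when their density mass lies near
the diagonal of $\Omega \times \Omega$ — the end-to-end test uses
self-connecting bundles for exactly this reason. The default basis
partitions the mesh into contiguous patches by seeded farthest-point
growing (disjoint supports make orthonormality exact); an externally
estimated basis can be supplied through `local_basis()`. Per-coefficient
two-sample tests are Welch's $t$ by default, with a seeded permutation
alternative; multiplicity control is Benjamini–Hochberg at $\alpha =
0.05$ by default (the multiple-comparison correction is cited generically
by the method's sources; BH is the field-standard choice), with Bonferroni
available. Coefficients constant in both groups get $p = 1$.

The prediction harness vectorizes each $P$ over its upper triangle
(including the diagonal — the lower triangle duplicates it), extracts
centered principal components, and fits ridge regression of a trait on
the first $K$ components over 50 random 80/20 train–test splits, with the
penalty chosen by 5-fold cross-validation *within the training split*
(glmnet; features standardized on the training split by default, with a
flag to disable). Bandwidth selection takes the best mean out-of-sample
MSE (or correlation), ties to the smaller bandwidth.

## Problem sizes used by the packaged checks

The test-suite and acceptance-script sizes are chosen so the full run
completes on a laptop-class single core in minutes: icosphere
subdivisions 1–3 for unit tests; a subdivision-5 sphere (10,242 vertices,
620 eigenpairs, full SHK matrix) for the Weyl-slope and sphere-identity
checks; consistency over $N \in \{25, 50, 100, 200, 400\}$ with 20
replicates; calibration and power simulations with 200 runs of 60-subject
groups. These are working scales, not limits — the matrix smoother on a
2562-vertex analysis mesh is interactive, and the eigensolver handles the
40,962-vertex template mesh.

## Known limitations

* The spherical fixture cannot exhibit the cortical-geometry effects that
  distinguish spherical-mapping kernels from intrinsic ones; conclusions
  about that contrast require real surfaces (FreeSurfer meshes can be
  supplied via OFF/PLY conversion).
* Streamline endpoints are snapped to nearest vertices; sub-vertex
  endpoint positions are retained in metadata but not yet used by an
  exact-location estimator.
* The consistent-mass eigenvectors are orthonormal with respect to the
  full mass matrix, not the lumped weights, and are intended for
  eigenvalue diagnostics rather than kernel construction.
* Reduced-rank inference with the diagonal coefficient reading has little
  power against effects concentrated far off the diagonal of
  $\Omega \times \Omega$; a full tensor-product basis would be needed
  there.
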