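---
title: "Diffusion communities and random-walk heterogeneity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion communities and random-walk heterogeneity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffcomm)
```

## The problem

Naive T cells searching a lymph node for antigen-bearing dendritic cells
migrate along the lymph-node conduit network, a quasi-regular 3D network of
~2e5 nodes in which most nodes have degree 3. Modelling this migration as a
simple random walk on the unweighted, undirected network raises a concrete
question: does the wiring favour some regions over others (heterogeneity),
or does it promote uniform collective exploration? Classical per-node
statistics such as the global mean first passage time do not delimit
regions and are not computable at this scale, so `diffcomm` works at the
level of *diffusion communities* — groups of nodes whose random walkers
have correlated presence fields — and compares region-level descriptors
against calibrated synthetic null networks.

## Model

For a connected simple graph with adjacency matrix $A$ and degrees
$d_i$, the walk's transition matrix is $T = D^{-1}A$,
$T_{ij} = p(j, t{=}1 \mid i)$. Its biorthogonal eigensystem
$T = \Psi \Lambda \Phi^\top$ (with $\Phi^\top\Psi = I$) is obtained from
the symmetric matrix $S = D^{-1/2} A D^{-1/2}$, which shares its spectrum:
if $v_k$ are orthonormal eigenvectors of $S$,

$$\psi_k = \sqrt{2E}\, D^{-1/2} v_k, \qquad
  \phi_k = D^{1/2} v_k / \sqrt{2E},$$

which pins the stationary mode to $\psi_0 \equiv 1$ and
$\phi_0 = d/(2E)$ (the stationary distribution). All quantities downstream
are functions of this eigensystem:

* **Diffusion coordinates** $X(t) = \Psi \Lambda^t$: node embeddings whose
  Euclidean distances are diffusion distances,
  $D_t^2(i_0,i_1) = \sum_{k\ge 1} \lambda_k^{2t} (\psi_k(i_0)-\psi_k(i_1))^2$,
  equal (at full rank) to the degree-weighted $\ell^2$ distance between the
  $t$-step presence fields of the two start nodes, with weights
  $w(j) = 1/\phi_0(j)$.
* **Presence fields** $p(j,t\mid i) = \sum_k \psi_k(i)\lambda_k^t\phi_k(j)$,
  row $i$ of $T^t$ at full rank.
* **Relaxation time** $\tau = 1/(1-|\lambda_1|)$, the characteristic
  mixing scale; it is undefined (and reported as an error) when
  $|\lambda_1| = 1$, i.e. on bipartite or disconnected graphs, which is why
  every pipeline entry point first restricts to the largest connected
  component and logs the retained fraction.
* **Truncation**: only the $K$ largest-magnitude eigenpairs are kept.
  Magnitude ordering (rather than algebraic) minimizes the spectral-norm
  truncation error and keeps near-$(-1)$ modes representable; $\lambda_0=1$
  is always retained. `truncation_error()` measures
  $\|T^t - \hat T_K^t\|_2 / \|T^t\|_2$ against an exact dense reference on
  graphs small enough to afford it.

**Communities** are k-means clusters of the rows of $X(t)$ at
$t = \lfloor\tau\rfloor$, with the constant mode-0 column dropped. At that
horizon most coordinates underflow to zero and clustering acts on the few
surviving slow modes — intentionally: the communities encode long-time
structure. Each community $C$ is then scored by

* the **Cheeger mixing index**
  $h(C) = \mathrm{cut}(C,\bar C)/\min(\mathrm{vol}\,C, \mathrm{vol}\,\bar C)$,
  whose unweighted mean $\bar h$ over communities measures *spatial
  coherence* (low $\bar h$: diffusion-close nodes are also shortest-path
  close);
* the **mean entry/exit probabilities**
  $\langle p_{\mathrm{in}}\rangle_C(t)$ and
  $\langle p_{\mathrm{out}}\rangle_C(t)$ — per-pair averages of
  $p(\text{target}, t \mid \text{source})$ over (outside, inside) and
  (inside, outside) pairs respectively, computed through per-community
  eigenvector sums in $O(kK)$ per time point, never through a dense $T^t$.
  On a fully regular graph the two coincide for every community and time;
  as $t \to \infty$ they approach
  $\langle d\rangle_C / 2E$ and $\langle d\rangle_{\bar C} / 2E$.

The network-level **heterogeneity statistic** is the maximum over a time
grid of the across-community standard deviation of
$\langle p_{\mathrm{in}}\rangle_C(t)$ (and of
$\langle p_{\mathrm{out}}\rangle_C(t)$). *Remote regions* are the
communities with jointly lowest entry and exit probabilities at the
biologically relevant time, obtained from the residence time of a T cell:
with a 12 h residence, 13 µm/min speed and 10 µm mean edge length,
`scan_steps(720, 13, 10)` gives a per-step duration of 0.77 min and 935
steps.

```{r scan}
scan_steps(720, 13, 10)
```

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `K` | 2000 (capped at `N`) | modes | truncation order of the eigensystem; full rank on small graphs |
| `k` | 100 | communities | resolution of the community partition |
| `t_embed` | `floor(tau)` | steps | embedding time for clustering |
| time grid | ~12 log-spaced ints in `[1, 2 floor(tau)]`, incl. `floor(tau)` | steps | where `p_in`/`p_out` are sampled |
| `m_extremes` | 5 | communities | how many extreme communities are ranked |
| scan parameters | 720 min, 13 µm/min, 10 µm | — | step-time conversion for the ranking time |
| jitter `noise` | 0.2 | lattice units | breaks lattice degeneracy in the homogeneous Voronoi generator |
| target mean degree | 2.8 | — | edge thinning target shared by all null models |

k-means uses k-means++ seeded initialization, 10 restarts, a relative
inertia tolerance of $10^{-6}$, nearest-centroid ties broken toward the
lowest community id, and empty clusters repaired by re-seeding the empty
centroid at the point farthest from its assigned centroid (with a
deterministic donor-split fallback for pathologically duplicate-heavy
embeddings, which arise when all coordinates underflow). These semantics —
in particular determinism and the guarantee of `k` non-empty communities —
are part of the package contract, which is why the Lloyd iteration is
implemented in-package rather than through `stats::kmeans`; the latter
serves as an independent cross-check in the test suite. No scaling or
normalization is applied to the diffusion coordinates before clustering.

## Null-network generators

The generators produce the reference topologies against which claims about
a real network are calibrated; the same code produces desk-scale fixtures
and full-scale networks.

* **Homogeneous Voronoi (HVor)**: a `31^3` integer lattice, filtered to
  the 5185 points nearest the origin (rank-based sphere filter — the rank
  rather than a radius is specified because the target count is the
  contract; boundary ties break lexicographically), jittered uniformly by
  ±0.2 lattice units, tessellated, thinned to mean degree 2.8 and reduced
  to its largest component. Jitter matters: on an exact lattice the
  tessellation degenerates (vertices tend to degree 6 rather than the
  generic 4).
* **Polar Voronoi (PVor)**: seeds drawn from two isotropic Gaussians —
  10,000 points, sd 5, at the origin and 18,752 points, sd 1, at (5,5,5) —
  then the same Voronoi → thinning → component pipeline. The density
  gradient makes it the positive control for heterogeneity.
* **Random**: a stub-matching configuration model on a constant
  degree-3 sequence, simplified, thinned, largest component. A structureless
  negative control with the same mean degree.
* **Rewired HVor**: `ceiling(f |E| / 2)` successful double edge swaps
  applied to an HVor network, i.e. a fraction `f` of edges rewired, with
  swaps that would create loops or duplicates rejected. Degree sequence,
  `|V|` and `|E|` are exactly preserved; increasing `f` progressively
  destroys spatial coherence while keeping local degree structure intact.

The 3D Voronoi tessellation itself is delegated to qhull via
`scipy.spatial`, invoked through the system `python`: Voronoi vertices are
circumcenters of Delaunay tetrahedra and two vertices are joined when their
tetrahedra share a face, which is exactly the finite Voronoi 1-skeleton
(vertices at infinity and their ridges discarded).

Thinning removes uniformly random edges one at a time until the mean
degree first crosses the target — a deterministic stopping rule given the
seed. Thinning precedes component extraction, so the final mean degree can
sit slightly above the target after isolated fragments are discarded; the
full-precision value is always reported.

### What the fixtures do and do not emulate

Desk-scale fixtures (31→11 grid side, 450 in-sphere seeds, ~2.5k nodes;
PVor scaled to 150 + 281 seeds preserving the two-Gaussian count ratio)
reproduce the *mechanism* of the full-scale recipes: quasi-regular Voronoi
topology, identical thinning target, identical noise amplitude. They do
not reproduce full-scale relaxation times (τ ≈ 300–600 at fixture scale
versus thousands at 2e5 nodes), absolute probability scales (which carry a
$1/2E$ factor), or the anisotropic boundary shape of a real organ. Passing
fixture-scale ordering tests therefore demonstrates that the workflow
detects the designed contrasts (coherence loss under rewiring; polarity of
PVor), not that any particular biological network is heterogeneous.

## Numerical choices

* **Eigensolver.** Graphs with `N <= 600`, or truncations within 2 of full
  rank, use LAPACK's dense symmetric solver; larger problems use ARPACK
  (through igraph) on the sparse symmetric matrix with a seeded start
  vector, so repeated runs agree. Eigenvectors are sign-fixed by making
  the largest-magnitude entry of each orthonormal vector positive.
  Degenerate eigenvalues are ordered by magnitude, then algebraically
  descending.
* **Large-time powers.** $\lambda^t$ is evaluated as
  $\mathrm{sign}(\lambda)^t \exp(t \log|\lambda|)$ with graceful underflow
  to 0, stable up to the $t = 10^6$ horizons used for stationary-limit
  checks.
* **Truncation bias at short times.** A rank-`K` reconstruction of
  $p_{\mathrm{in}}/p_{\mathrm{out}}$ is biased at small $t$, where the
  dropped modes have not yet decayed; because the across-community SD
  typically peaks at small-to-moderate $t$, heterogeneity comparisons are
  only meaningful where the truncation error is small. At full scale this
  is achieved by choosing `K` so the error is below ~0.1 % at the smallest
  time considered; at fixture scale (a few thousand nodes) the package's
  comparisons simply evaluate features at full rank — clustering still
  uses the truncated embedding — via `truncate_model()`, so one
  decomposition serves both roles.
* **Population SD.** The heterogeneity statistic uses the population
  standard deviation (divisor `k`); at `k = 100` the distinction from the
  sample SD is negligible but it is fixed for reproducibility.
* **Step-count rounding.** `scan_steps()` rounds the per-step duration to
  2 decimal places *before* dividing (0.77 min, 935 steps); exact division
  would give 936.
* **Degenerate inputs.** Isolated nodes are rejected by
  `transition_matrix()` with a pointer to `largest_component()`;
  `|lambda_1| = 1` yields an explicit "relaxation time undefined" error
  naming bipartiteness/disconnection; ties in component size break toward
  the component containing the smallest node id; `k = N` clustering
  returns the identity partition directly.

## Worked example

A dumbbell graph — two triangles joined by a bridge — is the smallest
fixture on which the whole pipeline is interpretable: the two triangles
are the only sensible 2-community structure.

```{r dumbbell}
db <- ugraph(6, rbind(c(0, 1), c(1, 2), c(0, 2),
                      c(3, 4), c(4, 5), c(3, 5), c(2, 3)))
res <- run_workflow(workflow_config(db, K = 6, k = 2, t_embed = 2, seed = 1,
                                    label = "dumbbell"), quiet = TRUE)
res$partition$labels        # the triangles separate
res$summary$tau             # relaxation time from the spectral gap
res$summary$mean_cheeger    # both communities: cut 1 / volume 7
```

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic
fixtures generated in code: random connected graphs up to 500 nodes for
oracle-equivalence and truncation checks (where dense $T^t$ references are
exact), and Voronoi fixtures of ~2.5–2.7k nodes (grid side 11, 450 seeds;
PVor 150 + 281 seeds) with `K = 48`, `k = 100`, across 5–10 seeds for the
rewiring-monotonicity and HVor-vs-PVor orderings. These sizes were chosen
as the smallest at which the Voronoi fixtures retain the quasi-regular
degree profile and a clear timescale separation (τ ≫ 1) while keeping the
full workflow comfortably interactive.

## Known limitations

* Unweighted, undirected, discrete-time walks only: edge lengths, angles,
  continuous-time or lazy/teleporting variants are out of scope.
* The Voronoi generators require a system `python` with scipy (used solely
  for the qhull tessellation); everything else is pure R.
* `truncation_error()` needs a dense reference and is capped (default
  2000 nodes) by design.
* Community detection at `t = floor(tau)` on heavily truncated embeddings
  clusters on few effective dimensions; with very small `K` the partition
  can be coarse. Choose `K` of at least a few dozen for fixture-scale work.
* Modularity-style or flow-based community methods are intentionally not
  included; the communities here are defined by the diffusion geometry.
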