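# diffcomm

Random-walk heterogeneity detection for large undirected networks.

Motivated by naive T cells scanning a lymph node: the cells migrate along
the lymph-node conduit network (~192k nodes, ~275k edges, mostly degree 3)
and their motion is well modelled as a simple random walk on that network.
`diffcomm` answers two questions about any such network: is it *spatially
coherent* (are regions that random walks connect tightly also close in the
graph?), and is it *heterogeneous* (do some regions trap or repel walkers
more than others?). It is aimed at network/systems biologists who have an
edge list and want region-level, statistically calibrated answers rather
than per-node statistics that do not scale.

## Method at its core

For the walk on a graph with adjacency `A` and degree matrix `D`, the
transition matrix is `T = D⁻¹A`. Its biorthogonal eigensystem
`T = Ψ Λ Φᵀ` (with `ΦᵀΨ = I`, `ψ₀ ≡ 1`, `φ₀ = d/2E`) yields:

- **diffusion coordinates** `X(t) = Ψ Λᵗ`, a node embedding in which
  Euclidean distance is the diffusion distance
  `D_t²(i₀,i₁) = Σ_{k≥1} λ_k^{2t} (ψ_k(i₀) − ψ_k(i₁))²`;
- the **relaxation time** `τ = 1/(1 − |λ₁|)`;
- **diffusion communities**: k-means clusters (k = 100 by default) of the
  rows of `X(⌊τ⌋)`;
- per community `C`, the **Cheeger mixing index**
  `h(C) = cut(C, C̄) / min(vol C, vol C̄)` (its mean `h̄` measures spatial
  coherence) and **mean entry/exit probabilities**
  `⟨p_in⟩_C(t)`, `⟨p_out⟩_C(t)`, computed through per-community
  eigenvector sums in `O(kK)` per time point;
- the **heterogeneity statistic** `max_t SD_C(⟨p_in⟩_C(t))` (and for
  `p_out`), the maximal across-community spread over a time grid;
- **remote regions**: communities with jointly lowest `⟨p_in⟩`/`⟨p_out⟩`
  at the biological scan time (`scan_steps(720, 13, 10) = 935` steps for a
  12 h residence at 13 µm/min over 10 µm edges).

Only the `K` largest-magnitude eigenpairs are kept (`K = 2000` by default,
capped at `N`), so the workflow scales to networks where full
diagonalization is impossible. Null-network generators — homogeneous and
polar 3D Voronoi tessellations, a configuration model, and degree-preserving
rewiring — provide the baselines that make "coherent" and "heterogeneous"
quantitative. See `vignettes/diffusion-communities.Rmd` for the full
methods account.

## Worked example

Two triangles joined by a bridge; the whole pipeline in one call:

```r
library(diffcomm)
db <- ugraph(6, rbind(c(0, 1), c(1, 2), c(0, 2),
                      c(3, 4), c(4, 5), c(3, 5), c(2, 3)))
res <- run_workflow(workflow_config(db, K = 6, k = 2, t_embed = 2, seed = 1,
                                    label = "dumbbell"), quiet = TRUE)
res
#> workflow_result 'dumbbell': N = 6, E = 7, mean degree 2.333
#>   tau = 4.89, k = 2 communities at t = 2
#>   mean Cheeger = 0.1429, max SD(p_in) = 2.19e-17, max SD(p_out) = 2.19e-17
res$partition$labels
#> [1] 0 0 0 1 1 1
```

The partition separates the two triangles; each community cuts 1 of its 7
volume units, so `h(C) = 1/7 ≈ 0.143`, and by symmetry the across-community
spread of the entry/exit probabilities is zero to machine precision.

At a more realistic scale, a homogeneous Voronoi null network (the desk-size
version of the reference recipe):

```r
g <- homogeneous_voronoi(grid_side = 11, noise = 0.2, sphere_keep = 450,
                         target_mean_degree = 2.8, seed = 1)
g
#> ugraph: 2603 nodes, 3677 edges, mean degree 2.8252, with 3D coordinates
res <- run_workflow(workflow_config(g, K = 48, k = 100, seed = 1,
                                    label = "HVor fixture"), quiet = TRUE)
res
#> workflow_result 'HVor fixture': N = 2603, E = 3677, mean degree 2.825
#>   tau = 292.60, k = 100 communities at t = 292
#>   mean Cheeger = 0.2021, max SD(p_in) = 5.85e-05, max SD(p_out) = 5.54e-05
res$rankings$lowest_pin
#>   community        value pct_of_mean
#> 1        46 0.0002501097    66.48888
#> 2        55 0.0002989139    79.46292
#> 3        99 0.0003197399    84.99928
#> 4        11 0.0003245840    86.28703
#> 5        10 0.0003342985    88.86953
```

`mean Cheeger ≈ 0.20` says each diffusion community keeps ~80 % of its
edge volume internal — a spatially coherent tessellation — and the five
listed communities are the hardest to enter (entry probability down to
~66 % of the across-community mean). Rewiring such a network degrades
coherence monotonically, and a polar (two-Gaussian) Voronoi network shows
larger heterogeneity maxima than the homogeneous one — the two orderings
the test suite verifies across seeds.

A thin CLI wraps the same functions: `exec/diffcomm generate|run|compare`.

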