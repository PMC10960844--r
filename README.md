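# hypermi

Community detection in hypergraphs by compression entropy minimization.

Many relational data sets — group conversations, co-authorships, classroom
contacts, cards drafted into the same deck — are *hypergraphs*: their edges
join arbitrary numbers of vertices at once. Collapsing such data to a
pairwise graph before clustering (a "clique projection") can destroy the
community signal entirely. `hypermi` clusters hypergraphs natively.

## The method

A partition of the vertices into `m` clusters induces a **compression** of a
hypergraph H: the cluster sizes, and for every λ-type (the vector
λ with λᵢ = |A ∩ Cᵢ|, the signature of how an edge A meets the clusters) the
count e_λ of edges of that type — optionally together with the vertex degree
sequence. Let Z(γ) be the number of hypergraphs compatible with the
compression γ. Choosing the partition that is maximally informative about H
(maximal mutual information between H and a hypergraph re-sampled from its
compression) is equivalent to minimizing the conditional entropy

    H(H | γ) = log Z(γ).

`hypermi` implements closed-form log-counts for

* **simple** hypergraphs: Z(γ) = ∏_λ C(N_λ, e_λ) with
  N_λ = ∏ᵢ C(|Cᵢ|, λᵢ);
* **multi**-hypergraphs: Z(γ) = ∏_{A∈E} ∏ᵢ C(|Cᵢ|, |A ∩ Cᵢ|);
* the **degree-corrected** stub count with the degree sequence held fixed:
  Z(γ) = ∏ᵢ eᵢ! / (∏_λ e_λ! · ∏_λ ∏ᵢ (λᵢ!)^{e_λ}),
  where eᵢ = Σ_λ λᵢ e_λ is the degree sum of cluster i — this is the
  microcanonical analogue of degree correction in stochastic blockmodels;
* the module-matrix count for ordinary **graphs**, which the simple count
  reduces to on 2-uniform input.

Minimization is by Metropolis–Hastings **simulated annealing** over
single-vertex label moves with the linear schedule β(t) = (t+1)·10⁻⁴,
tracking the best assignment seen (`anneal()`, `multi_run_anneal()`). The
number of clusters can be chosen by **minimum description length**
(`select_m()`), coding cost n·log₂ m + Σ_k C(m+k−1, k)·log₂ ℓ_k plus
log₂ Z(γ) bits.

Benchmark generators (`planted_partition()`, `dchsbm()`), clique projections
(`simple_projection()`, `multiedge_projection()`), ARI scoring
(`adjusted_rand_index()`), a spectral-clustering baseline
(`spectral_baseline()`) and sweep harnesses (`heatmap_sweep()`,
`entropy_vs_ari()`) round out the toolkit.

## Worked example: degree correction matters

The degree-corrected blockmodel generator produces two 50-vertex
communities whose vertex degrees are strongly heterogeneous but carry no
information about the communities:

```r
library(hypermi)
gen <- dchsbm(seed = 42)
gen$hypergraph
#> hypergraph: 100 vertices, 1496 edges (non-simple)
#> edge sizes: 2-edges: 138, 3-edges: 1358

dc <- multi_run_anneal(gen$hypergraph, m = 2, model = "degree_corrected",
                       runs = 10, steps = 20000, seed = 1)
dc
#> simulated annealing (degree_corrected model, m = 2)
#> best entropy: 19804.24 nats (28571.48 bits)
#> accepted 11237 of 20000 proposals
adjusted_rand_index(dc$best_labels, gen$labels)
#> [1] 1

nc <- multi_run_anneal(gen$hypergraph, m = 2, model = "simple",
                       runs = 10, steps = 20000, seed = 1)
adjusted_rand_index(nc$best_labels, gen$labels)
#> [1] 0.02542638
```

The degree-corrected chain recovers the planted communities exactly
(ARI = 1); the non-corrected chain, run identically, is drawn to the degree
structure instead and scores at chance (ARI ≈ 0).

A command-line wrapper with the same functionality ships in
`inst/exec/hypermi.R` (subcommands `generate-planted`, `generate-dchsbm`,
`project`, `cluster`, `select-m`, `score`).

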