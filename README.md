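# admixorient

Maximum likelihood estimation of **admixture graphs** — phylogenetic
networks with drift branch lengths and admixture proportions — from
f2-statistics, with an exhaustive **maximum likelihood network
orientation (MLNO)** step that lets starting-tree-based searches escape a
provable local optimum.

## Who this is for

Population geneticists fitting demographic histories with gene flow from
f-statistics (the qpGraph/TreeMix family of workflows), and method
developers studying the search space of directed phylogenetic networks.
The package starts from f2 tables; it does not estimate f-statistics
from allele counts.

## The model and the problem

An admixture graph is a pair (N, Θ): a rooted binary network N on
populations S whose in-degree-2 vertices are admixture nodes, plus drift
lengths c_e ≥ 0 and proportions γ ∈ [0, 1].  The expected f2-statistic
between populations i and j is

    Y_ij = Σ_e (p_i(e) − p_j(e))² c_e

with p_i(e) the admixture-weighted probability that the root-to-i
inheritance path uses edge e (the path-length sum between leaves when N
is a tree).  Observed statistics X with scales Z are scored by the
composite Gaussian log-likelihood

    log ℓ(N) = −½ Σ_i [ (X_i − Y_i)²/Z_i² + 2 log Z_i + log 2π ].

Starting-tree-based searches build a tree, then add gene-flow edges by
hill climbing.  This package ships a five-population, one-admixture
fixture on which that strategy is *guaranteed* to stop at a wrong
topology — the best edge addition from the (NJ = ML) starting tree makes
the outgroup admixed, and the true network is three tail moves away
through strictly worse networks.  The trapped network and the truth are
two *orientations* of the same undirected network, so the fix is to
search the orientation neighborhood: all ways of re-choosing the
admixture vertices (root fixed on the outgroup's pendant edge),
re-scored by the same likelihood.

## Worked example

```r
library(admixorient)

fx <- make_m1()                   # the five-population case-study fixture
#> Model fixture 'm1': 5 populations, h = 1, 10 f2 pairs

score_graph(fx$graph, fx$data, "treemix")   # fit the true topology
#> Admixture graph fit (treemix convention): loglik = 82.914
#>   admixture proportions: 11: 0.4500
cat(write_enewick(fx$graph))
#> (E,((D,#H1),(C,((A)#H1,B))));

baseline <- run_search(fx$data, search_config(1, "E", mlno = FALSE))
triplet_distance(baseline$network, fx$graph)
#> [1] 9

oriented <- run_search(fx$data, search_config(1, "E", mlno = TRUE))
triplet_distance(oriented$network, fx$graph)
#> [1] 0
oriented$trace
#>   iteration         stage       loglik
#> 1         0 starting_tree -13383.75265
#> 2         1 edge_addition  -3967.08598
#> 3         1    tail_moves  -3967.08598
#> 4         1          mlno     82.91402
```

Reading the numbers: 82.914 is the perfect-fit bound
−(10/2)(2 ln 10⁻⁴ + ln 2π) for 10 pairs at standard error 10⁻⁴, so the
true topology explains its own data exactly (the printed score rounds to
83).  The baseline search ends at −3967 — a network in which the
outgroup E is wrongly admixed, differing from the truth on 9 of the 10
leaf triples — while the orientation step replaces it with the true
network at the perfect-fit score (triplet distance 0).

A thin command-line interface wraps the same functions
(`exec/admixorient`): subcommands `infer`, `score`, `orient`,
`distance`, `simulate`, `fixture` over TSV f2 tables and edge-list graph
files; see the roxygen help for `cli_main`.

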