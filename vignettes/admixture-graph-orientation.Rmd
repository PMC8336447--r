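---
title: "Admixture graph estimation from f2-statistics with maximum likelihood network orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture graph estimation from f2-statistics with maximum likelihood network orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixorient)
```

## The model

An admixture graph is a pair $(N, \Theta)$: a rooted binary phylogenetic
network $N$ on a population set $S$, plus numerical parameters $\Theta$ —
a drift length $c_e \ge 0$ per edge and an admixture proportion
$\gamma \in [0, 1]$ per admixture node (an internal vertex with in-degree
2).  Allele frequencies evolve along edges by genetic drift (variance
$c_e$) and mix at admixture nodes: the admixed population's frequency is
the $\gamma$-weighted average of its two parents' frequencies.

Under this model the expected f2-statistic between populations $i$ and
$j$ is

$$Y_{ij} \;=\; \sum_{e \in E(N)} \bigl(p_i(e) - p_j(e)\bigr)^2\, c_e,$$

where $p_i(e)$ is the admixture-weighted probability that the inheritance
path from the root to leaf $i$ traverses $e$ (`path_weights()`).  On a
tree this is simply the path length between the two leaves, and the
package tests pin that case against an independent shortest-path oracle
and the admixed case against a Monte-Carlo Brownian simulation with
frequency mixing at the admixture node.

Observed statistics $X_i$ with scales $Z_i$ are scored by the composite
Gaussian log-likelihood

$$\log \ell(N) = -\tfrac{1}{2} \sum_i \left( \frac{(X_i - Y_i)^2}{Z_i^2}
  + 2 \log Z_i + \log 2\pi \right),$$

so a perfect fit over $n$ pairs at constant scale $Z$ equals
$-(n/2)(2\log Z + \log 2\pi)$ — with $Z = 10^{-4}$ that is $82.914$ for
10 pairs, $124.371$ for 15, and $373.113$ for 45.  Natural logarithms are
used throughout, and $Z$ enters exactly as the scale whose square divides
the squared residual.  The interface exposes no shift constant on $Z$;
model fixtures set the standard error to $10^{-4}$ directly, which is
also what keeps the perfect-fit scores finite.

## Fitting a fixed topology

The three branch lengths incident to an admixture node are not jointly
identifiable, so `fit_params()` supports the two conventions in use:

* **admixturegraph**: both incoming edges of each admixture node are
  pinned to length 0 and the outgoing edge is estimated;
* **treemix**: the estimated edges are exactly the base-tree edges (those
  labeled 0 by a tree-based labeling $\psi$) whose tail is not an
  admixture node; gene-flow edges and edges emanating from admixture
  nodes are pinned to 0.

For fixed proportions $\gamma$, $Y$ is linear in the free lengths, so the
profile problem is a weighted nonnegative least squares solved exactly by
Lawson–Hanson NNLS.  The design matrix is rank-deficient by construction
— the two root edges contribute identical columns because only their sum
is identifiable — so the solve is stabilized with a tiny ridge
($10^{-7}$ of the design scale, escalated only if the active-set solver
still fails); the induced bias is orders of magnitude below the data
scale, and the parameter-recovery tests (branch lengths within $10^{-5}$
drift units on noiseless trees) bound it empirically.

The proportions are then optimized by coordinate descent: the profile
log-likelihood is evaluated on the grid $\{0.05, 0.10, \ldots, 0.95\}$
(applied to all admixture nodes simultaneously), the best starts are
refined by bounded one-dimensional optimization per node, alternating
with the NNLS solve until the objective changes by less than $10^{-10}$.
The profile in $\gamma$ can be multimodal, which is why grid seeding is
used rather than a single gradient path.  Because a fit costs a fraction
of a second and search steps score dozens to hundreds of candidates,
neighborhood scans first rank all candidates with a cheap profile fit
(5-point grid, single refinement) and then refit the leaders exactly —
every decision (the argmax of a scan, acceptance of a hill-climbing step)
is made on exact fits only, and the tests cross-check scan argmaxes
against brute-force rescoring.

Under the treemix convention the likelihood can depend on which incoming
admixture edge is designated part of the base tree; `score_graph()`
therefore evaluates all $2^h$ labelings (those that are tree-based) and
returns the best.  On the case-study fixture the per-labeling scores
agree to $10^{-3}$ while the admixture-edge parameters differ, as
expected from the identifiability structure.

## The search and its failure mode

`run_search()` implements the starting-tree-based maximum likelihood
(STB-ML) paradigm: build a starting tree rooted at the outgroup (neighbor
joining by default; exact enumeration and random stepwise addition are
available), then for each admixture event (2a) score every legal
gene-flow edge addition — pairs of base-tree edges whose linking arc
cannot create a cycle, tested against a precomputed reachability closure
— (2b) hill-climb with tail moves, and (2c) optionally replace the
network by its maximum likelihood orientation.

The package ships a five-population fixture (`make_m1()`) on which the
baseline search provably fails: a caterpillar on A..E rooted at the
outgroup E, with a gene-flow arc from D's pendant edge into A's pendant
edge.  Its numerical constants are package constants chosen so that the
construction-time checks in `validate_m1()` hold:

* the NJ tree of the exact f2 data (which is also the exact ML tree) is
  `((((B,C),A),D),E)` — not a base tree of the truth;
* the best gene-flow edge addition from that tree makes the *outgroup* E
  admixed (log-likelihood $-3967$), not A;
* the truth is the unique global optimum (82.914, the perfect-fit bound)
  among all 525 one-admixture classes on five populations, and the
  E-admixed network is second best;
* the E-admixed local optimum is exactly three tail moves from the truth,
  no single head move helps, and every tail-move neighbor of the truth
  scores far below the local optimum — so steepest-ascent hill climbing
  can never cross.

The long outgroup pendant edge (0.15 drift units against internal edges
of 0.02–0.06) is what makes mis-assigning the admixture to the outgroup
attractive; the admixture proportion 0.45 keeps the NJ tree off both base
trees.

## Maximum likelihood network orientation

The escape hatch is that the local optimum and the truth are different
*orientations* of the same undirected network: redirecting edges so that
A rather than E is admixed turns one into the other.  `orient()`
reconstructs a directed network from an undirected one given a root edge
and the set of admixture vertices, by constraint propagation on required
in-degrees (root 0, admixture nodes 2, every other vertex 1): a vertex
that has reached its required in-degree directs its remaining edges
outward, one whose remaining edges exactly cover its deficit directs them
inward.  The result, when propagation completes and validates, is the
unique orientation; the tests compare against an exhaustive
direction-assignment oracle over all $2^{|E|}$ assignments on small
fixtures, including the no-orientation cases.

`enumerate_orientations()` generates the outgroup-rooted orientation
neighborhood: all admixture-set choices among internal vertices, root
fixed on the outgroup's pendant edge (a flag unlocks all root edges —
root position does not move the likelihood, so outgroup rooting is a
harmless and much cheaper default).  The vertex created by subdividing
the root edge is never itself an admixture candidate, since the root must
stay ancestral to admixture nodes.  `mlno()` scores every member over all
tree-based labelings and returns the argmax; the input network is always
the first candidate, so the step never decreases the likelihood.
Exhaustive search is refused above a configurable admixture count
(default 6), where the $\binom{|V|}{h}$ neighborhood becomes
impractical; a constrained incremental variant (reorienting only around
the latest edge addition) is a known direction but is not implemented.

On the fixture, the orientation neighborhood of the trapped network
contains the truth, and the MLNO-augmented pipeline returns it with the
perfect-fit score, while the baseline returns the E-admixed network at
triplet distance 9 from the truth.

## Topological accuracy

`triplet_distance()` counts the 3-subsets of populations on which two
networks display different sets of rooted triplet topologies, the sets
being unions over each network's displayed trees (one tree per choice of
incoming edge at each admixture node).  An alternative convention —
summing the sizes of the per-subset symmetric differences — is available
behind a flag; the default convention reproduces the distance of 9
between the fixture's local optimum and its truth, so the alternative was
left as an option only.

## Move-space distances

`move_distance()` runs breadth-first search over tail- or head-move
space, with two subtleties.  Equality of states is isomorphism *modulo
the root position*: two directed networks are identified when their
undirected versions match under a leaf-label-preserving isomorphism that
also carries admixture nodes to admixture nodes (by orientation
uniqueness this is exactly reroot-equivalence).  And because a move's
legality depends on where the root is, each visited class is expanded
from all of its rootings before moves are enumerated.  Layers are
deduplicated by iterated neighborhood color refinement anchored at leaf
labels (a cheap invariant key) with a backtracking matching inside key
buckets, and exact directed duplicates are filtered first.  A network
whose root sits directly above an admixture node's two parents
undirects to a multigraph (a parallel pair); such states are kept, with
the parallel copies treated as interchangeable root edges.

## The synthetic-data generator

`random_graph()` draws a random rooted binary tree by stepwise leaf
insertion at uniformly chosen edges, then applies `h` random legal
gene-flow edge additions between base-tree edges.  Drift lengths are
Uniform(0.01, 0.5) on edges not incident to an admixture node — the range
of magnitudes typical for population pairs separated by moderate drift —
and exactly 0 on admixture-incident edges, so the implied f2 data are
representable without error under both fitting conventions and any
labeling; proportions are Uniform(0.1, 0.9).  `simulate_f2()` adds
independent Gaussian noise of a chosen standard deviation to the exact
expectations, which matches the likelihood's own error model.  What this
emulates is the infinite-data regime of the study design (exact
statistics, small constant reported error) plus an idealized finite-data
regime; it does not emulate the correlated, heteroscedastic errors of
block-jackknifed genome data, linked-site effects, or SNP ascertainment —
so passing tests certify search and fitting behavior, not robustness to
real-data error structure.

## Numerical choices and scales

* Hill climbing accepts a move only if it improves the log-likelihood by
  more than $10^{-6}$; exact refits are reproducible to $\sim 10^{-11}$,
  so this tolerance separates real improvement from optimizer noise and
  prevents wandering among reroot-equivalent neighbors at a plateau.
* Ties in any argmax are broken by enumeration order, which is itself
  fixed by stable integer vertex ids assigned in creation order.
* Brute-force enumerations used in validation run at five populations
  (105 rooted trees, 525 one-admixture classes), where the global
  optimum scan and the distance-3 breadth-first search complete in
  minutes on one core; the test suite uses 5–10 populations and
  $h \le 2$ throughout.
* Degenerate inputs: a network failing validation is rejected with the
  violated rule named; datasets must cover every population pair exactly
  once with positive scales; `orient()` returns `NULL` (not an error)
  when no orientation exists.

## Limitations

Estimation of f2-statistics and their standard errors from allele counts
is out of scope — the package starts from f-statistics.  The likelihood
treats pairs as independent (composite likelihood), as its progenitors
do.  Exhaustive orientation search scales exponentially in the admixture
count, and no constrained heuristic is provided.  Confidence intervals
on fitted proportions and lengths are not computed.
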