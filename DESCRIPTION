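Package: admixorient
Title: Admixture Graph Estimation from f2-Statistics with Maximum
    Likelihood Network Orientation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates admixture graphs (phylogenetic networks with drift
    branch lengths and admixture proportions) from f2-statistics under the
    composite Gaussian likelihood used by starting-tree-based maximum
    likelihood methods.  Provides data structures for binary directed and
    undirected phylogenetic networks, tree-based labelings, expected
    f2-statistics under the drift model, constrained parameter fitting by
    nonnegative least squares, topology search moves (edge additions, tail
    moves, head moves), exhaustive maximum likelihood network orientation
    (MLNO), a full search driver, triplet-distance evaluation, model
    fixtures and an f2 simulator, plus TSV/extended-Newick input and
    output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    pracma,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
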