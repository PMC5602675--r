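Package: mosaweak
Title: Weak-Spot Assessment of Mosasauroid Phylogenies Across Tree-Search Strategies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the robustness ("weak spots") of mosasauroid
    phylogenetic hypotheses across alternative tree-search strategies. Implements
    parsimony scoring of discrete morphological matrices under unordered (Fitch)
    and ordered (additive) optimization, implied weighting, heuristic tree search
    with random-addition replicates and branch swapping, Bremer decay via
    converse-constraint searches, nonparametric character bootstrap, strict and
    majority-rule consensus, Bayesian tip dating under the Mk model conditioned on
    variable characters with a fossilized birth-death sampled-ancestor tree prior,
    posterior summaries (maximum clade credibility tree, sampled-ancestor
    histograms, effective sample sizes), a formal evaluator of node- and
    branch-based phylogenetic clade definitions that detects self-destruction, and
    simulators of Mk character matrices and fossilized birth-death trees for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
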