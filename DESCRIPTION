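Package: duproot
Title: Species Tree Rooting from Gene Duplication Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outgroup-free rooting of a species tree from a set of unrooted
    gene trees. Well-supported gene duplication events are identified in each
    gene tree by mapping the species content of candidate post-duplication
    subtrees onto the bipartitions of the species tree and applying strict
    grandchild-presence and local-topology filters. The detected events are
    used to find the maximum-parsimony root (the branch violating the fewest
    events) and, through a two-component Poisson mixture model of true- and
    false-positive duplications with an integral over the root position along
    a branch, to compute a posterior probability for every branch of the
    unrooted species tree being the root. A seeded duplication-loss simulator
    with ground-truth event logs supports validation of detection precision,
    recall, and root recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
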