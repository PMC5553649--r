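Package: treeroot
Title: Minimum-Variance, Midpoint and Outgroup Rooting of Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Roots unrooted phylogenetic trees with branch lengths using
    three strategies: minimum-variance (MV) rooting, which places the root
    at the point minimizing the variance of root-to-tip distances via a
    linear-time three-traversal dynamic program; linear-time midpoint (MP)
    rooting at the middle of the longest leaf-to-leaf path; and outgroup
    rooting on the edge separating a designated taxon set.  Includes
    rooting-accuracy metrics (rooted triplet distance, delta triplet
    distance against the best achievable rooting, normalized branch
    distance, unrooted Robinson-Foulds), a synthetic-tree generator for
    clock-deviated gene trees (bounded random deviations and mean-one
    gamma rate multipliers), multispecies-coalescent outgroup-discordance
    arithmetic, and a command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
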