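Package: tadfd
Title: Dendrogram-Based Functional Diversity of Tadpole Stream Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dendrogram-based functional diversity (FD) analysis of
    stream tadpole communities: Gower distances on mixed binary/continuous
    trait matrices, agglomerative clustering with automated linkage selection
    against the cophenetic criterion, FD as the branch length of the subtree
    spanning a community on the regional functional dendrogram, a
    richness-controlled null model of random assembly, polynomial-regression
    tests for functional redundancy, and grouped Michaelis-Menten curve
    comparison of observed versus null-expected FD.  A habitat-ordination
    stage (Box-Cox transforms, correlation-matrix PCA with
    bootstrapped-eigenvector loading tests, broken-stick retention, and
    backward-eliminated regression of species richness on components) links
    richness to stream gradients.  A synthetic-data module generates trait,
    community, and habitat tables under neutral, environmental-filtering, and
    competition assembly rules so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    cluster,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
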