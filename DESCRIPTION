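Package: dryfreeze
Title: Paired Comparison of Dried and Frozen Sample Preservation for Microbiome Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for comparing two sample-preservation
    treatments (desiccation versus freezing) across multiple source materials
    with replicated samples. Implements material-stratified ratio-of-means
    permutation location tests for scalar success metrics (DNA yield, read
    counts, contig counts and similar), compositional agreement tests between
    treatment-mean feature proportions using a coefficient-of-determination
    statistic with a treatment-label permutation null, a within-OTU strain-level
    decomposition of amplicon sequence variants, abundance-weighted Bray-Curtis
    and Jaccard (Ruzicka) dissimilarities, metric multidimensional scaling by
    Kruskal stress minimisation, principal coordinates analysis, and
    per-material PERMANOVA with the pseudo-F statistic. A synthetic-data
    generator emulates the paired study design (materials x treatments x
    replicates) with known ground-truth effects so every stage can be verified
    for calibration and recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
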