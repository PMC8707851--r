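Package: taxconsensus
Title: Multi-Method Taxonomic Profile Consensus and Oil Biodegradation
    Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating prokaryotic community profiles produced
    by different sequencing and taxonomic classification methods (Kraken2,
    Bracken, Kaiju, amplicon/mothur), with rank-based consensus estimates,
    top-set overlap analysis, compositional (clr) transforms and Ward
    clustering, and a from-scratch multiple co-inertia analysis with RV
    coefficients. Includes window-of-linearity qPCR quantification to anchor
    sequencing-based proportions to absolute 16S rRNA gene abundances,
    annotation of hydrocarbon-degrading genera, hydrocarbon-degradation-gene
    profiling (RPKG and cluster presence) of communities and
    metagenome-assembled genomes with quality filtering and ANI
    dereplication, oil-depletion metrics, and a synthetic-data generator
    with known ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-rng.R'
    'synthetic-truth.R'
    'synthetic-observe.R'
    'synthetic-qpcr.R'
    'synthetic-hdg-mags.R'
    'taxprofiles-io.R'
    'taxprofiles-consensus.R'
    'qpcr.R'
    'hdo.R'
    'mcia.R'
    'hdg-mags.R'
    'depletion.R'
    'pipeline.R'
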