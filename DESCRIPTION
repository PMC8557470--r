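Package: admixscan
Title: Genome Scans for Adaptive Introgression, Selective Sweeps and
    Balancing Selection in Admixed Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genomic scans for admixed cohorts of
    diploid individuals: nucleotide diversity, absolute divergence and
    Hudson's FST in non-overlapping windows; four-taxon introgression
    statistics (Patterson's D, fdM and a distance-fraction estimator)
    with genome-wide Z-score and FDR outlier calling; supervised
    admixture proportions and local-ancestry dosage via a two-donor
    hidden Markov model with the allele-dosage-difference (ADD) score;
    a haplotype-allele-frequency (HAF/SAFE/iSAFE) selective-sweep scan
    with case/control contrast; and a folded-beta balancing-selection
    scan with cross-population shared-site intersection and beta-by-ADD
    classification.  Includes a synthetic admixed-cohort generator
    (divergent donor panels, an outgroup, ancestry-mosaic hybrids, a
    planted introgressed sweep tract and clustered balancing-selection
    loci) with a machine-readable truth record, plus site-level VCF
    filters, LD pruning and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'gio.R'
    'simdata.R'
    'winstats.R'
    'introg.R'
    'ancestry.R'
    'sweep.R'
    'balsel.R'
    'pipeline.R'
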