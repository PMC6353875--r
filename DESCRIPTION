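Package: csptitr
Title: Chemical Shift Perturbation Titration Analysis and Affinity Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of protein-ligand NMR titrations followed
    by 1H-15N HSQC spectroscopy. Computes weighted (normalized) chemical shift
    perturbations per backbone amide, classifies significantly perturbed
    residues with a trimmed mean-plus-SD threshold, fits the one-site binding
    isotherm with explicit ligand depletion to per-residue shift trajectories,
    and aggregates per-residue dissociation constants into a global Kd with
    outlier exclusion and lower-limit reporting. Also maps perturbed residues
    onto secondary-structure region annotations, exports ambiguous interaction
    restraints for data-driven docking, implements a strand-aware
    within-distance genomic peak overlap criterion for ChIP-seq comparisons,
    and provides a synthetic titration generator for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'binding.R'
    'csp.R'
    'csptitr-package.R'
    'overlap.R'
    'peaklist-io.R'
    'restraints.R'
    'regions.R'
    'significance.R'
    'pipeline.R'
    'simulate.R'
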