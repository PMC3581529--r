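Package: radsig
Title: Radiation Signatures and Structural Annotation for R2 Retrotransposon Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics for ancient rapid radiations in phylogenies of R2
    non-LTR retrotransposons, together with the structural annotation that
    defines the R2 clades. Implements likelihood mapping of quartets under
    amino-acid substitution models with discrete-gamma rate heterogeneity
    (barycentric weights, seven-region simplex classification, chi-squared
    comparison of sampling schemes), tree-shape radiation statistics
    (terminal versus internodal branch-length partition with Welch's t-test,
    relative node height versus nodal support correlation), neighbor joining
    with nonparametric bootstrap supports, N-terminal zinc-finger scanning
    and clade typing, 28S rRNA target-site and insertion-junction detection,
    family clustering at 90 percent identity, a permutation test for the
    "library" pattern of coexisting conspecific lineages, and seeded
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
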