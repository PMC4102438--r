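Package: par1map
Title: Pedigree Crossover Maps and Recombination-Driven Sequence Evolution
    in the Human Pseudoautosomal Region
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying recombination in the human pseudoautosomal
    region PAR1. Implements crossover detection in nuclear families with
    genotyping error and missing parents via a Lander-Green hidden Markov
    model over inheritance vectors, sex-specific genetic-map estimation
    from crossover posteriors, statistics comparing pedigree and
    LD-based maps (rank correlation at scale, crossover-centred rate
    profiles with bootstrap, two-map mixture-weight likelihood fits,
    mean-squared-difference bootstrap), degenerate-motif scanning and
    anchor thinning around PRDM9 binding targets, allele-frequency-spectrum
    statistics for GC-biased gene conversion (fixation-bias ratios,
    U-shaped mixture fits, near-motif spectra), human-chimpanzee
    substitution classification with per-class regression on recombination
    rate, and seeded generators that simulate every input so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
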