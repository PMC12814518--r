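Package: pancseq
Title: Selection-Sequencing Analysis for Phage-Assisted Site-Saturation Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for phage-assisted noncontinuous selection
    (PANCS) experiments on site-saturation mutagenesis libraries, as used to
    assay Rubisco large-subunit (RbcL) assembly at scale. Enumerates the
    codon-window variant space, counts variants from amplicon FASTQ reads by
    flank-anchored window extraction, computes per-passage frequency
    trajectories and log10 frequency-ratio fitness scores with a
    depleted/positive/negative classification, builds per-residue amino-acid
    enrichment matrices over positive-fitness variants, and includes a
    stochastic serial-passage simulator (multinomial infection bottleneck,
    chaperonin buffering, hitchhiker second-site mutations) that provides
    ground-truth data for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
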