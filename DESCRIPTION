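Package: methwindow
Title: Windowed Methylation Analysis for Targeted Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Context-resolved (CpG/CHG/CHH) DNA methylation analysis of
    TSS-anchored target regions from cytosine-level bisulfite sequencing
    counts. Enumerates strand-resolved cytosine sites and classifies their
    trinucleotide context, computes read-weighted and per-context methylation
    levels, decomposes methylated and unmethylated site fractions by context,
    measures shared methylation states between sample groups, tiles regions
    into 50-bp windows for metaprofiles, and calls differentially methylated
    regions and genes with a two-tailed Fisher's exact test combined with a
    percentage-point effect-size threshold. A seeded simulator emulates a
    two-condition by two-embryo-part factorial design with three replicates
    so every stage can be verified end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
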