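Package: abequant
Title: Quantification of Adenine Base-Editing Outcomes from Amplicon Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify adenine base editor (ABE) outcomes from targeted
    amplicon deep sequencing. Reads are quality-filtered, optionally merged,
    demultiplexed to reference amplicons, and aligned semi-globally; per-position
    A-to-G profiles, indel frequencies, cumulative editing and a positional
    precision metric are computed, and each read's allele within the
    quantification window is classified into wild-type, desired-only,
    desired-plus-bystander, bystander-only and indel categories, from which
    product purity and founder-triage calls are derived. Also includes an sgRNA
    design helper for PAM-flexible nickase editors (PAM classing, codon
    consequence annotation, off-target mismatch annotation) and a synthetic-read
    simulator with narrow- and broad-window editor presets and mosaic-founder
    mixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, CRISPR, Alignment, Software
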