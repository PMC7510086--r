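Package: dualedit
Title: Quantification of Dual Base Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies and quantifies base-editing outcomes at CRISPR
    protospacers from amplicon deep-sequencing reads. Each read is
    quality-filtered, oriented and aligned to its reference amplicon, and
    classified as unedited, C-to-T only, A-to-G only, simultaneous
    same-strand C-to-T plus A-to-G, indel-bearing, or other. Site-level
    summaries include outcome-category frequencies, allele (haplotype)
    tables, per-position editing spectra in PAM-relative coordinates,
    cross-site window aggregation, dinucleotide motif preference, and
    Welch t-test group comparisons. Also provides sgRNA design checks
    under the G-N19-NGG rule, PAM-anchored spacer-length variants, a
    k-mismatch un-gapped off-target scanner, and a synthetic FASTQ
    generator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
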