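Package: bedesign
Title: Design and a Priori Scoring of CRISPR Base-Editing Guide RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs libraries of guide RNAs for CRISPR base editors (cytosine
    and adenine deaminase fusions) against locally annotated genomes (FASTA +
    GFF3). Mutation requests are accepted at nucleotide level (genome
    coordinate and desired base) or amino-acid level (transcript id, residue
    position and desired residue), in "model" mode (introduce a mutation on
    the reference background) or "correct" mode (revert an alternative allele
    to the reference). Guides are enumerated for arbitrary combinations of
    base editors (conversion chemistry plus activity window) and IUPAC PAM
    patterns on either side of the spacer, on both strands. Each guide is
    scored a priori by a multiplicative penalty system combining mismatch
    position penalties at genome-wide off-target alignments (Hamming distance
    within a configurable mismatch budget), genic/intergenic placement of
    those alignments, and whether the editable base lies inside the editor's
    activity window. Includes positive (nonsense) and negative (no editable
    base in window) control guide design, poly-T annotation, a deterministic
    synthetic genome/mutation fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
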