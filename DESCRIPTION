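Package: contigdot
Title: K-mer Dot-Plot Alignment and Ordering of Contigs Against a Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns assembled contigs (query FASTA records) against a single
    reference sequence by exact k-mer matching on both strands, merges
    co-diagonal k-mer anchors into maximal exact-match segments, resolves
    overlapping segments into a non-overlapping reference tiling by a greedy
    longest-segment sweep, ranks queries by percent similarity to the
    reference, and renders dot plots (PDF, PNG, PS, SVG) together with text
    outputs: the optimally placed segment listing and the similarity-ranked
    query FASTA. Includes a synthetic-data generator that splits a reference
    into fragments and shuffles them for validation of the alignment
    pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    graphics,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
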