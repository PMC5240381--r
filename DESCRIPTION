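Package: truncmap
Title: Crosslink-Site Mapping and Diagnostics for Truncation-Based CLIP Data
Version: 0.1.0
Authors@R:
    person("truncmap", "developers", email = "truncmap@example.org",
           role = c("aut", "cre"))
Description: Analysis of iCLIP, eCLIP and irCLIP libraries in which reverse
    transcription truncates at the crosslinked peptide, so that cDNA-starts
    identify protein-RNA crosslink sites and cDNA-ends mark RNase cleavage
    sites. Provides UMI-aware loading of aligned cDNAs, definition of
    crosslink-associated (CL) sequence motifs, positional deletion and
    T-to-C transition profiles, permutation-FDR crosslink-cluster and peak
    calling, diagnostics for cDNA-end constraints (start/end offset
    heatmaps, peak-to-flank log2 ratios, length-stratified profiles),
    metagene RNA maps around exon-exon junctions and pyrimidine tracts,
    and a mechanistic read simulator with per-molecule ground truth so
    that every analysis stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
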