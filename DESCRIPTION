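Package: disintegrindb
Title: Discovery of Putative Disintegrins in Secreted Salivary Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Scans protein sequences from blood-feeding animals for the
    eight disintegrin tripeptide motifs (RGD, MLD, KGD, VGD, KTS, RTS,
    WGD, RED) presented between flanking cysteines within bounded
    spacers, gates candidates on the presence of an N-terminal signal
    peptide, annotates each hit with its putative integrin and cell
    targets, flags duodegrins (sequences carrying more than one distinct
    motif), and writes a sialogenin database table. A phylogenetics
    module builds neighbor-joining phylograms with percent bootstrap
    supports from protein alignments. A synthetic proteome generator
    with a ground-truth ledger makes every pipeline stage testable
    offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
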