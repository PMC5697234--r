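Package: synviz
Title: Multi-Genome Synteny Detection and Visualization
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparative genomics: validates
    repositories of annotated genome assemblies (genome/cds/pep FASTA plus
    GFF3), clusters all-vs-all protein similarity hits into ortholog groups
    by reciprocal best hits with single-linkage clustering or by Markov
    clustering (MCL), chains collinear ortholog pairs between genome pairs
    into syntenic blocks with a DAGchainer-style dynamic program, orders and
    orients scaffolds to minimize ribbon crossings between adjacent genome
    tracks, and renders a publication-style multi-genome synteny ribbon
    figure to PDF, driven by a self-generated, hand-editable configuration
    file. Includes a genome-rearrangement simulator (inversions,
    translocations, gene loss and duplication, noisy hit tables) with a
    complete truth ledger for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    data.table,
    igraph,
    methods,
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    parallel,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
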