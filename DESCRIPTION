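Package: rRFscan
Title: Identification, Classification and Quantification of rRNA-Derived
    Small RNAs from Small RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates ribosomal-RNA-derived small RNAs (rsRNAs, 16-40 nt)
    from reference-aligned small RNA sequencing reads. Builds an
    rRNA-masked "artificial" genome together with an rRNA transcript
    reference from an NCBI assembly feature table, retains reads that map
    exclusively to rRNA space, classifies fragments positionally into
    5'-anchored (rRF-5), 3'-anchored (rRF-3) and internal (rRF-i)
    categories, aggregates them into loci with a predominant sequence,
    normalizes abundance to reads per million (RPM), and writes annotation
    tables, summary statistics, figures and a self-contained HTML report
    with dot-bracket secondary structure. Includes a deterministic
    synthetic-data generator (reference, reads, truth tables and SAM
    alignments) and a YAML-configured pipeline driver with content-digest
    freshness checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
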