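Package: amplimeth
Title: Epiallele Pattern Counting for Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes per-read CpG methylation patterns (epialleles) from
    targeted bisulfite amplicon sequencing. Parses Bismark
    methylation-extractor call files and a BED-like amplicon definition file,
    assembles ordered methylation-state strings for every read over each
    amplicon's CpG sites, counts and ranks the distinct patterns, computes
    bisulfite conversion QC from non-CpG calls, and writes a tab-delimited
    pattern-count summary plus a self-contained HTML visualization per
    sample. Includes a simulator that generates extractor-format files from
    declared epiallele mixtures with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
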