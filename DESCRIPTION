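Package: compactaln
Title: Structured Compression and Multi-Tier Storage of Sequencing Reads and Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Schema-evolvable columnar compression of high-throughput
    sequencing reads and alignments. Implements a chunked container format
    with pluggable codecs (gzip, bzip2 and an arithmetic-coding/template
    hybrid), separate field encoding, field modeling, template compression
    and intra-chunk link optimization, with lossless round-trip fidelity.
    Includes SAM and FASTQ interoperability, genomic sorting and indexing,
    query-index permutation, and deterministic synthetic fixture generators
    emulating RNA-Seq, exome, whole-genome and bisulfite alignment data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
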