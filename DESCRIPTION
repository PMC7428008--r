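Package: trcscan
Title: Binned ChIP-Seq Enrichment, Read Apportionment, and Replication
    Stress Assays for Transcription-Replication Conflict Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for studies of transcription-replication
    conflicts and R-loop associated DNA damage. Converts aligned ChIP-Seq
    reads into depth-normalized 25-bp binned density tracks (200-bp read
    extension), identifies significantly enriched bins under a Poisson
    background model estimated from whole-cell-extract input, and calls
    per-gene fold enrichment between two conditions intersected with
    co-regulated gene sets. Also apportions reads sequentially to genomic
    feature classes (TSS region, 5'UTR, TTS region, 3'UTR, exonic, intronic,
    intergenic), quantifies DRIP-qPCR relative abundance of DNA:RNA hybrids
    normalized to non-immunoprecipitated input, computes comparative-Ct
    relative expression, and converts DNA fiber combing tract lengths into
    replication fork speeds and fork-class calls. A synthetic-data generator
    emulates a paired DMSO/JQ1 two-condition ChIP-Seq design (BRD4, gH2AX,
    RNAPII ser2, input libraries) with ground truth for recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    BiocGenerics,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
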