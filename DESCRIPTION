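Package: cgimprint
Title: CpG Island Positional Profiling, Tiling-Array Transcript Extent, and
    Imprinting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational analyses used to characterise a CpG
    island (CGI) lying downstream of the promoter of an imprinted macro
    non-coding RNA. Includes a CGI-centric transcription start site metagene
    profiler with proportional 50%-length flanks, a tiling-array
    relative-intensity pipeline (Tukey biweight normalisation, overlapping
    9-tile windows averaged in blocks of 20) with a transcript-extent caller,
    strand-specific read-count log2-ratio windows, bisulfite clone quality
    control and per-allele methylation summaries, allelic-expression and
    qPCR relative-quantification helpers, Mendelian genotype-ratio tests,
    and seeded synthetic-data generators that emulate each input so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
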