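Package: barcodify
Title: Synthetic Cell Barcode Injection and Read-Structure Rewriting for
    FASTQ
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Streaming manipulation of FASTQ read structures for
    plate-based single-cell sequencing libraries that lack in-read cell
    barcodes. Inserts a user-defined synthetic cell barcode (or synthetic
    UMI, or any arbitrary nucleotide sequence) at the 5' end of each read
    or immediately after a 5' UMI, and removes fixed-length linker/spacer
    sequences, so that the rewritten reads satisfy the cell-barcode plus
    UMI geometry expected by droplet-oriented tools such as STARsolo,
    zUMIs, and Alevin. Reads and writes plain or gzip-compressed FASTQ,
    including standard input and output, in a single bounded-memory pass.
    Ships a seeded synthetic-read generator with a ground-truth
    decomposition table for validation, and a pipe-friendly command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
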