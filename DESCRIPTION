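Package: esega
Title: Decoding Six-Letter AEGIS DNA from Four-Letter Sequencing Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for enzyme-assisted sequencing of an expanded genetic
    alphabet (ESEGA). Six-letter GACTZP DNA built on the artificially
    expanded genetic information system (AEGIS) Z:P pair cannot be read
    directly by standard sequencers; it is first transliterated to
    four-letter DNA by cytidine deamination (C to U) and transliterative
    PCR (Z to C, P to G), sequenced, and then decoded back to six letters
    by comparing deaminated against control runs or sense against
    antisense strands. The package provides the expanded-alphabet sequence
    model with in-silico restriction digestion, a seeded forward simulator
    of the deamination/transliteration chemistry that generates FASTQ
    reads with ground truth, lightweight amplicon read processing (pair
    merging, inline-barcode filtering, anchored alignment, per-position
    pileups), single-strand and duplex six-letter base callers with
    composition tables and sequence-logo matrices, and the fidelity
    statistics used to characterise six-nucleotide PCR: per-position Z:P
    retention, nominal doublings, per-cycle fidelity, mixture-series
    calibration, and flanking-context bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
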