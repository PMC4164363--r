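Package: barcodeLib
Title: Curation and Species Assignment with COI DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate reference libraries of COI-5P DNA barcodes and to
    assign species to blind query sequences. Implements sequence quality
    control for the mitochondrial barcode fragment (reading-frame and
    stop-codon checks under the vertebrate mitochondrial code), Kimura
    2-parameter pairwise distances with pairwise deletion and undefined-pair
    tracking, neighbour-joining trees with bootstrap support, extraction of
    monophyletic clusters below a divergence threshold, an A-E reliability
    grading of reference species, a two-stage blind assignment protocol
    (cluster membership at <2% divergence, then a >=98% identity fallback
    search), flagging of deep intraspecific divergences with geographic
    sorting, and a coalescent-free hierarchical simulator of barcode
    libraries with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
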