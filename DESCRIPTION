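Package: toxcut
Title: Endoribonuclease Toxin Cleavage-Site Mapping and Codon-Dependent
    Proteome Reprogramming from 5'-End RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps the RNA targets of MazF-family endoribonuclease toxins
    from 5'-OH-selected RNA-seq libraries and follows the downstream
    consequences of tRNA cleavage through to the proteome. Implements the
    full computational pipeline (adapter/UMI trimming to 20-nt reads,
    exact-match read-start counting, rpm normalisation and pseudocounted
    fold changes, threshold-based cleavage-site calling, ribosome-stall
    inference from secondary mRNA cuts ~15 nt upstream of lysine codons,
    and spectral-count differential translation stratified by AAA/AAG
    codon content), together with a forward simulator of the whole
    mechanism so every stage is verifiable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
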