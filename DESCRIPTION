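Package: nomtrans
Title: Neural Translation Between SMILES and IUPAC Chemical Notations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidirectional translation between SMILES strings and IUPAC
    chemical names with a sequence-to-sequence Transformer trained from
    scratch. Provides rule-based lossless tokenizers for both notations, a
    curated IUPAC token lexicon, corpus screening, an encoder-decoder
    Transformer with beam-search decoding implemented in C++, and a
    round-trip verification step that parses every candidate name back to a
    structure and abstains rather than emit a wrong name. Includes a
    synthetic generator of provably correct (canonical SMILES, IUPAC name)
    pairs for a constrained acyclic nomenclature subclass, a rule-based
    name-to-structure parser for that subclass, and evaluation protocols:
    exact-match accuracy per beam size, accuracy-versus-length binning,
    stereo-density subsetting, and kekulized/augmented-SMILES robustness
    harnesses. Canonicalization is delegated to Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
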