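# Shared fixtures, built in code.

# Tautomer fixture: guanine and uracil tautomers with systematic names
# (distinct canonical SMILES per tautomer; several carry several names).
tautomer_smiles <- c(
  "N=c1nc(O)c2[nH]cnc2[nH]1",
  "Nc1nc(=O)c2nc[nH]c2[nH]1",
  "Nc1nc(=O)c2[nH]cnc2[nH]1",
  "Nc1[nH]c(=O)c2[nH]cnc2n1",
  "Nc1nc(O)c2[nH]cnc2n1",
  "O=c1cc[nH]c(=O)[nH]1",
  "Oc1ccnc(O)n1",
  "O=c1ccnc(O)[nH]1",
  "Oc1cc[nH]c(=O)n1"
)

tautomer_names <- c(
  "2-Imino-3,7-dihydropurin-6-ol", "2-imino-1,7-dihydropurin-6-ol",
  "2-Amino-3,9-dihydropurin-6-one",
  "2-Amino-3,7-dihydropurin-6-one", "2-amino-6,7-dihydro-3H-purin-6-one",
  "2-amino-3,6-dihydropurin-6-one", "2-amino-7H-purin-6-one",
  "2-Amino-1,7-dihydropurin-6-one", "2-amino-1,6-dihydropurin-6-one",
  "2-Amino-7H-purin-6-ol", "2-aminopurin-6-ol",
  "1H-Pyrimidine-2,4-dione",
  "Pyrimidine-2,4-diol",
  "2-Hydroxy-1H-pyrimidin-6-one", "2-hydroxypyrimidin-6-one",
  "4-Hydroxy-1H-pyrimidin-2-one", "4-hydroxypyrimidin-2-one"
)

# pairs: each tautomer SMILES with its first listed name
tautomer_pairs <- data.frame(
  smiles = tautomer_smiles,
  name = tautomer_names[c(1, 3, 4, 8, 10, 12, 13, 14, 16)],
  stringsAsFactors = FALSE
)

# the four names generated for the dual-benzamide worked example
benzamide_names <- c(
  "3-[[2-[3-(tert-butylcarbamoyl)anilino]acetyl]amino]-N-(3-methoxypropyl)benzamide",
  "N-(3-methoxypropyl)-3-[[2-[3-(tert-butylcarbamoyl)anilino]acetyl]amino]benzamide",
  "N-tert-butyl-3-[[2-[3-(3-methoxypropylcarbamoyl)anilino]-2-oxoethyl]amino]benzamide",
  "3-[[2-[3-(3-methoxypropylcarbamoyl)anilino]-2-oxoethyl]amino]-N-tert-butylbenzamide"
)

# small deterministic corpus shared across tests (cached per session)
.fixture_env <- new.env()
small_corpus <- function(size = 400, seed = 7, stereo_fraction = 0.1) {
  key <- paste(size, seed, stereo_fraction)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_pairs(
      generator_spec(size = size, seed = seed,
                     stereo_fraction = stereo_fraction),
      self_validate = FALSE)
  }
  .fixture_env[[key]]
}

# micro-lexicon: five name tokens, so the target vocabulary is small
# enough for exhaustive sequence enumeration in the beam-oracle tests
toy_lexicon <- function() {
  if (is.null(.fixture_env$toylex)) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("# version: toy-0", "etha\tstem", "propa\tstem",
                 "metha\tstem", "nol\tsuffix", "ne\tsuffix"), f)
    .fixture_env$toylex <- read_lexicon(f)
  }
  .fixture_env$toylex
}

# a tiny trained model on a micro-vocabulary task, for decode tests
toy_model <- function(seed = 1) {
  key <- paste0("toy", seed)
  if (is.null(.fixture_env[[key]])) {
    pairs <- data.frame(
      smiles = c("CCO", "CCC", "CO"),
      name = c("ethanol", "propane", "methanol"),
      stringsAsFactors = FALSE
    )
    .fixture_env[[key]] <- nomtrans(
      pairs, "smiles2name",
      config = model_config("desk", n_encoder_layers = 1, n_decoder_layers = 1,
                            n_heads = 2, d_model = 32, d_ff = 64, max_len = 16,
                            dropout = 0),
      training = training_config(epochs = 250, batch_size = 3, lr_mult = 1,
                                 warmup_steps = 50, label_smoothing = 0,
                                 seed = seed),
      lexicon = toy_lexicon(),
      quiet = TRUE)
  }
  .fixture_env[[key]]
}
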