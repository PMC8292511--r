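# nomtrans: neural translation between SMILES and IUPAC chemical names

Chemical structures are written two ways: as SMILES strings
(machine-friendly line notation) and as systematic IUPAC names (required
by journals, patents and regulatory filings). Turning a structure into a
correct name is classically the job of large hand-curated rule engines.
`nomtrans` treats it as machine translation: an encoder–decoder
Transformer reads one notation token by token and writes the other, and a
**verification step** makes the statistical model trustworthy — every
candidate name produced by beam search is parsed back to a structure, and
a name is emitted only if its structure is *canonically identical* to the
input. If no candidate survives, the system abstains: a wrong name is
never displayed.

The package is a complete, self-contained laboratory for this approach,
written for R with the heavy numerics in C++ (RcppArmadillo):

* **Tokenizers** — character-level SMILES tokenization and a rule-based
  IUPAC tokenizer over a curated, versioned lexicon (stems, suffixes,
  prefixes, multipliers, stereo-descriptors, locants, punctuation), both
  lossless, with corpus screening (`screen_corpus()`) that excludes
  untokenizable molecules.
* **Model** — a from-scratch Transformer (`nomtrans()`): multi-head
  attention, post-layer-norm residual blocks, sinusoidal positions, Adam
  with inverse-square-root warmup, label smoothing, gradient clipping,
  deterministic seeding; greedy and beam-search decoding with exact
  tie-breaking (`translate_beam()`, `translate_greedy()`).
* **Verification** — `verify_candidates()` / `predict(..., verify = TRUE)`
  with an injectable name→structure parser; the built-in `parse_iupac()`
  covers the package's nomenclature subclass plus multi-parent benzamide
  names. Canonical identity is decided by Open Babel (via ChemmineOB).
* **Synthetic corpus** — `generate_pairs()` emits provably correct
  (canonical SMILES, IUPAC name) pairs for acyclic chains C1–C20
  (alkanes, alkanols, alkanones, haloalkanes, (E/Z)-alkenes, diols,
  polysubstituted variants); every batch is self-validated by round-trip
  parsing.
* **Evaluation** — exact-match accuracy per beam width (abstentions count
  as errors), accuracy-versus-length binning, stereo-density subsetting
  (I = S/N), length distributions, and kekulized / augmented-SMILES
  robustness harnesses.

## A worked example

```r
library(nomtrans)

# a provably correct corpus: 5,000 (canonical SMILES, name) pairs
pairs <- generate_pairs(generator_spec(size = 5000, seed = 42))
sp    <- split_pairs(pairs, holdout_fraction = 0.1, seed = 1)

# train the structure-to-name Transformer (desk preset: 2+2 layers,
# 4 heads, d_model 128 -- minutes on one CPU)
model <- nomtrans(sp$train, "smiles2name",
                  config = model_config("desk"),
                  training = training_config(seed = 1))
#> training smiles2name Transformer on 4500 pairs (50 epochs, batch 64, seed 1)
model
#> nomtrans Transformer (smiles2name)
#>   2+2 layers, 4 heads, d_model 128, d_ff 256 -- 705,419 parameters
#>   trained 3550 steps on 4500 pairs (lexicon 1.0); final loss 0.8669

# translate held-out structures with beam search + verification
predict(model, sp$holdout$smiles[1:3], beam = 5)[, c("input", "output", "n_correct", "abstained")]
#>                             input                     output n_correct abstained
#>                   CCCCC(CC(CC)O)O            nonane-3,5-diol         1     FALSE
#>          CCCCCCCCCCC(CCCCCC(O)C)O        octadecane-2,8-diol         1     FALSE
#>   CCCCCCC(CCCCCCCC(CCCC)(Cl)Cl)Cl 5,5,13-trichlorononadecane         1     FALSE

# evaluation protocol on the full held-out split
ev <- evaluate_model(model, sp$holdout, beams = c(1, 3, 5))
sapply(c(1, 3, 5), function(k) exact_match_accuracy(ev, k))
#> [1] 0.832 0.958 0.980
```

(Output above is from one desk run with the seeds shown; loss and
accuracy reproduce exactly for a fixed seed on the same backend.)

Every emitted name is round-trip correct by construction:
`nonane-3,5-diol` parses back to `CCCCC(CC(CC)O)O`'s canonical form.
Accuracy climbs with beam width (83.2% → 95.8% → 98.0%) because
verification can rescue a correct name from anywhere in the beam.
Molecules whose candidates all fail verification return `output = NA`
(`abstained = TRUE`) instead of a wrong name.

A thin CLI mirrors the library (`inst/cli/nomtrans`): `generate`,
`tokenize`, `train`, `translate --verify --beam K`, `evaluate`,
`pipeline`.

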