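test_that("SMILES tokenization is one character per token and lossless", {
  expect_equal(tokenize_smiles("CCO")$tokens, c("C", "C", "O"))
  uracil <- "O=c1cc[nH]c(=O)[nH]1"
  tk <- tokenize_smiles(uracil)
  expect_length(tk$tokens, nchar(uracil))
  expect_length(tk$tokens, 20L)
  expect_identical(detokenize(tk), uracil)
  # atom mode keeps bracket atoms and two-letter halogens together
  at <- tokenize_smiles("CC(Cl)[nH]1", mode = "atom")
  expect_true("Cl" %in% at$tokens && "[nH]" %in% at$tokens)
  expect_identical(detokenize(at), "CC(Cl)[nH]1")
})

test_that("SMILES tokenization rejects bad input with position information", {
  expect_error(tokenize_smiles(""), "empty")
  err <- tryCatch(tokenize_smiles("CCq"), error = identity)
  expect_match(conditionMessage(err), "'q'")
  expect_match(conditionMessage(err), "position 3")
})

test_that("IUPAC tokenization is deterministic, lossless and lexicon-bound", {
  lex <- default_lexicon()
  expect_equal(tokenize_iupac("pyrimidine-2,4-diol")$tokens,
               c("pyrimidine", "-", "2", ",", "4", "-", "di", "ol"))
  nm <- "2-aminopurin-6-ol"
  tk1 <- tokenize_iupac(nm); tk2 <- tokenize_iupac(nm)
  expect_identical(tk1, tk2)
  expect_identical(detokenize(tk1), nm)
  # every token is a lexicon entry
  expect_true(all(tk1$tokens %in% lex$iupac$token))
})

test_that("tautomer-table and worked-example names all round-trip losslessly", {
  for (nm in c(tautomer_names, benzamide_names)) {
    expect_identical(detokenize(tokenize_iupac(nm)), nm)
  }
})

test_that("out-of-lexicon fragments are rejected with the longest prefix", {
  err <- tryCatch(tokenize_iupac("2-amino-1,3-selenazole"),
                  error = identity)
  expect_match(conditionMessage(err), "untokenizable")
  expect_match(conditionMessage(err), "longest tokenizable prefix")
})

test_that("single-step backtracking recovers from greedy dead ends", {
  lexfile <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# version: toy", "ab\tstem", "abc\tstem", "ca\tsuffix"),
             lexfile)
  lex <- read_lexicon(lexfile)
  # greedy eats "abc" then dead-ends on "a"; backtracking finds ab + ca
  expect_equal(tokenize_iupac("abca", lex)$tokens, c("ab", "ca"))
  expect_true(segmentable("abca", lex))
  expect_false(segmentable("abx", lex))
})

test_that("empty-input and detokenize edge cases behave", {
  expect_error(tokenize_iupac(""), "empty")
  expect_identical(detokenize(character(0)), "")
})

test_that("greedy segmentation agrees with the exhaustive oracle on corpus names", {
  pairs <- small_corpus()
  for (nm in pairs$name) {
    greedy_ok <- !inherits(try(tokenize_iupac(nm), silent = TRUE), "try-error")
    expect_identical(greedy_ok, segmentable(nm), info = nm)
  }
})

test_that("screen_corpus keeps exactly the tokenizable pairs and reports causes", {
  pairs <- data.frame(
    smiles = c("CCO", "CCC", "CCq", "CCCC"),
    name = c("ethanol", "propane", "propane", "xylitolZZZ"),
    stringsAsFactors = FALSE)
  out <- screen_corpus(pairs)
  expect_equal(out$report$n_input, 4L)
  expect_equal(out$report$n_kept, 2L)
  expect_equal(out$report$n_rejected_smiles, 1L)
  expect_equal(out$report$n_rejected_name, 1L)
  expect_equal(out$report$coverage, 0.5)
  expect_identical(out$kept$smiles, c("CCO", "CCC"))

  # all-tokenizable input: full coverage
  ok <- screen_corpus(tautomer_pairs)
  expect_equal(ok$report$n_kept, nrow(tautomer_pairs))
  expect_equal(ok$report$coverage, 1.0)
})

test_that("lexicon coverage is monotone in the lexicon", {
  # removing entries can only lose coverage; adding them back restores it
  lex <- default_lexicon()
  small <- lex
  drop <- small$iupac$token != "purin"
  small$iupac <- small$iupac[drop, ]
  small$index <- nomtrans:::.build_match_index(small$iupac$token)
  pairs <- tautomer_pairs
  cov_small <- screen_corpus(pairs, small)$report$coverage
  cov_full <- screen_corpus(pairs, lex)$report$coverage
  expect_lte(cov_small, cov_full)
  expect_lt(cov_small, 1.0)
})

test_that("the shipped lexicon satisfies its structural invariants", {
  lex <- default_lexicon()
  expect_true(all(nzchar(lex$iupac$token)))
  classes <- c("stem", "suffix", "prefix", "multiplier", "stereo", "locant",
               "punct", "symbol")
  expect_setequal(unique(lex$iupac$class), classes)
  # entries called out by the nomenclature: suffixes, multipliers, stems,
  # descriptors, the lambda marker
  need <- c("one", "al", "ol", "oxy", "hydroxy", "di", "tri", "tetra",
            "naphthalene", "pyrazole", "pyran", "adamantane",
            "(", ")", "[", "]", "-", ",", "N", "R", "S", "E", "Z",
            "λ", as.character(0:9))
  expect_true(all(need %in% lex$iupac$token))
  expect_false(anyDuplicated(paste(lex$iupac$token, lex$iupac$class)) > 0)
})
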