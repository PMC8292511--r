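test_that("fixed family members carry textbook names and structures", {
  alk <- generate_pairs(generator_spec(families = "alkane", size = 20, seed = 1,
                                       stereo_fraction = 0))
  expect_true(all(c("propane", "icosane", "methane") %in% alk$name))
  expect_true(canonical_equal(alk$smiles[alk$name == "propane"], "CCC"))
  ols <- generate_pairs(generator_spec(families = "alkan-1-ol", size = 20,
                                       seed = 1, stereo_fraction = 0))
  expect_true(canonical_equal(ols$smiles[ols$name == "ethanol"], "CCO"))
  ones <- generate_pairs(generator_spec(families = "alkan-2-one", size = 10,
                                        seed = 1, stereo_fraction = 0))
  expect_true(canonical_equal(ones$smiles[ones$name == "propan-2-one"],
                              "CC(=O)C"))
})

test_that("generation is a pure function of the spec", {
  sp <- generator_spec(size = 60, seed = 123, stereo_fraction = 0.1)
  p1 <- generate_pairs(sp, self_validate = FALSE)
  p2 <- generate_pairs(sp, self_validate = FALSE)
  expect_identical(p1, p2)
  # a different seed gives a different draw
  p3 <- generate_pairs(generator_spec(size = 60, seed = 124,
                                      stereo_fraction = 0.1),
                       self_validate = FALSE)
  expect_false(identical(p1$smiles, p3$smiles))
})

test_that("emitted corpora are canonical, tokenizable, duplicate-free and round-trip correct", {
  pairs <- generate_pairs(generator_spec(size = 150, seed = 5,
                                         stereo_fraction = 0.1))  # validating
  expect_false(anyDuplicated(pairs$smiles) > 0)
  expect_identical(pairs$smiles, canonical_smiles(pairs$smiles))
  expect_equal(sum(pairs$stereo), 15L)
  # stereo rows actually carry stereo marks
  expect_true(all(count_stereocenters(pairs$smiles[pairs$stereo],
                                      canonicalize = FALSE) >= 1L))
})

test_that("every lexicon class is exercised by the default families", {
  pairs <- small_corpus()
  lex <- default_lexicon()
  toks <- unique(unlist(lapply(pairs$name, function(nm)
    tokenize_iupac(nm, lex)$tokens)))
  cls <- unique(lex$iupac$class[lex$iupac$token %in% toks])
  expect_true(all(c("stem", "suffix", "prefix", "multiplier", "stereo",
                    "locant", "punct") %in% cls))
})

test_that("infeasible specs are rejected", {
  expect_error(generate_pairs(generator_spec(families = "alkane", size = 5,
                                             seed = 1, stereo_fraction = 0,
                                             length_window = c(500, 600))),
               "infeasible")
  expect_error(generate_pairs(generator_spec(families = "alkane", size = 100,
                                             seed = 1, stereo_fraction = 0)),
               "infeasible")
  expect_error(generator_spec(families = "no-such-family", size = 5),
               "unknown")
})
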