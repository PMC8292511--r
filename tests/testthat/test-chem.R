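test_that("canonical equality identifies identical molecules across writings", {
  expect_true(canonical_equal("CCO", "OCC"))
  expect_false(canonical_equal("CCO", "CCN"))
  expect_true(canonical_equal("C1=CC=CC=C1", "c1ccccc1"))
  # stereochemistry participates in identity
  expect_false(canonical_equal("C/C=C/C", "C/C=C\\C"))
  # tautomers are different canonical structures
  expect_false(canonical_equal(tautomer_smiles[6], tautomer_smiles[7]))
  expect_error(canonical_equal("C1CC", "CC"), "left")
  expect_error(canonical_equal("CC", "[Xx]"), "right")
})

test_that("kekulization removes aromatic lowercase and preserves identity", {
  k <- kekulize_input("c1ccccc1")
  expect_false(grepl("[cnops]", gsub("\\[[^]]*\\]", "", k)))
  expect_true(canonical_equal(k, "c1ccccc1"))
  expect_identical(kekulize_input("CCO"), "CCO")
  guanine <- "Nc1nc(=O)c2[nH]cnc2[nH]1"
  kg <- kekulize_input(guanine)
  expect_false(grepl("c", kg, fixed = TRUE))
  expect_true(canonical_equal(kg, guanine))
})

test_that("augmentation rewrites the string but never the molecule", {
  a <- augment_smiles("CCO", seed = 1)
  expect_true(canonical_equal(a, "CCO"))
  expect_false(identical(a, canonical_smiles("CCO")))
  # degenerate single-atom case: no alternative traversal exists
  expect_identical(augment_smiles("C", seed = 1), "C")
  # many augmentations of one decane all stay the same molecule
  dec <- canonical_smiles("CCCCCCCCCC")
  augs <- vapply(1:25, function(s) augment_smiles(dec, seed = s), "")
  expect_true(all(canonical_equal(augs, dec)))
  # determinism in (input, seed)
  expect_identical(augment_smiles("CC(Cl)CCO", seed = 9),
                   augment_smiles("CC(Cl)CCO", seed = 9))
})

test_that("stereo counting sees tetrahedral marks and marked double bonds", {
  expect_equal(count_stereocenters(c("C/C=C/C", "CCCC", "C[C@H](N)C(=O)O")),
               c(1L, 0L, 1L))
  expect_equal(count_stereocenters("C/C=C/C=C/C"), 2L)
  expect_equal(smiles_length("O=c1cc[nH]c(=O)[nH]1"), 20L)
})
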