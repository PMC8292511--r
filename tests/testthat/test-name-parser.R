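# The rule-based name -> structure parser, checked against independently
# written SMILES for the supported nomenclature subset.

test_that("acyclic parents, suffixes and prefixes parse to the right structures", {
  cases <- list(
    c("propane", "CCC"),
    c("icosane", strrep("C", 20)),
    c("methanol", "CO"),
    c("ethanol", "CCO"),
    c("butan-2-ol", "CCC(C)O"),
    c("propan-2-one", "CC(C)=O"),
    c("ethanal", "CC=O"),
    c("2-methylpropane", "CC(C)C"),
    c("1-chlorobutane", "CCCCCl"),
    c("chloromethane", "CCl"),
    c("butane-1,3-diol", "OCCC(C)O"),
    c("2,3-dichloropentane", "CCC(Cl)C(C)Cl"),
    c("2,2-dimethylbutane", "CCC(C)(C)C"),
    c("1,1,1-trichloroethane", "CC(Cl)(Cl)Cl"),
    c("4-chlorobutan-1-ol", "OCCCCCl"),
    c("5-bromononan-3-ol", "CCCCC(Br)CC(O)CC")
  )
  for (cs in cases) {
    expect_true(canonical_equal(parse_iupac(cs[1]), cs[2]), info = cs[1])
  }
})

test_that("E/Z descriptors produce the right double-bond geometry", {
  expect_true(canonical_equal(parse_iupac("(E)-but-2-ene"), "C/C=C/C"))
  expect_true(canonical_equal(parse_iupac("(Z)-but-2-ene"), "C/C=C\\C"))
  expect_false(canonical_equal(parse_iupac("(E)-hex-3-ene"),
                               parse_iupac("(Z)-hex-3-ene")))
  expect_true(canonical_equal(parse_iupac("(Z)-pent-2-en-1-ol"), "OC/C=C\\CC"))
})

test_that("the four multi-parent benzamide names map to one structure", {
  smis <- vapply(benzamide_names, parse_iupac, "", USE.NAMES = FALSE)
  cans <- canonical_smiles(smis)
  expect_length(unique(cans), 1L)
  # and that structure contains two amide carbonyls on aromatic rings
  expect_equal(lengths(regmatches(cans[1], gregexpr("C\\(=O\\)N|NC\\(=O\\)|O=C", cans[1]))) > 0, TRUE)
})

test_that("malformed or out-of-scope names raise parser errors", {
  expect_error(parse_iupac("2-aminopurin-6-ol"), "unsupported parent stem")
  expect_error(parse_iupac("butan-9-ol"), "locant")
  expect_error(parse_iupac("butan-1-"), "suffix|end of name|expected")
  expect_error(parse_iupac("(E)-butane"), "stereo")
})
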