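.cand <- function(outputs) {
  data.frame(output = outputs,
             log_score = -seq_along(outputs),
             rank = seq_along(outputs) - 1L,
             stringsAsFactors = FALSE)
}

test_that("the highest-ranked correct candidate is emitted", {
  v <- verify_candidates("CCO", .cand(c("ethanol", "ethanal")))
  expect_false(v$abstained)
  expect_identical(v$emitted, "ethanol")
  expect_equal(v$emitted_rank, 0L)
  expect_equal(v$n_valid, 2L)
  expect_equal(v$n_correct, 1L)

  # correct name at a lower rank still gets emitted
  v2 <- verify_candidates("CCO", .cand(c("ethanal", "ethanol")))
  expect_identical(v2$emitted, "ethanol")
  expect_equal(v2$emitted_rank, 1L)
})

test_that("abstention happens exactly when no candidate is correct", {
  v <- verify_candidates("CCO", .cand(c("not a name", "zzz")))
  expect_true(v$abstained)
  expect_true(is.na(v$emitted))
  expect_equal(v$n_valid, 0L)
  expect_equal(v$n_correct, 0L)

  v2 <- verify_candidates("CCO", .cand(c("propane", "butane")))
  expect_true(v2$abstained)
  expect_equal(v2$n_valid, 2L)
  expect_equal(v2$n_correct, 0L)
})

test_that("verification counts respect 0 <= n_correct <= n_valid <= k", {
  outs <- list(c("ethanol", "ethanol", "broken("),
               c("methanol", "ethanol"),
               c("not-a-name"))
  for (o in outs) {
    v <- verify_candidates("CCO", .cand(o))
    expect_gte(v$n_correct, 0L)
    expect_lte(v$n_correct, v$n_valid)
    expect_lte(v$n_valid, length(o))
    expect_identical(v$abstained, v$n_correct == 0L)
  }
})

test_that("every non-abstained emission parses back to the input structure", {
  # the core promise, checked by construction over a verified batch
  pairs <- small_corpus()[1:40, ]
  for (i in seq_len(nrow(pairs))) {
    # a mix of right and wrong names as mock candidates
    v <- verify_candidates(pairs$smiles[i],
                           .cand(c(pairs$name[(i %% 40) + 1], pairs$name[i])))
    if (!v$abstained) {
      expect_true(canonical_equal(parse_iupac(v$emitted), pairs$smiles[i]))
    }
  }
})

test_that("the worked example verifies: four names, one molecule, n_correct = 4", {
  structure_smiles <- parse_iupac(benzamide_names[1])
  v <- verify_candidates(structure_smiles, .cand(benzamide_names))
  expect_equal(v$n_correct, 4L)
  expect_equal(v$n_valid, 4L)
  expect_identical(v$emitted, benzamide_names[1])
})

test_that("multiplicity histograms tally verified translations", {
  mk <- function(nv, nc) structure(list(n_valid = nv, n_correct = nc),
                                   class = "nomtrans_verified")
  h <- multiplicity_histogram(list(mk(2L, 1L), mk(3L, 2L), mk(1L, 1L)))
  expect_equal(as.integer(h$n_correct[c("1", "2")]), c(2L, 1L))
  expect_equal(sum(h$n_valid), 3)
  expect_equal(sum(h$n_correct), 3)
  h0 <- multiplicity_histogram(list())
  expect_equal(length(h0$n_valid), 0L)
})

test_that("a reverse-direction model can close the verification loop", {
  pairs <- data.frame(smiles = c("CCO", "CCC", "CO"),
                      name = c("ethanol", "propane", "methanol"))
  rev <- nomtrans(pairs, "name2smiles",
                  config = model_config("desk", n_encoder_layers = 1,
                                        n_decoder_layers = 1, n_heads = 2,
                                        d_model = 32, d_ff = 64, max_len = 16,
                                        dropout = 0),
                  training = training_config(epochs = 250, batch_size = 3,
                                             lr_mult = 1, warmup_steps = 50,
                                             label_smoothing = 0, seed = 1),
                  quiet = TRUE)
  parser <- model_parser(rev)
  expect_true(canonical_equal(parser("ethanol"), "CCO"))
  v <- verify_candidates("CCO", .cand(c("ethanol", "propane")),
                         parser = parser)
  expect_identical(v$emitted, "ethanol")
  expect_equal(v$n_correct, 1L)
  expect_error(model_parser(toy_model()), "name2smiles")
})

test_that("a dual-parent fixture yields multiplicity mass at n_correct = 2", {
  # two legal name orderings for the same diol: both verify
  v <- verify_candidates("OCCCO", .cand(c("propane-1,3-diol",
                                          "3,1-propanediol-like-wrong",
                                          "propane-1,3-diol")))
  expect_gte(v$n_correct, 2L)
  h <- multiplicity_histogram(list(v))
  expect_true("2" %in% names(h$n_correct))
})
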