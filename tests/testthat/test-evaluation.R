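.mkrec <- function(correct, len = NULL, I = NULL) {
  n <- length(correct)
  df <- data.frame(
    smiles = strrep("C", 3 + seq_len(n)),
    smiles_len = if (is.null(len)) 3 + seq_len(n) else len,
    iupac_len = 4 + seq_len(n),
    n_stereocenters = 0L,
    correct_at_5 = correct,
    abstained_at_5 = !correct
  )
  df$stereo_density <- if (is.null(I)) 0 else I
  df
}

test_that("exact-match accuracy counts abstentions as incorrect", {
  expect_equal(exact_match_accuracy(.mkrec(c(TRUE, TRUE, TRUE, FALSE)), 5), 0.75)
  expect_equal(exact_match_accuracy(.mkrec(rep(FALSE, 3)), 5), 0)
  expect_error(exact_match_accuracy(.mkrec(TRUE)[0, ], 5), "no evaluation")
  expect_error(exact_match_accuracy(.mkrec(TRUE), 3), "beam 3")
})

test_that("accuracy is invariant to record order and bin-weighted accuracies recompose it", {
  set.seed(1)
  rec <- .mkrec(runif(40) > 0.4, len = sample(c(4, 8, 25, 60), 40, TRUE))
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(exact_match_accuracy(rec, 5), exact_match_accuracy(perm, 5))
  tab <- accuracy_by_length(rec, 5)
  expect_equal(sum(tab$n * tab$accuracy) / sum(tab$n),
               exact_match_accuracy(rec, 5))
})

test_that("the length-bin grid is the 46-bin 3..300 protocol grid", {
  b <- length_bins()
  expect_equal(length(b), 46L)
  expect_equal(min(b), 3L)
  expect_equal(max(b), 300L)
  expect_true(all(3:10 %in% b))
  expect_true(all(seq(15, 100, 5) %in% b))
  expect_true(all(seq(110, 300, 10) %in% b))
  expect_false(anyDuplicated(b) > 0)
})

test_that("per-bin tables report occupied bins only", {
  rec <- .mkrec(c(TRUE, FALSE, TRUE, TRUE), len = c(7, 7, 7, 7))
  tab <- accuracy_by_length(rec, 5)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$bin, 7L)
  expect_equal(tab$accuracy, 0.75)
})

test_that("stereo-density arithmetic and stereo-enriched subsetting", {
  rec <- .mkrec(rep(TRUE, 3), len = c(20, 30, 40), I = c(0.0, 0.2, 0.1))
  # I = S/N arithmetic: N=20, S=2 -> 0.1
  expect_equal(2 / 20, 0.1)
  top2 <- stereo_enriched_subset(rec, window = c(10, 60), size = 2)
  expect_equal(top2$stereo_density, c(0.2, 0.1))
  expect_warning(stereo_enriched_subset(rec, window = c(10, 60), size = 5),
                 "only 3")
})

test_that("the stereo-enriched subset raises the mean stereo density", {
  pairs <- small_corpus(size = 300, seed = 9, stereo_fraction = 0.3)
  rec <- data.frame(
    smiles_len = smiles_length(pairs$smiles),
    stereo_density = count_stereocenters(pairs$smiles, canonicalize = FALSE) /
      smiles_length(pairs$smiles))
  win <- rec[rec$smiles_len >= 10 & rec$smiles_len <= 60, ]
  sub <- stereo_enriched_subset(rec, window = c(10, 60),
                                size = round(nrow(win) * 0.1))
  expect_gt(mean(sub$stereo_density), mean(win$stereo_density))
  expect_lte(nrow(sub), round(nrow(win) * 0.1))
})

test_that("length distributions conserve record counts", {
  pairs <- small_corpus()[1:50, ]
  ld <- length_distribution(pairs)
  expect_equal(sum(ld$hist_smiles), 50)
  expect_equal(sum(ld$hist_iupac), 50)
  expect_equal(ld$mean_smiles, mean(smiles_length(pairs$smiles)))
  expect_error(length_distribution(pairs[0, ]), "no records")
  # trivial means
  expect_equal(length_distribution(
    data.frame(smiles_len = c(2, 4), iupac_len = c(3, 5)))$mean_smiles, 3.0)
})

test_that("robustness harness rejects empty input and is a no-op under identity transforms", {
  m <- toy_model()
  expect_error(robustness_harness(m, data.frame(smiles = character(0),
                                                name = character(0))),
               "empty")
  pairs <- data.frame(smiles = c("CCO", "CCC"),
                      name = c("ethanol", "propane"))
  rk <- robustness_harness(m, pairs, mode = "kekulized", beams = 1L)
  expect_equal(rk$n_excluded, 0L)
  # nothing aromatic: the transform is the identity, accuracy matches
  ev <- evaluate_model(m, pairs, beams = 1L)
  expect_equal(unname(rk$accuracy["beam_1"]), exact_match_accuracy(ev, 1L))
})

test_that("evaluation records on a real model satisfy their invariants", {
  m <- toy_model()
  pairs <- data.frame(smiles = c("CCO", "CCC", "CO"),
                      name = c("ethanol", "propane", "methanol"))
  ev <- evaluate_model(m, pairs, beams = c(1, 5))
  expect_equal(ev$stereo_density, ev$n_stereocenters / ev$smiles_len)
  expect_true(all(ev$n_correct <= ev$n_valid))
  expect_true(all(ev$n_valid <= 5L))
  expect_identical(ev$abstained_at_5, !ev$correct_at_5)
  # this memorized model translates its corpus perfectly
  expect_equal(exact_match_accuracy(ev, 5), 1.0)
})
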